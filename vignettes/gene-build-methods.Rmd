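---
title: "Methods: evidence-based gene building and tissue-specific cluster analysis"
author: "kaikobuild"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evidence-based gene building and tissue-specific cluster analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`kaikobuild` reimplements, as a tested pipeline, the analysis stack of a
large-scale full-length cDNA (FL-cDNA) project in a lepidopteran genome:
5' EST clustering and FL-cDNA candidate selection, spliced
transcript-to-genome mapping with identity/coverage prefilters and
chimera screening, partitioning of all evidence into mapped gene loci
(set A), EST-only loci (set B) and unmappable sequence clusters (set C),
EST-based tissue-specificity calling, detection of tissue-specific
chromosomal gene clusters with a Fisher exact adjacency test, gonadal
density metrics on a Z-like sex chromosome, and ortholog-group summary
statistics. Because the underlying clone libraries of such projects are
not reproducible at desk scale, the package ships a deterministic
synthetic-data generator whose defaults define the package's reference
study conditions; every analytical claim the test suite makes is a
parameter-recovery statement against that generator's ground truth.

# The synthetic genome and libraries

`simulateGenome()` plants `nGenes` (default 200) non-overlapping genes on
`nChromosomes` (default 4) chromosomes of `chromosomeLength` bp (default
1.2 Mb); chromosome 1 is named `chrZ` and is treated as the Z sex
chromosome. Distribution families are fixed and parameterized by their
means:

* exons per transcript: `1 + Poisson(mean - 1)`, default mean 4.8;
* exon length: shifted geometric, minimum 27 bp, mean 353 bp;
* intron length: shifted geometric, minimum 34 bp, mean 1904 bp — the
  long, heavy-tailed introns characteristic of a transposon-inflated
  genome;
* EST 5' truncation: shifted geometric with mean 20 bp (the empirical
  truncation profile of oligo-capped libraries is not published, so this
  is an exposed knob rather than an asserted truth);
* poly-A tail: 10 + Poisson(8).

Intergenic and intronic sequence is AT-rich (GC 0.38) with a configurable
fraction (default 0.35) overwritten by mutated copies (2% per-copy
divergence) of a small library of four fixed 200–500 bp transposon-like
motifs, so repeat-driven ambiguity exists but is controllable. Every
planted intron is given canonical GT...AG ends on the transcribed strand.
Strand is uniform per gene; mature transcripts are the concatenated exons
(no 5' cap chemistry is simulated, as nothing downstream consumes it).

Three deterministic guards make the planted structure the *unique*
optimal alignment, so "exact structure recovery" is well defined: no
GT/AG motifs at the ±2-shifted junction positions, no GT at the last two
bases of a donor-side exon (and no AG opening an acceptor-side exon), and
a non-A final transcript base plus a `CGCG` scar after the gene's 3' end
so a poly-A tail can never extend the terminal exon. These are generator
design choices, fixed before any test was run.

Tissue labels: each non-cluster gene is tissue-specific with probability
`tissueSpecificFraction` (default 0.3) over five tissues sampled by six
EST libraries (two testis libraries, pooled at the tissue level, matching
how stage-replicate libraries of one tissue are treated downstream). On
`chrZ` the conditional probability of the testis label is raised so that
the *density* of testis-specific genes on Z is `testisZEnrichment`
(default 1.6) times the genome-wide average; because genes are placed
uniformly per bp, the required conditional probability has the closed
form `q_Z = r p lA / (L - r lZ)`. A tissue-specific gene expresses
`1 - specificityLeak` (default 99.5%) of its transcripts in its own
tissue. The leak is deliberately small: with the strict ">90% of
identical ESTs from one tissue" call rule, a gene observed with ~10 ESTs
tolerates at most one stray EST, so leaks of a few percent would make the
planted labels themselves unrecoverable — the generator plants the
sharply specific expression the calling rule presumes.

Planted clusters (default: 12 ovary-specific genes within 100 kb on
chromosome 2 and 6 midgut-specific genes within 80 kb on chromosome 3)
are laid out as consecutive blocks; their intron means are shrunk
deterministically until the block fits its span. Half of each planted
cluster is one tandem-duplication family: copies share the founder's exon
structure and carry 2% per-copy exonic divergence, giving the
within-cluster duplication signal the summary statistics look for.

Chimeric clones (rate 0.05 of emitted FL-cDNAs, drawn binomially) fuse
the 5' half of one mature transcript to the 3' half of another. Partners
are constrained to different chromosomes or > 250 kb apart — beyond the
maximum intron the aligner may bridge — and to a mature-length ratio of
at most 3, so that neither half alone can reach the 0.9 joint-coverage
bound that defines a complete placement. Without these constraints a
"chimera" would be undetectable *by construction*, not by algorithm.

`simulateLocusCalls()` is a sequence-free companion that draws only locus
coordinates and tissue labels through the same label-assignment code. It
exists for statistical calibration (200 null replicates of the adjacency
test, density-ratio recovery at ~200 testis genes) where sequence
simulation would add minutes and nothing else.

# EST clustering

Two 5' ESTs are linked when their best local alignment (+1 match, −1
mismatch, −2 per gap position; `N` matches nothing) contains a window of
≥ 100 aligned columns with strictly more than 95% matching columns.
Contigs are the connected components of the linkage graph — single
linkage, matching the assembly semantics of pooling clones that read the
same transcript — with a shift-invariant k-mer prefilter (12-mers ending
`AC`, so truncated copies sample identical k-mers) limiting which pairs
are examined; below 61 records all pairs are examined. Each candidate
pair is first checked ungapped at the modal shift of its shared k-mers
— an ungapped overlap that passes the window rule is itself a valid
local alignment, so a pass decides linkage immediately — and only pairs
the fast path cannot confirm go to the gapped aligner. Member 5' positions
are propagated along linkage edges and the most upstream member is the
FL-cDNA candidate, ties broken to the lexicographically smallest clone
id. Whether the original identity rule was gapped is unstated; gapped
comparison was chosen and the rule's parameters are exposed in
`IdentityRule()`. Reverse-complement linkage is not attempted: 5' ESTs
from oriented libraries share strand by construction.

# Spliced alignment

Mapping follows the classical two-stage design: a fast similarity search
narrows each transcript to candidate genomic windows, then an
est2genome-style dynamic program aligns within the window.

*Prefilter.* Exact 16-mer seeds sampled every 40 bp along the transcript
(both orientations) are matched against the genome; hits on one
chromosome and orientation chain into a window when their genomic gap is
≤ `maxIntron` (120 kb, motivated by the largest observed introns). Seeds
with more than 50 genomic hits are discarded as repeat-derived. A window
side whose terminal seed hit gets ~200 bp of slack; a side with unseeded
transcript sequence gets the full `windowPad` (15 kb), because a missed
terminal exon may sit beyond a long intron. The pad is a deliberate
departure from padding by the full maximum intron: at these window sizes
the dynamic-programming matrix stays in the tens of megabytes, and a
terminal intron beyond 15 kb (probability ≈ e^(−15000/1870) under the
intron model) is the accepted residual risk.

*Dynamic program.* A three-state local alignment: match/mismatch (+2/−3)
with affine short gaps (−6 open, −2 extend), plus an intron state that
jumps the genome at a fixed penalty −40, reduced by +15 when the skipped
segment is flanked by GT...AG — a bonus, not a requirement, so
non-canonical introns remain representable. The intron penalty is
deliberately steep: a net canonical intron cost of −25 means a spurious
intron only pays for itself beyond ~13 matched bases, which chance
matching essentially never provides; with milder penalties the local
aligner demonstrably chases 3–10 bp chance matches through fake introns,
corrupting terminal exon boundaries and hiding chimeras. For the same
reason terminal alignment blocks shorter than a 16 bp anchor are trimmed
after traceback, and trailing pure-A runs (≥ 5 nt) are soft-masked to
`N` before alignment — the poly-A tail must soft-clip, not seed a
downstream "intron". Minus-strand placements align the transcript as-is
against the reverse-complemented window, so the GT–AG bonus applies in
the transcribed frame. Local semantics floor scores at zero; the intron
state enforces the 30 bp minimum intron via a delayed opening buffer.
Scores are kept in a full int16 matrix with a one-byte traceback code per
cell (three bytes per cell total); gap runs and intron openings are
re-derived from the stored match scores during traceback.

*Status assignment and chimeras.* Identity is matches over aligned exon
columns; coverage is aligned transcript length over total length. A
placement is *complete* when segments on one chromosome and strand,
spanning ≤ 100 kb (`chimeraWindow`), jointly cover ≥ 0.9 of the clone
(`chimeraCoverage`). A clone with no complete placement whose
identity-passing segments jointly reach 0.9 only across incompatible
loci is `chimeric`; otherwise the 95% identity and 0.5 coverage
prefilters decide `mapped` versus `unmapped_low_homology` /
`unmapped_low_coverage`. The separate 0.9 threshold operationalizes
"perfect alignment within 100 kb": the published criterion cannot mean
the ordinary 0.5 coverage bound, since one half of any 5'+3' fusion
always carries ≥ 50% of the clone and chimera detection would be
vacuous. Transcripts with multiple equally scoring loci keep the forward
strand, then the first window in (chromosome, start) order.

# Gene build

Mapped FL-cDNA, public mRNA and predicted-model evidence merges into
class-A loci by transitive closure of same-strand exon overlap (≥ 1 bp;
exon rather than span overlap avoids fusing nested genes). Mapped ESTs
overlapping a class-A locus attach to it; the remainder group into
class-B loci by the same closure, ids prefixed `e`. Unmapped transcripts
cluster into coordinate-free class-C loci using the EST linkage rule (a
stand-in for sequence-cluster tools of the CLOBB family, which group by
the same pairwise-identity principle). Chimeric clones are excluded from
locus building but stay in the assignment table, so the partition
property — every transcript in exactly one of A/B/C/excluded — is
checkable by counting. Isoform counts per A locus are distinct exon-chain
patterns among FL-cDNA members. The simulator emits predicted models as
the true structures of a 70% subset of genes; predictor misannotation is
not emulated because no in-scope statistic consumes it.

ORF detection scans the three forward frames (FL-cDNA clones are
oriented) for the longest ATG-initiated, stop-terminated frame and
reports it at ≥ 31 encoded amino acids, implementing "longer than 30".
Poly-A detection asks whether the final 15 nt contain a run of ≥ 10 A
with at most one interruption. Exon/intron statistics (totals,
mean/median exon count, max/mean/median/min exon and intron lengths)
read the exon blocks of mapped structures; single-exon transcripts
contribute no intron.

# Expression and tissue specificity

Per-locus profiles count the assigned ESTs per tissue, pooling libraries
with the same tissue label. A locus is tissue-specific with strictly more
than 3 identical ESTs in total and strictly more than 90% from one
tissue; both strict inequalities follow from reading "more than three
copies" and "fewer than 10% from other tissues" literally, and both are
exposed as parameters. The rule is intentionally not scale-invariant
below the copy threshold (a 2:0 profile is uncalled, a 6:0 profile is
called); the documentation states this rather than hiding it. Whether the
original 90% rule was applied per library or per tissue is unstated;
per tissue was chosen because the downstream cluster table is organized
by tissue.

# Cluster analysis

Same-tissue loci on one chromosome chain into a cluster when the gap
from the end of one interval to the start of the next is ≤ 100 kb —
gaps, not midpoints, so the rule is well defined for long genes and
matches the chromatin-loop framing that motivates the threshold. The
summary table reports, per tissue and in total: specific genes, clustered
genes, integer-percent clustered fraction, cluster count, and the
fraction of clustered genes that are duplicated. Duplication linkage
defaults to ≥ 40% protein identity over ≥ 50% of the shorter protein
when both members have ORFs, else ≥ 70% nucleotide identity over ≥ 50%
of the shorter sequence (the source states no rule; these are
conventional homology thresholds).

The adjacency test tabulates, over genomically adjacent locus pairs,
first-locus specificity against second-locus specificity and applies the
exact two-sided Fisher test, computed from the hypergeometric density
with no lower floor on p. The published 2×2 construction is unstated, so
it is configurable: the default asks whether the neighbour is specific
for *any* tissue in both rows, which keeps the two rows' null match rates
equal and the test calibrated (type-I error ≈ 3–5% at α = 0.05 in null
simulations). The same-tissue variant (`matchMode = "same"`) sharpens the
biological question but compares a 1/n-tissue match rate against an
any-tissue rate, which is not a calibrated independence test; it is
retained for exploration. Chromosome density ratios are per-length:
(specific genes on the chromosome / its length) over (genome-wide
specific genes / genome length) — counts per Mb, the more defensible of
the two readings of a density ratio.

# Comparative summaries

Ortholog-group tables (`group_id`, `species_id`, `gene_id`; a gene in at
most one group) are categorized from their species sets: species-specific
(one species), Lepidoptera-specific (≥ 2 species, all lepidopteran),
insect-common (all insect-set species present; `1:1` when single-copy
everywhere, else `N:N`), otherwise `other`. Species sets come from
arguments, never hard-coding, so three-species synthetic universes work
unchanged. Per-species summaries report group counts, gene counts and
genes-per-group ratios (rounded to 2 decimals, the printed convention)
plus ratios of species-specific group counts against a reference
species. Pearson correlation (with the t-distribution p-value on n − 2
df) is provided for genome-size regressions; inputs arrive as a small
table, since re-deriving per-species annotation statistics is out of
scope.

# Problem sizes and what the tests show

The reference conditions are one 4.8 Mb genome, 200 genes, ~2000 ESTs,
~210 FL-cDNA clones (including ~10 chimeras) and 20 mRNA records; a full
pipeline run takes a few minutes on one core and is computed once per
test session. Calibration runs use the sequence-free locus simulator
(200 replicates for test size; 820 loci for density-ratio recovery) and
a 500-gene genome for distribution-mean recovery. Against these
conditions the suite verifies: byte-level determinism; exact
exon-structure recovery for error-free clones; ≥ 95% recall of planted
chimeras and of planted tissue-specific genes with ≥ 8 ESTs (≤ 1% false
calls on broad genes); the A/B/C partition accounting; equality of the
Fisher test with full enumeration up to N = 40; adjacency-test size
≤ 0.075; and recovery of the configured intron mean (±10%) and planted Z
density ratio (±20%).

Passing these tests shows the pipeline recovers what this generator
plants. Real FL-cDNA data differ in ways the generator does not emulate:
base-call quality structure and vector contamination (assumed trimmed
upstream), genome assembly gaps and collapsed paralog arrays, alternative
splicing and antisense transcription, library normalization biases, and
intron length distributions with more mass at both extremes. Results on
real data therefore depend on upstream cleaning in ways these tests
cannot certify.

# Numerical and degenerate-input choices

Coordinates are 1-based inclusive GRanges throughout — the Bioconductor
frame — and GFF3 is emitted directly in it; no 0-based frame exists in
the package. Alignment ties prefer the forward strand, then the first
locus in (chromosome, position) order; contig representatives and locus
ordering tie-break on lexicographic ids; component labels are canonical
in first-appearance order of the smallest member id, making every
clustering order-invariant. Degenerate inputs are defined rather than
accidental: empty EST sets cluster to empty tables; a 2×2 table with any
zero margin has p = 1; zero-variance vectors and tissues with zero
specific genes are errors or `NA` ("—") as documented; transcripts
shorter than a seed are unmapped with a warning; models outside the
assembly are rejected with a warning; placement-infeasible simulation
configurations fail naming the offending gene.
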