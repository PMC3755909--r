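#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges CharacterList
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end strand width
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement writeXStringSet
#'   readDNAStringSet subseq pairwiseAlignment translate
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels
#' @importFrom stats rbinom rgeom rmultinom rpois runif setNames dhyper cor.test
#' @importFrom utils write.table read.delim head tail
#' @useDynLib kaikobuild, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Simulation configuration
#'
#' Parameters of the synthetic genome/transcriptome generator. The generator
#' emulates the statistical structure of a lepidopteran FL-cDNA project:
#' a small multi-chromosome genome whose first chromosome is "Z-like"
#' (enriched for testis-specific genes), gene structures with
#' transposon-inflated introns, tissue-biased EST libraries, 5'-truncated
#' error-bearing ESTs, poly-A-tailed FL-cDNA clones and a small fraction of
#' chimeric clones.
#'
#' Distribution families are fixed (documented in the package vignette) and
#' parameterized by their means: exon count per transcript is
#' \code{1 + Poisson(exonCountMean - 1)}; exon and intron lengths and the
#' EST 5' truncation offset are shifted geometric (minimum + geometric with
#' the configured mean); the poly-A tail is \code{polyaMin +
#' Poisson(polyaMean - polyaMin)}.
#'
#' @slot seed integer; every random choice of the generator derives from it.
#' @slot nChromosomes integer; chromosome 1 is named \code{chrZ}.
#' @slot chromosomeLength integer bp per chromosome.
#' @slot nGenes integer number of planted genes.
#' @slot exonCountMean,exonLengthMean,exonLengthMin,intronLengthMean,intronLengthMin
#'   numeric; structure distribution parameters (defaults 4.8, 353, 27,
#'   1904, 34, mirroring the empirical exon/intron statistics the package
#'   reproduces).
#' @slot teFraction proportion of intergenic/intronic sequence occupied by
#'   repeated transposon-like motifs.
#' @slot tissues character vector of tissue names.
#' @slot libraries data.frame with columns \code{library}, \code{tissue},
#'   \code{n_ests}: the EST library manifest.
#' @slot tissueSpecificFraction proportion of (non-cluster) genes planted as
#'   tissue-specific.
#' @slot specificityLeak proportion of a tissue-specific gene's expression
#'   that leaks into other tissues.
#' @slot clusterPlantSpec data.frame with columns \code{tissue},
#'   \code{chromosome}, \code{span}, \code{n_genes}: planted tissue-specific
#'   gene clusters.
#' @slot clusterDupFraction proportion of each planted cluster's genes that
#'   belong to one tandem-duplication family.
#' @slot testisZEnrichment target ratio of testis-specific gene density on
#'   the Z-like chromosome to the genome-wide average density.
#' @slot estErrorRate per-base substitution probability of ESTs.
#' @slot estTruncationMean mean 5' truncation offset (bp) of ESTs.
#' @slot estReadLength maximum EST read length (bp).
#' @slot chimeraRate proportion of emitted FL-cDNAs that are 5'+3' fusions
#'   of two transcripts.
#' @slot polyaMin,polyaMean integer; appended A-tail length distribution.
#' @slot mrnaFraction proportion of genes also represented by a public-mRNA
#'   style record.
#' @slot modelFraction proportion of genes covered by a predicted gene model
#'   in the emitted annotation.
#' @export
setClass("SimulationConfig", representation(
  seed = "integer",
  nChromosomes = "integer",
  chromosomeLength = "integer",
  nGenes = "integer",
  exonCountMean = "numeric",
  exonLengthMean = "numeric",
  exonLengthMin = "integer",
  intronLengthMean = "numeric",
  intronLengthMin = "integer",
  teFraction = "numeric",
  tissues = "character",
  libraries = "data.frame",
  tissueSpecificFraction = "numeric",
  specificityLeak = "numeric",
  clusterPlantSpec = "data.frame",
  clusterDupFraction = "numeric",
  testisZEnrichment = "numeric",
  estErrorRate = "numeric",
  estTruncationMean = "numeric",
  estReadLength = "integer",
  chimeraRate = "numeric",
  polyaMin = "integer",
  polyaMean = "numeric",
  mrnaFraction = "numeric",
  modelFraction = "numeric"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  prop <- function(x, nm) {
    if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
      msg <<- c(msg, paste0(nm, " must be a single proportion in [0, 1]"))
  }
  prop(object@teFraction, "teFraction")
  prop(object@tissueSpecificFraction, "tissueSpecificFraction")
  prop(object@specificityLeak, "specificityLeak")
  prop(object@chimeraRate, "chimeraRate")
  prop(object@estErrorRate, "estErrorRate")
  prop(object@mrnaFraction, "mrnaFraction")
  prop(object@modelFraction, "modelFraction")
  prop(object@clusterDupFraction, "clusterDupFraction")
  if (object@nChromosomes < 1L) msg <- c(msg, "need at least one chromosome")
  if (object@intronLengthMin < 1L) msg <- c(msg, "intronLengthMin must be >= 1")
  if (object@exonCountMean < 1) msg <- c(msg, "exonCountMean must be >= 1")
  if (object@testisZEnrichment <= 0) msg <- c(msg, "testisZEnrichment must be > 0")
  lib <- object@libraries
  if (nrow(lib) && !all(c("library", "tissue", "n_ests") %in% names(lib)))
    msg <- c(msg, "libraries needs columns library, tissue, n_ests")
  if (nrow(lib) && !all(lib$tissue %in% object@tissues))
    msg <- c(msg, paste0("library manifest names unknown tissue(s): ",
                         paste(setdiff(lib$tissue, object@tissues), collapse = ", ")))
  cps <- object@clusterPlantSpec
  if (nrow(cps)) {
    if (!all(c("tissue", "chromosome", "span", "n_genes") %in% names(cps)))
      msg <- c(msg, "clusterPlantSpec needs columns tissue, chromosome, span, n_genes")
    else {
      if (!all(cps$tissue %in% object@tissues))
        msg <- c(msg, "clusterPlantSpec names unknown tissue(s)")
      if (any(cps$span > object@chromosomeLength))
        msg <- c(msg, "planted cluster span exceeds chromosome length")
      if (any(cps$chromosome < 1L | cps$chromosome > object@nChromosomes))
        msg <- c(msg, "planted cluster chromosome index out of range")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated genome
#'
#' Per-gene truth emitted by [simulateGenome()]: planted coordinates, exon
#' structures, tissue labels, cluster and duplication-family memberships,
#' and the mature (spliced, untailed) transcript of every gene.
#' Per-transcript truth (source gene, library, chimera flag) travels as
#' metadata columns of the [TranscriptSet] produced by
#' [simulateLibraries()].
#'
#' @slot genes `GRanges`, one range per gene, with metadata columns
#'   `gene_id`, `tissue` (`"broad"` or a tissue name), `cluster_id`,
#'   `family_id`, `n_exons`.
#' @slot exons `GRangesList` of planted exons, names = gene ids.
#' @slot matureSeq `DNAStringSet` of mature transcripts, names = gene ids.
#' @export
setClass("GroundTruth", representation(
  genes = "GRanges",
  exons = "GRangesList",
  matureSeq = "DNAStringSet"
))

setValidity("GroundTruth", function(object) {
  ids <- object@genes$gene_id
  if (is.null(ids)) return("genes must carry a gene_id column")
  if (length(ids) == 0L && length(object@exons) == 0L &&
      length(object@matureSeq) == 0L) return(TRUE)
  if (!identical(names(object@exons), ids)) return("exons names must match gene ids")
  if (!identical(names(object@matureSeq), ids)) return("matureSeq names must match gene ids")
  TRUE
})

#' A simulated genome with its ground truth
#'
#' Container returned by [simulateGenome()].
#'
#' @slot genome named `DNAStringSet` of chromosome sequences.
#' @slot truth a [GroundTruth-class].
#' @slot config the [SimulationConfig-class] used.
#' @export
setClass("GenomeSimulation", representation(
  genome = "DNAStringSet",
  truth = "GroundTruth",
  config = "SimulationConfig"
))

#' A set of transcript records
#'
#' A `DNAStringSet` whose metadata columns carry the provenance of each
#' record: `clone_id`, `library` (NA for public-mRNA records), `tissue`,
#' `type` (one of `"EST"`, `"FLC"`, `"mRNA"`), and, for simulated data, the
#' truth columns `source_gene`, `source_gene2` (second parent of a chimera)
#' and `is_chimera`.
#'
#' @export
setClass("TranscriptSet", contains = "DNAStringSet")

setValidity("TranscriptSet", function(object) {
  mc <- mcols(object)
  need <- c("clone_id", "library", "type")
  if (!all(need %in% names(mc)))
    return(paste("metadata columns required:", paste(need, collapse = ", ")))
  if (length(object) && !all(mc$type %in% c("EST", "FLC", "mRNA")))
    return("type must be EST, FLC or mRNA")
  TRUE
})

#' Identity rule for EST linkage
#'
#' Two 5' ESTs are linked (treated as reads of the same transcript) when
#' some local alignment contains a window of at least `minSpan` aligned
#' columns with strictly more than `minIdentity` matching columns.
#'
#' @slot minIdentity proportion, default 0.95 (strictly exceeded).
#' @slot minSpan integer bp, default 100.
#' @export
setClass("IdentityRule", representation(minIdentity = "numeric", minSpan = "integer"))

setValidity("IdentityRule", function(object) {
  if (object@minIdentity <= 0 || object@minIdentity > 1)
    return("minIdentity must be in (0, 1]")
  if (object@minSpan < 1L) return("minSpan must be >= 1")
  TRUE
})

#' @describeIn IdentityRule-class Constructor.
#' @param minIdentity,minSpan see slots.
#' @export
IdentityRule <- function(minIdentity = 0.95, minSpan = 100L) {
  new("IdentityRule", minIdentity = as.numeric(minIdentity),
      minSpan = as.integer(minSpan))
}

#' Mapping thresholds for transcript-to-genome alignment
#'
#' @slot minIdentity minimum percent identity (proportion) for a mapped
#'   alignment, default 0.95.
#' @slot minCoverage minimum alignment coverage (aligned transcript length
#'   over total length), default 0.5.
#' @slot minIntron,maxIntron intron length bounds (bp), defaults 30 and
#'   120000.
#' @slot chimeraWindow genomic span (bp) within which a clone must place to
#'   be considered non-chimeric, default 100000.
#' @slot chimeraCoverage joint coverage a placement must reach to count as
#'   a complete ("perfect") placement in chimera classification, default 0.9.
#' @slot seedK k-mer length of the alignment prefilter, default 16.
#' @slot seedStride sampling stride (bp) of prefilter seeds, default 40.
#' @slot windowPad padding (bp) added around chained seed spans to form the
#'   dynamic-programming window, default 15000.
#' @slot match,mismatch,gapOpen,gapExtend,intronPenalty,spliceBonus integer
#'   alignment scores (defaults +2, -3, -6, -2, -40, +15; the splice bonus
#'   rewards GT...AG introns without requiring them).
#' @export
setClass("MappingThresholds", representation(
  minIdentity = "numeric", minCoverage = "numeric",
  minIntron = "integer", maxIntron = "integer",
  chimeraWindow = "integer", chimeraCoverage = "numeric",
  seedK = "integer", seedStride = "integer", windowPad = "integer",
  match = "integer", mismatch = "integer", gapOpen = "integer",
  gapExtend = "integer", intronPenalty = "integer", spliceBonus = "integer"
))

setValidity("MappingThresholds", function(object) {
  msg <- character()
  if (object@minIdentity <= 0 || object@minIdentity > 1)
    msg <- c(msg, "minIdentity must be in (0, 1]")
  if (object@minCoverage <= 0 || object@minCoverage > 1)
    msg <- c(msg, "minCoverage must be in (0, 1]")
  if (object@minIntron >= object@maxIntron)
    msg <- c(msg, "minIntron must be < maxIntron")
  if (object@seedK < 8L) msg <- c(msg, "seedK must be >= 8")
  if (length(msg)) msg else TRUE
})

#' @describeIn MappingThresholds-class Constructor.
#' @param minIdentity,minCoverage,minIntron,maxIntron,chimeraWindow,chimeraCoverage,seedK,seedStride,windowPad,match,mismatch,gapOpen,gapExtend,intronPenalty,spliceBonus
#'   see slots.
#' @export
MappingThresholds <- function(minIdentity = 0.95, minCoverage = 0.5,
                              minIntron = 30L, maxIntron = 120000L,
                              chimeraWindow = 100000L, chimeraCoverage = 0.9,
                              seedK = 16L, seedStride = 40L, windowPad = 15000L,
                              match = 2L, mismatch = -3L, gapOpen = -6L,
                              gapExtend = -2L, intronPenalty = -40L,
                              spliceBonus = 15L) {
  new("MappingThresholds",
      minIdentity = as.numeric(minIdentity), minCoverage = as.numeric(minCoverage),
      minIntron = as.integer(minIntron), maxIntron = as.integer(maxIntron),
      chimeraWindow = as.integer(chimeraWindow),
      chimeraCoverage = as.numeric(chimeraCoverage),
      seedK = as.integer(seedK), seedStride = as.integer(seedStride),
      windowPad = as.integer(windowPad),
      match = as.integer(match), mismatch = as.integer(mismatch),
      gapOpen = as.integer(gapOpen), gapExtend = as.integer(gapExtend),
      intronPenalty = as.integer(intronPenalty),
      spliceBonus = as.integer(spliceBonus))
}

#' Spliced alignments of transcripts on a genome
#'
#' One row of `info` per input transcript, whether or not it mapped.
#' `status` is one of `mapped`, `unmapped_low_coverage`,
#' `unmapped_low_homology`, `chimeric`. Exon blocks of the chosen placement
#' (and, for chimeras, of all contributing placements) are in `blocks`, a
#' `GRangesList` indexed by transcript id; block metadata columns
#' `tstart`/`tend` give the aligned transcript interval of each block.
#'
#' @slot info `DataFrame` with columns `transcript_id`, `chromosome`,
#'   `strand`, `identity`, `coverage`, `n_blocks`, `score`, `status`.
#' @slot blocks `GRangesList` of exon blocks, names = transcript ids.
#' @export
setClass("SplicedAlignmentSet", representation(
  info = "DataFrame", blocks = "GRangesList"
))

setValidity("SplicedAlignmentSet", function(object) {
  need <- c("transcript_id", "chromosome", "strand", "identity", "coverage",
            "n_blocks", "score", "status")
  if (!all(need %in% names(object@info)))
    return(paste("info needs columns:", paste(need, collapse = ", ")))
  ok <- c("mapped", "unmapped_low_coverage", "unmapped_low_homology", "chimeric")
  if (nrow(object@info) && !all(object@info$status %in% ok))
    return("invalid status value")
  cov <- object@info$coverage
  idn <- object@info$identity
  if (any(cov > 1 + 1e-9, na.rm = TRUE) || any(idn > 1 + 1e-9, na.rm = TRUE))
    return("identity and coverage must not exceed 1")
  TRUE
})

#' An evidence-partitioned gene locus set
#'
#' The result of the gene build: loci of class A (FL-cDNA/mRNA/model
#' supported, mapped), B (EST-only, mapped; ids prefixed `"e"`) and C
#' (unmappable sequence clusters; ids prefixed `"c"`, no coordinates), plus
#' an assignment table placing every input transcript in exactly one of
#' {A locus, B locus, C locus, excluded-chimeric}.
#'
#' @slot loci `DataFrame`: `locus_id`, `class` (`"A"`, `"B"`, `"C"`),
#'   `chromosome`, `strand`, `start`, `end` (NA for class C), `n_members`,
#'   `isoform_count`.
#' @slot members `CharacterList` of member transcript/model ids per locus.
#' @slot exons `GRangesList` of the exon union per locus (empty for C).
#' @slot assignment `DataFrame`: `id`, `kind` (transcript type or
#'   `"model"`), `locus_id` (NA for excluded), `class` (`"A"`, `"B"`,
#'   `"C"` or `"chimeric_excluded"`).
#' @export
setClass("GeneLocusSet", representation(
  loci = "DataFrame", members = "CharacterList",
  exons = "GRangesList", assignment = "DataFrame"
))

setValidity("GeneLocusSet", function(object) {
  lo <- object@loci
  if (!all(c("locus_id", "class", "chromosome", "strand", "start", "end",
             "n_members", "isoform_count") %in% names(lo)))
    return("loci is missing required columns")
  if (nrow(lo)) {
    ab <- lo$class %in% c("A", "B")
    if (any(ab & (is.na(lo$chromosome) | is.na(lo$strand))))
      return("class A/B loci must have chromosome and strand")
    if (any(!ab & lo$class == "C" & !is.na(lo$chromosome)))
      return("class C loci must not carry coordinates")
  }
  if (length(object@members) != nrow(lo))
    return("members must parallel loci")
  TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: seed", object@seed, "|", object@nGenes, "genes on",
      object@nChromosomes, "chromosomes x", object@chromosomeLength, "bp\n")
  cat("  exon count mean", object@exonCountMean,
      "| exon length mean", object@exonLengthMean,
      "| intron length mean", object@intronLengthMean, "\n")
  cat("  tissues:", paste(object@tissues, collapse = ", "), "\n")
  cat("  libraries:", nrow(object@libraries),
      "| planted clusters:", nrow(object@clusterPlantSpec),
      "| chimera rate:", object@chimeraRate, "\n")
})

setMethod("show", "GenomeSimulation", function(object) {
  cat("GenomeSimulation:", length(object@genome), "chromosomes (",
      sum(as.numeric(Biostrings::width(object@genome))), "bp ),",
      length(object@truth@genes), "planted genes\n")
})

setMethod("show", "TranscriptSet", function(object) {
  tab <- table(factor(mcols(object)$type, levels = c("EST", "FLC", "mRNA")))
  cat("TranscriptSet of", length(object), "records:",
      paste(paste0(names(tab), "=", as.integer(tab)), collapse = " "), "\n")
})

setMethod("show", "SplicedAlignmentSet", function(object) {
  tab <- table(object@info$status)
  cat("SplicedAlignmentSet of", nrow(object@info), "transcripts\n")
  for (nm in names(tab)) cat("  ", nm, ":", tab[[nm]], "\n")
})

setMethod("show", "GeneLocusSet", function(object) {
  tab <- table(object@loci$class)
  cat("GeneLocusSet:", nrow(object@loci), "loci (",
      paste(paste0("set ", names(tab), "=", as.integer(tab)), collapse = ", "),
      ")\n")
})

# ---- accessors ----

#' Accessors for package containers
#'
#' @param x an object of the corresponding class.
#' @return `alignmentInfo` and `lociTable` return a `DataFrame`;
#'   `exonBlocks` and `locusExons` a `GRangesList`; `locusMembers` a
#'   `CharacterList`; `locusAssignment` a `DataFrame`; `truthGenes` a
#'   `GRanges`; `truthExons` a `GRangesList`; `matureTranscripts` a
#'   `DNAStringSet`; `simConfig` a [SimulationConfig-class];
#'   `simGenome` a `DNAStringSet`; `simTruth` a [GroundTruth-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
alignmentInfo <- function(x) { stopifnot(is(x, "SplicedAlignmentSet")); x@info }

#' @rdname accessors
#' @export
exonBlocks <- function(x) { stopifnot(is(x, "SplicedAlignmentSet")); x@blocks }

#' @rdname accessors
#' @export
lociTable <- function(x) { stopifnot(is(x, "GeneLocusSet")); x@loci }

#' @rdname accessors
#' @export
locusMembers <- function(x) { stopifnot(is(x, "GeneLocusSet")); x@members }

#' @rdname accessors
#' @export
locusExons <- function(x) { stopifnot(is(x, "GeneLocusSet")); x@exons }

#' @rdname accessors
#' @export
locusAssignment <- function(x) { stopifnot(is(x, "GeneLocusSet")); x@assignment }

#' @rdname accessors
#' @export
truthGenes <- function(x) {
  if (is(x, "GenomeSimulation")) x <- x@truth
  stopifnot(is(x, "GroundTruth")); x@genes
}

#' @rdname accessors
#' @export
truthExons <- function(x) {
  if (is(x, "GenomeSimulation")) x <- x@truth
  stopifnot(is(x, "GroundTruth")); x@exons
}

#' @rdname accessors
#' @export
matureTranscripts <- function(x) {
  if (is(x, "GenomeSimulation")) x <- x@truth
  stopifnot(is(x, "GroundTruth")); x@matureSeq
}

#' @rdname accessors
#' @export
simConfig <- function(x) { stopifnot(is(x, "GenomeSimulation")); x@config }

#' @rdname accessors
#' @export
simGenome <- function(x) { stopifnot(is(x, "GenomeSimulation")); x@genome }

#' @rdname accessors
#' @export
simTruth <- function(x) { stopifnot(is(x, "GenomeSimulation")); x@truth }
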