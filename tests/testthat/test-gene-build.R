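# Gene-set partitioning, ORF/poly-A detection, exon/intron statistics.

grB <- function(chr, starts, ends, strand = "+")
  GenomicRanges::GRanges(chr, IRanges::IRanges(starts, ends), strand = strand,
                         tstart = starts - starts[1] + 1L,
                         tend = ends - starts[1] + 1L)

test_that("FL-cDNA matching a model forms one class-A locus with both members", {
  ev <- makeEvidence(
    blocks = list(FLC1 = grB("chr1", c(100L, 500L), c(200L, 700L))),
    statuses = "mapped", types = "FLC")
  models <- GenomicRanges::GRangesList(
    model_G1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100L, 500L),
                                                               c(200L, 700L)),
                                      strand = "+"))
  gs <- buildGeneSets(ev$aln, ev$transcripts, models)
  lo <- as.data.frame(lociTable(gs))
  expect_equal(nrow(lo), 1L)
  expect_equal(lo$class, "A")
  expect_setequal(locusMembers(gs)[[1]], c("FLC1", "model_G1"))
})

test_that("opposite-strand overlap does not merge loci", {
  ev <- makeEvidence(
    blocks = list(FLC1 = grB("chr1", 100L, 700L, "+"),
                  FLC2 = grB("chr1", 150L, 750L, "-")),
    statuses = c("mapped", "mapped"), types = c("FLC", "FLC"))
  gs <- buildGeneSets(ev$aln, ev$transcripts)
  expect_equal(nrow(lociTable(gs)), 2L)
})

test_that("alternative exon chains in one locus raise the isoform count", {
  ev <- makeEvidence(
    blocks = list(FLC1 = grB("chr1", c(100L, 500L, 900L), c(200L, 600L, 1000L)),
                  FLC2 = grB("chr1", c(100L, 500L, 1200L), c(200L, 600L, 1300L))),
    statuses = c("mapped", "mapped"), types = c("FLC", "FLC"))
  gs <- buildGeneSets(ev$aln, ev$transcripts)
  lo <- as.data.frame(lociTable(gs))
  expect_equal(nrow(lo), 1L)
  expect_equal(lo$isoform_count, 2L)
})

test_that("mapped ESTs attach to class A when overlapping, else form class B", {
  ev <- makeEvidence(
    blocks = list(FLC1 = grB("chr1", 100L, 700L),
                  EST1 = grB("chr1", 650L, 900L),
                  EST2 = grB("chr1", 5000L, 5400L),
                  EST3 = grB("chr1", 5300L, 5700L)),
    statuses = rep("mapped", 4), types = c("FLC", "EST", "EST", "EST"))
  gs <- buildGeneSets(ev$aln, ev$transcripts)
  lo <- as.data.frame(lociTable(gs))
  expect_equal(sort(lo$class), c("A", "B"))
  asg <- as.data.frame(locusAssignment(gs))
  expect_equal(asg$class[asg$id == "EST1"], "A")
  expect_equal(asg$class[asg$id == "EST2"], "B")
  expect_true(startsWith(lo$locus_id[lo$class == "B"], "e"))
  expect_setequal(locusMembers(gs)[[which(lo$class == "B")]],
                  c("EST2", "EST3"))
})

test_that("unmapped transcripts cluster into coordinate-free class-C loci", {
  set.seed(51)
  wseq <- rndDna(600) # a "W-chromosome" transcript absent from the assembly
  ev <- makeEvidence(
    blocks = list(FLC1 = grB("chr1", 100L, 700L),
                  ESTw1 = GenomicRanges::GRanges(),
                  ESTw2 = GenomicRanges::GRanges(),
                  ESTx = GenomicRanges::GRanges()),
    statuses = c("mapped", "unmapped_low_homology", "unmapped_low_homology",
                 "unmapped_low_coverage"),
    types = c("FLC", "EST", "EST", "EST"),
    seqs = c(FLC1 = rndDna(600), ESTw1 = substr(wseq, 1, 400),
             ESTw2 = substr(wseq, 150, 600), ESTx = rndDna(300)))
  gs <- buildGeneSets(ev$aln, ev$transcripts)
  lo <- as.data.frame(lociTable(gs))
  cRows <- lo[lo$class == "C", ]
  expect_equal(nrow(cRows), 2L)
  expect_true(all(is.na(cRows$chromosome)))
  expect_true(all(startsWith(cRows$locus_id, "c")))
  sizes <- sort(cRows$n_members)
  expect_equal(sizes, c(1L, 2L))
})

test_that("chimeric clones are excluded from loci but kept in the accounting", {
  ev <- makeEvidence(
    blocks = list(FLC1 = grB("chr1", 100L, 700L),
                  CHI1 = grB("chr1", 100L, 400L)),
    statuses = c("mapped", "chimeric"), types = c("FLC", "FLC"))
  gs <- buildGeneSets(ev$aln, ev$transcripts)
  asg <- as.data.frame(locusAssignment(gs))
  expect_equal(asg$class[asg$id == "CHI1"], "chimeric_excluded")
  expect_true(is.na(asg$locus_id[asg$id == "CHI1"]))
  expect_equal(nrow(lociTable(gs)), 1L)
})

test_that("every simulated transcript lands in exactly one partition class", {
  res <- smallRun()
  asg <- as.data.frame(locusAssignment(res$geneSets))
  md <- S4Vectors::mcols(res$transcripts)
  inputs <- c(md$clone_id, names(simulatedModels(res$sim)))
  expect_setequal(asg$id, inputs)
  expect_false(anyDuplicated(asg$id) > 0)
  expect_equal(sum(table(asg$class)), length(inputs))
})

test_that("with all genes expressed as FL-cDNAs, set A recovers every gene", {
  res <- smallRun()
  lo <- as.data.frame(lociTable(res$geneSets))
  expect_equal(sum(lo$class == "A"), simConfig(res$sim)@nGenes)
  expect_equal(sum(lo$class == "B"), 0L)
  expect_equal(sum(lo$class == "C"), 0L)
})

test_that("a gene expressed only as ESTs is recovered as one class-B locus", {
  res <- smallRun()
  md <- S4Vectors::mcols(res$transcripts)
  tg <- truthGenes(res$sim)
  estCount <- table(md$source_gene[md$type == "EST"])
  gid <- names(estCount)[which(estCount >= 3)][1]
  keep <- !(md$type %in% c("FLC", "mRNA") & md$source_gene == gid)
  mods <- simulatedModels(res$sim)
  mods <- mods[names(mods) != paste0("model_", gid)]
  sub <- res$transcripts[keep]
  alnInfo <- alignmentInfo(res$alignments)
  subAln <- new("SplicedAlignmentSet",
                info = alnInfo[alnInfo$transcript_id %in%
                                 S4Vectors::mcols(sub)$clone_id, ],
                blocks = exonBlocks(res$alignments)[
                  S4Vectors::mcols(sub)$clone_id])
  gs <- buildGeneSets(subAln, sub, mods)
  m2t <- matchLociToTruth(gs, res$sim)
  lo <- as.data.frame(lociTable(gs))
  bOfGene <- m2t$locus_id[m2t$gene_id == gid & !is.na(m2t$gene_id)]
  expect_length(bOfGene, 1L)
  expect_equal(lo$class[lo$locus_id == bOfGene], "B")
})

test_that("ORF detection obeys the 30-amino-acid boundary", {
  set.seed(52)
  body30 <- paste(rep("GCT", 30), collapse = "")
  orf31 <- paste0("CCCC", "ATG", body30, "TAA", "CCCC")
  got <- detectOrf(orf31)
  expect_equal(got$aa_length, 31L)
  expect_equal(got$start, 5L)
  # one codon shorter fails the default threshold
  orf30 <- paste0("CCCC", "ATG", paste(rep("GCT", 29), collapse = ""),
                  "TAA", "CCCC")
  expect_null(detectOrf(orf30))
  expect_equal(detectOrf(orf30, minOrfAa = 30L)$aa_length, 30L)
  # no start codon anywhere
  expect_null(detectOrf(strrep("C", 300)))
})

test_that("ORF detection equals a brute-force scan on random sequence", {
  set.seed(53)
  for (rep in 1:8) {
    s <- rndDna(2000)
    got <- detectOrf(s)
    want <- oracleOrfScan(s)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$aa_length, want)
    }
  }
})

test_that("poly-A detection follows the terminal-run rule", {
  expect_true(detectPolya(paste0(rndDna(50), strrep("A", 12))))
  expect_true(detectPolya(paste0(rndDna(50), "AAAAAAGAAAAA"))) # one break
  expect_false(detectPolya(paste0(rndDna(50), "AAAAAGAAAAGA"))) # two breaks
  expect_false(detectPolya(rndDna(8)))
  expect_false(detectPolya(paste0(strrep("A", 30), rndDna(20))))
})

test_that("poly-A recall on simulated FL-cDNA clones is essentially complete", {
  res <- smallRun()
  md <- S4Vectors::mcols(res$transcripts)
  flc <- res$transcripts[md$type == "FLC"]
  feat <- transcriptFeatures(flc)
  expect_gte(mean(feat$has_polya), 0.99)
})

test_that("exon/intron statistics compute the documented quantities", {
  one <- GenomicRanges::GRangesList(
    t1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1L, 601L),
                                                         c(100L, 800L))))
  st <- exonIntronStats(one)
  expect_equal(st$total_exons, 2L)
  expect_equal(st$exons_per_transcript$mean, 2)
  expect_equal(st$exon_length$mean, 150)
  expect_equal(st$intron_length$mean, 500)
  mono <- GenomicRanges::GRangesList(
    t1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(1L, 500L)))
  st2 <- exonIntronStats(mono)
  expect_true(is.na(st2$intron_length$mean))
  expect_true(st2$exon_length$min <= st2$exon_length$median &&
                st2$exon_length$median <= st2$exon_length$max)
})

test_that("structure statistics are invariant to transcript order", {
  res <- smallRun()
  info <- alignmentInfo(res$alignments)
  ids <- info$transcript_id[info$status == "mapped"]
  s1 <- exonIntronStats(exonBlocks(res$alignments)[ids])
  s2 <- exonIntronStats(exonBlocks(res$alignments)[rev(ids)])
  expect_equal(s1, s2)
})
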