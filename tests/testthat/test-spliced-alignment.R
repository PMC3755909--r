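# Seed prefilter, splice-aware DP, chimera classification.

test_that("the DP score matches an independent plain-R implementation", {
  set.seed(41)
  for (rep in 1:12) {
    m <- sample(10:30, 1)
    n <- sample(40:100, 1)
    t <- rndDna(m)
    g <- if (rep %% 3 == 0) {
      # embed the transcript with a short intron so the intron state fires
      cut <- sample(4:(m - 4), 1)
      paste0(rndDna(10), substr(t, 1, cut), "GT", rndDna(31), "AG",
             substr(t, cut + 1, m), rndDna(10))
    } else rndDna(n)
    got <- kaikobuild:::.spliceAlignCpp(t, g, 2L, -3L, -6L, -2L, -40L, 15L,
                                        10L, 1L)$score
    want <- oracleSpliceScore(t, g, minIntron = 10)
    expect_equal(got, want)
  }
})

test_that("prefilter finds the locus of an embedded transcript and nothing for foreign sequence", {
  set.seed(42)
  chr <- rndDna(60000)
  tpos <- 20001L
  t <- substr(chr, tpos, tpos + 799L)
  gen <- Biostrings::DNAStringSet(c(chr1 = chr))
  w <- seedPrefilter(c(tx = t), gen)
  wp <- w[w$strand == "+", ]
  expect_gte(nrow(wp), 1L)
  expect_true(any(wp$wstart <= tpos & wp$wend >= tpos + 799L))
  w2 <- seedPrefilter(c(foreign = rndDna(800)), gen)
  expect_equal(nrow(w2), 0L)
})

test_that("a spliced transcript's window spans both exons across the intron", {
  set.seed(43)
  ex1 <- rndDna(300); ex2 <- rndDna(300)
  intr <- paste0("GT", rndDna(4996), "AG")
  chr <- paste0(rndDna(5000), ex1, intr, ex2, rndDna(5000))
  gen <- Biostrings::DNAStringSet(c(chr1 = chr))
  t <- paste0(ex1, ex2)
  w <- seedPrefilter(c(tx = t), gen)
  wp <- w[w$strand == "+", ]
  expect_equal(nrow(wp), 1L)
  expect_lte(wp$wstart, 5001L)
  expect_gte(wp$wend, 5000L + 300L + 5000L + 300L)
  al <- spliceAlign(t, substr(chr, wp$wstart, wp$wend), wp$wstart, "+")
  expect_equal(al$identity, 1)
  expect_equal(al$coverage, 1)
  expect_equal(al$blocks$gstart, c(5001L, 10301L))
  expect_equal(al$blocks$gend, c(5300L, 10600L))
})

test_that("identity below 95% is filtered as low homology", {
  set.seed(44)
  sim <- simulateGenome(smallConfig(seed = 44, nGenes = 4L))
  mat <- as.character(matureTranscripts(sim))[1]
  x <- strsplit(mat, "")[[1]]
  p <- sample(length(x), ceiling(0.06 * length(x)))
  for (q in p) x[q] <- setdiff(c("A", "C", "G", "T"), x[q])[1]
  bad <- setNames(paste(x, collapse = ""), "mut")
  aln <- mapTranscripts(bad, simGenome(sim))
  expect_equal(alignmentInfo(aln)$status, "unmapped_low_homology")
})

test_that("coverage below 50% is filtered as low coverage", {
  set.seed(45)
  sim <- simulateGenome(smallConfig(seed = 45, nGenes = 4L))
  mat <- as.character(matureTranscripts(sim))
  long <- mat[which.max(nchar(mat))]
  frag <- substr(long, 1, floor(0.4 * nchar(long)))
  # splice a 60% foreign tail so total length restores but only 40% aligns
  probe <- setNames(paste0(frag, rndDna(nchar(long) - nchar(frag))), "halfmap")
  aln <- mapTranscripts(probe, simGenome(sim))
  expect_equal(alignmentInfo(aln)$status, "unmapped_low_coverage")
  expect_lt(alignmentInfo(aln)$coverage, 0.5)
})

test_that("chimera classification separates co-placeable from split placements", {
  thr <- MappingThresholds()
  near <- data.frame(chromosome = "chr2", strand = "+",
                     gstart = c(100000L, 135000L), gend = c(101000L, 140000L),
                     tstart = c(1L, 1000L), tend = c(1040L, 2000L))
  expect_equal(classifyChimera(near, 2000L, thr), "mapped")
  split <- data.frame(chromosome = c("chr2", "chr5"), strand = "+",
                      gstart = c(100000L, 500000L), gend = c(101000L, 501000L),
                      tstart = c(1L, 1000L), tend = c(1040L, 2000L))
  expect_equal(classifyChimera(split, 2000L, thr), "chimeric")
  onlyHalf <- split[1, ]
  expect_equal(classifyChimera(onlyHalf, 2000L, thr), "mapped") # 0.52 coverage
  short <- data.frame(chromosome = "chr2", strand = "+", gstart = 1L,
                      gend = 700L, tstart = 1L, tend = 700L)
  expect_equal(classifyChimera(short, 2000L, thr), "unmapped_low_coverage")
  expect_equal(classifyChimera(split[0, ], 2000L, thr),
               "unmapped_low_coverage")
})

test_that("error-free evidence maps with perfect structure on a small genome", {
  res <- smallRun()
  md <- S4Vectors::mcols(res$transcripts)
  info <- as.data.frame(alignmentInfo(res$alignments))
  expect_true(all(info$identity <= 1 + 1e-12, na.rm = TRUE))
  expect_true(all(info$coverage <= 1 + 1e-12, na.rm = TRUE))
  mapped <- info[info$status == "mapped", ]
  thr <- MappingThresholds()
  expect_true(all(mapped$identity >= thr@minIdentity))
  expect_true(all(mapped$coverage >= thr@minCoverage |
                    mapped$n_blocks > 0)) # multi-window joint placements
  flc <- md$clone_id[md$type == "FLC" & !md$is_chimera]
  for (id in flc) {
    g <- md$source_gene[md$clone_id == id]
    b <- sort(exonBlocks(res$alignments)[[id]])
    te <- sort(truthExons(res$sim)[[g]])
    expect_equal(GenomicRanges::start(b), GenomicRanges::start(te), label = id)
    expect_equal(GenomicRanges::end(b), GenomicRanges::end(te), label = id)
    expect_equal(as.character(GenomicRanges::strand(b))[1],
                 as.character(GenomicRanges::strand(te))[1])
  }
  chim <- md$clone_id[md$is_chimera]
  if (length(chim))
    expect_true(all(info$status[match(chim, info$transcript_id)] == "chimeric"))
})

test_that("transcripts shorter than a seed are left unmapped with a warning", {
  sim <- simulateGenome(smallConfig(seed = 46, nGenes = 2L))
  expect_warning(aln <- mapTranscripts(c(tiny = "ACGTACGT"), simGenome(sim)),
                 "shorter than seedK")
  expect_equal(alignmentInfo(aln)$status, "unmapped_low_homology")
})
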