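# The generator's contracts: determinism, planted structure, configured
# distribution means, library provenance, chimera accounting.

test_that("an empty configuration yields a genome with no genes", {
  cfg <- smallConfig(seed = 1, nGenes = 0L)
  sim <- simulateGenome(cfg)
  expect_length(simGenome(sim), 3L)
  expect_equal(sum(Biostrings::width(simGenome(sim))), 3L * 350000L)
  expect_length(truthGenes(sim), 0L)
  expect_length(truthExons(sim), 0L)
})

test_that("the same seed reproduces byte-identical outputs", {
  cfg <- smallConfig(seed = 5, nGenes = 6L)
  sim1 <- simulateGenome(cfg)
  sim2 <- simulateGenome(cfg)
  expect_identical(as.character(simGenome(sim1)), as.character(simGenome(sim2)))
  expect_identical(as.data.frame(truthGenes(sim1)),
                   as.data.frame(truthGenes(sim2)))
  tr1 <- simulateLibraries(sim1)
  tr2 <- simulateLibraries(sim2)
  expect_identical(as.character(tr1), as.character(tr2))
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  writeSimulation(sim1, d1, tr1)
  writeSimulation(sim2, d2, tr2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7), label = f)
  }
})

test_that("planted introns are GT..AG and at least the configured minimum", {
  sim <- simulateGenome(smallConfig(seed = 9, nGenes = 10L))
  gen <- simGenome(sim)
  minIntron <- simConfig(sim)@intronLengthMin
  for (gid in names(truthExons(sim))) {
    e <- sort(truthExons(sim)[[gid]])
    if (length(e) < 2L) next
    chr <- as.character(GenomicRanges::seqnames(e))[1]
    st <- as.character(GenomicRanges::strand(e))[1]
    s <- GenomicRanges::end(e)[-length(e)] + 1L
    en <- GenomicRanges::start(e)[-1L] - 1L
    expect_true(all(en - s + 1L >= minIntron))
    don <- substring(as.character(gen[[chr]]), s, s + 1L)
    acc <- substring(as.character(gen[[chr]]), en - 1L, en)
    if (st == "+") {
      expect_true(all(don == "GT") && all(acc == "AG"))
    } else {
      expect_true(all(don == "CT") && all(acc == "AC"))
    }
  }
})

test_that("realized structure means track the configured distributions", {
  # moderate n keeps this fast; the acceptance suite re-checks at n = 500
  cfg <- simulationConfig(seed = 2, nGenes = 200L, nChromosomes = 4L,
                          chromosomeLength = 1500000L,
                          libraries = data.frame(library = character(),
                                                 tissue = character(),
                                                 n_ests = integer()),
                          clusterPlantSpec = data.frame(
                            tissue = character(), chromosome = integer(),
                            span = integer(), n_genes = integer()))
  sim <- simulateGenome(cfg)
  ex <- truthExons(sim)
  nEx <- lengths(ex)
  exLens <- unlist(lapply(ex, GenomicRanges::width))
  intrLens <- unlist(lapply(ex, function(gr) {
    gr <- sort(gr)
    if (length(gr) < 2L) return(numeric(0))
    GenomicRanges::start(gr)[-1L] - GenomicRanges::end(gr)[-length(gr)] - 1L
  }))
  expect_lt(abs(mean(nEx) - 4.8) / 4.8, 0.1)
  expect_lt(abs(mean(exLens) - 353) / 353, 0.1)
  expect_lt(abs(mean(intrLens) - 1904) / 1904, 0.1)
})

test_that("error-free ESTs are exact substrings of their mature transcript", {
  cfg <- smallConfig(seed = 4, nGenes = 8L, estErrorRate = 0,
                     chimeraRate = 0)
  sim <- simulateGenome(cfg)
  tr <- simulateLibraries(sim)
  md <- S4Vectors::mcols(tr)
  expect_false(any(md$is_chimera))
  mature <- as.character(matureTranscripts(sim))
  est <- which(md$type == "EST")
  expect_gt(length(est), 50L)
  for (i in est) {
    expect_true(grepl(as.character(tr)[[i]],
                      mature[[md$source_gene[i]]], fixed = TRUE))
  }
})

test_that("FL-cDNA clones carry poly-A tails of at least the configured minimum", {
  sim <- simulateGenome(smallConfig(seed = 4, nGenes = 8L))
  tr <- simulateLibraries(sim)
  md <- S4Vectors::mcols(tr)
  flc <- as.character(tr)[md$type == "FLC"]
  tails <- vapply(flc, function(s) {
    m <- regexpr("A+$", s)
    attr(m, "match.length")
  }, integer(1))
  expect_true(all(tails >= simConfig(sim)@polyaMin))
})

test_that("tissue-specific genes draw almost all ESTs from their own tissue", {
  res <- smallRun()
  md <- S4Vectors::mcols(res$transcripts)
  tg <- truthGenes(res$sim)
  est <- md[md$type == "EST", ]
  for (gid in tg$gene_id[tg$tissue != "broad"]) {
    mine <- est[est$source_gene == gid, ]
    if (nrow(mine) < 10L) next
    own <- mean(mine$tissue == tg$tissue[tg$gene_id == gid])
    expect_gt(own, 0.9)
  }
})

test_that("chimera truth flags are binomially consistent with the configured rate", {
  res <- referenceRun()
  md <- S4Vectors::mcols(res$transcripts)
  cfg <- simConfig(res$sim)
  nG <- cfg@nGenes
  rate <- cfg@chimeraRate
  nChim <- sum(md$is_chimera)
  mu <- nG * rate / (1 - rate)
  sigma <- sqrt(nG * (rate / (1 - rate)) * (1 - rate / (1 - rate)))
  expect_lt(abs(nChim - mu), 3 * sigma + 1)
  chim <- md[md$is_chimera, ]
  expect_true(all(!is.na(chim$source_gene2)))
  expect_true(all(chim$source_gene != chim$source_gene2))
})

test_that("impossible placements fail with the offending gene index", {
  cfg <- smallConfig(seed = 1, nGenes = 60L, chromosomeLength = 40000L)
  expect_error(simulateGenome(cfg), "cannot place gene")
})

test_that("a library manifest naming an unknown tissue is rejected", {
  expect_error(
    smallConfig(libraries = data.frame(library = "fxx", tissue = "gill",
                                       n_ests = 10L)),
    "unknown tissue")
})

test_that("the locus-call simulator plants density enrichment and clusters", {
  lc <- simulateLocusCalls(seed = 10, nLoci = 500, specificFraction = 0.4,
                           clusterPlant = data.frame(
                             tissue = "ovary", chromosome = 2L,
                             span = 90000L, n_genes = 10L))
  expect_equal(nrow(lc$calls), 500L)
  expect_true(all(lc$calls$specific_tissue[1:10] == "ovary"))
  expect_true(all(lc$calls$end[1:10] - lc$calls$start[1:10] > 0))
  expect_lte(max(lc$calls$start[1:10]) - min(lc$calls$start[1:10]), 90000L)
})
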