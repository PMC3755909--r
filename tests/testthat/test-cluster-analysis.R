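# 100-kb cluster chaining, Fisher exact test, duplication fractions,
# density ratios.

mkCalls <- function(starts, tissues, chrom = "chr1", width = 2000L) {
  data.frame(locus_id = sprintf("g%02d", seq_along(starts)),
             chromosome = chrom, start = starts, end = starts + width - 1L,
             specific_tissue = tissues, stringsAsFactors = FALSE)
}

test_that("the 100-kb gap rule chains clusters and leaves singletons", {
  calls <- mkCalls(c(100000L, 192000L, 344000L),
                   c("midgut", "midgut", "midgut"))
  # gaps: 90 kb (chained) then 150 kb (broken)
  cl <- detectClusters(calls)
  expect_equal(nrow(cl), 1L)
  expect_setequal(cl$members[[1]], c("g01", "g02"))
  expect_equal(cl$n_members, 2L)
  one <- detectClusters(mkCalls(500000L, "ovary"))
  expect_equal(nrow(one), 0L)
  # the boundary is a gap of exactly clusterGap: still one cluster
  edge <- detectClusters(mkCalls(c(1L, 102000L), c("wing", "wing")),
                         clusterGap = 100000L)
  expect_equal(nrow(edge), 1L)
})

test_that("different tissues and chromosomes never co-cluster", {
  calls <- rbind(mkCalls(c(100000L, 150000L), c("ovary", "testis")),
                 mkCalls(c(100000L, 150000L), c("brain", "brain"), "chr2"))
  calls$locus_id <- sprintf("g%02d", 1:4)
  cl <- detectClusters(calls)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$tissue, "brain")
  expect_equal(cl$chromosome, "chr2")
})

test_that("cluster detection is idempotent, order-free and gap-monotone", {
  set.seed(61)
  calls <- mkCalls(sort(sample(1:3000000, 40)) ,
                   sample(c("ovary", "testis", NA), 40, TRUE))
  c1 <- detectClusters(calls)
  c2 <- detectClusters(calls[sample(nrow(calls)), ])
  expect_identical(lapply(c1$members, as.character),
                   lapply(c2$members, as.character))
  narrow <- detectClusters(calls, clusterGap = 50000L)
  wide <- detectClusters(calls, clusterGap = 200000L)
  expect_gte(sum(lengths(wide$members)), sum(lengths(narrow$members)))
})

test_that("the cluster summary reproduces printed-fraction arithmetic", {
  # 185 specific genes of which 88 clustered gives the printed 48%
  expect_equal(round(100 * 88 / 185), 48)
  calls <- mkCalls(c(1e5, 1.9e5, 5e5, 9e5), rep("midgut", 4))
  cl <- detectClusters(calls)
  sm <- summarizeClusters(calls, cl)
  mid <- sm[sm$tissue == "midgut", ]
  expect_equal(mid$n_specific, 4L)
  expect_equal(mid$n_clustered, 2L)
  expect_equal(mid$pct_clustered, 50)
  tot <- sm[sm$tissue == "Total", ]
  expect_equal(tot$n_specific, sum(sm$n_specific[sm$tissue != "Total"]))
  expect_equal(tot$n_clustered, sum(sm$n_clustered[sm$tissue != "Total"]))
  none <- summarizeClusters(mkCalls(c(1e5, 9e5), c("brain", "brain")),
                            detectClusters(mkCalls(c(1e5, 9e5),
                                                   c("brain", "brain"))))
  expect_equal(none$pct_clustered[none$tissue == "brain"], 0)
})

test_that("adjacency tables capture neighbour specificity patterns", {
  alt <- mkCalls(seq(1e5, 8e5, by = 1e5),
                 rep(c("ovary", NA), 4))
  tab <- adjacencyTable(alt)
  expect_equal(tab["specific", "match"], 0L)
  allSpec <- mkCalls(seq(1e5, 4e5, by = 1e5), rep("ovary", 4))
  tab2 <- adjacencyTable(allSpec)
  expect_equal(tab2["specific", "match"], 3L)
  expect_equal(sum(tab2) - tab2["specific", "match"], 0L)
  # the same-tissue variant distinguishes mixed-tissue neighbours
  mix <- mkCalls(seq(1e5, 3e5, by = 1e5), c("ovary", "testis", "testis"))
  expect_equal(adjacencyTable(mix, "same")["specific", "match"], 1L)
  expect_equal(adjacencyTable(mix, "any")["specific", "match"], 2L)
})

test_that("planted clusters reject adjacency independence at alpha = 0.001", {
  # ~45% of specific loci sit in planted clusters, matching the clustered
  # fraction the summary statistics report on real-scale builds
  lc <- simulateLocusCalls(seed = 77, nLoci = 600, specificFraction = 0.15,
                           clusterPlant = data.frame(
                             tissue = rep(c("ovary", "midgut", "testis"), 2),
                             chromosome = c(2L, 3L, 4L, 2L, 3L, 4L),
                             span = rep(40000L, 6), n_genes = rep(12L, 6)))
  p <- fisherExact2x2(adjacencyTable(lc$calls))
  expect_lt(p, 0.001)
})

test_that("fisher exact matches hand-enumerated tables", {
  expect_equal(fisherExact2x2(matrix(c(1L, 1L, 1L, 1L), 2)), 1)
  expect_equal(fisherExact2x2(matrix(c(2L, 0L, 0L, 2L), 2)), 1 / 3)
  expect_equal(fisherExact2x2(matrix(c(5L, 0L, 0L, 5L), 2)), 2 / 252,
               tolerance = 1e-12)
  # degenerate margins
  expect_equal(fisherExact2x2(matrix(c(0L, 0L, 3L, 4L), 2)), 1)
  expect_equal(fisherExact2x2(matrix(c(0L, 0L, 0L, 0L), 2)), 1)
})

test_that("fisher exact agrees with stats::fisher.test on random tables", {
  set.seed(62)
  for (rep in 1:40) {
    tab <- matrix(rpois(4, 6), 2)
    expect_equal(fisherExact2x2(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("duplicated cluster members are recognized by sequence linkage", {
  set.seed(63)
  base <- rndDna(900)
  mut <- function(s, rate) {
    x <- strsplit(s, "")[[1]]
    p <- which(runif(length(x)) < rate)
    for (q in p) x[q] <- setdiff(c("A", "C", "G", "T"), x[q])[1]
    paste(x, collapse = "")
  }
  twins <- c(m1 = base, m2 = mut(base, 0.02))
  r <- duplicationFraction(twins)
  expect_equal(r$fraction, 1)
  expect_equal(r$n_duplicated, 2L)
  unrelated <- c(u1 = rndDna(1000), u2 = rndDna(1000))
  expect_equal(duplicationFraction(unrelated)$fraction, 0)
  fam <- setNames(c(base, mut(base, 0.03), mut(base, 0.03), mut(base, 0.04),
                    mut(base, 0.02), replicate(5, rndDna(900))),
                  sprintf("m%02d", 1:10))
  r2 <- duplicationFraction(fam)
  expect_equal(r2$fraction, 0.5)
  expect_setequal(r2$duplicated, sprintf("m%02d", 1:5))
})

test_that("density ratios behave at the uniform and concentrated extremes", {
  lens <- c(chrZ = 1e6, chr2 = 1e6)
  even <- data.frame(locus_id = c("a", "b"), chromosome = c("chrZ", "chr2"),
                     start = c(1, 1), end = c(100, 100),
                     specific_tissue = "testis")
  expect_equal(chromosomeDensityRatio(even, "testis", "chrZ", lens), 1)
  onez <- even; onez$chromosome <- c("chrZ", "chrZ")
  expect_equal(chromosomeDensityRatio(onez, "testis", "chrZ", lens), 2)
  expect_error(chromosomeDensityRatio(even, "wing", "chrZ", lens),
               "no wing-specific")
})

test_that("the planted ovary cluster is recovered intact by detection", {
  res <- referenceRun()
  tg <- truthGenes(res$sim)
  m2t <- matchLociToTruth(res$geneSets, res$sim)
  planted <- tg$gene_id[!is.na(tg$cluster_id) & tg$cluster_id == "pc1"]
  lociOf <- m2t$locus_id[match(planted, m2t$gene_id)]
  membership <- vapply(lociOf, function(l) {
    hit <- which(vapply(res$clusters$members, function(mm) l %in% mm,
                        logical(1)))
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
  called <- membership[!is.na(membership)]
  expect_gte(length(called), 10L) # nearly all 12 called specific
  expect_length(unique(called), 1L) # and all in one detected cluster
})
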