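# Independent oracles used to freeze expected values. These deliberately
# re-derive results by brute force or by the defining formula, sharing no
# code with the implementation paths they check.

# exhaustive ungapped shift-and-count: does any shift give a window of
# minSpan columns with > minIdentity matches? returns list(linked, offset)
oracleShiftCount <- function(a, b, minSpan = 100L, minIdentity = 0.95) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  best <- NULL
  for (shift in seq(-(length(b) - 1L), length(a) - 1L)) {
    # a[i] pairs with b[i - shift]
    i <- seq_along(a)
    j <- i - shift
    ok <- j >= 1L & j <= length(b)
    if (sum(ok) < minSpan) next
    m <- as.integer(a[i[ok]] == b[j[ok]] & a[i[ok]] != "N")
    cs <- c(0L, cumsum(m))
    n <- length(m)
    w <- minSpan
    wins <- cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)]
    if (max(wins) > minIdentity * w) return(list(linked = TRUE, offset = shift))
  }
  list(linked = FALSE, offset = NA_integer_)
}

# plain-R re-implementation of the splice-aware local DP recurrences
# (scores only, no traceback); independent of the compiled kernel
oracleSpliceScore <- function(tseq, gseq, match = 2, mismatch = -3,
                              gapOpen = -6, gapExt = -2, intron = -40,
                              bonus = 15, minIntron = 30) {
  t <- strsplit(tseq, "")[[1]]; g <- strsplit(gseq, "")[[1]]
  m <- length(t); n <- length(g)
  NEG <- -1e9
  M <- matrix(NEG, m + 1, n + 1)
  Ix <- matrix(NEG, m + 1, n + 1)
  Iy <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in 1:m) {
    for (j in 1:n) {
      s <- if (t[i] == g[j] && t[i] != "N") match else mismatch
      C <- NEG
      jEnd <- j - 1L
      if (jEnd - minIntron >= 1L) {
        accAG <- jEnd >= 2L && g[jEnd - 1L] == "A" && g[jEnd] == "G"
        for (j0 in 1:(jEnd - minIntron)) {
          v <- M[i - 1 + 1, j0 + 1]
          if (v < NEG / 2) next
          cost <- intron
          if (accAG && j0 + 1L < n && g[j0 + 1L] == "G" && g[j0 + 2L] == "T")
            cost <- cost + bonus
          C <- max(C, v + cost)
        }
      }
      Ix[i + 1, j + 1] <- max(M[i, j + 1] + gapOpen, Ix[i, j + 1] + gapExt)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] + gapOpen, Iy[i + 1, j] + gapExt)
      M[i + 1, j + 1] <- s + max(0, M[i, j], Ix[i, j], Iy[i, j], C)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# brute-force longest forward-frame ORF: scan every ATG in every frame
oracleOrfScan <- function(seq, minAa = 31L) {
  L <- nchar(seq)
  bestAa <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (s in seq_len(max(0L, L - 5L))) {
    if (substr(seq, s, s + 2L) != "ATG") next
    p <- s + 3L
    while (p + 2L <= L) {
      cod <- substr(seq, p, p + 2L)
      if (cod %in% stops) {
        aa <- (p - s) %/% 3L
        if (aa > bestAa) bestAa <- aa
        break
      }
      p <- p + 3L
    }
  }
  if (bestAa >= minAa) bestAa else NULL
}

# full hypergeometric enumeration of the two-sided Fisher p-value using
# exact binomial coefficients (choose), no dhyper
oracleFisherEnum <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
  supp <- max(0, k - n):min(k, m)
  probs <- choose(m, supp) * choose(n, k - supp) / choose(m + n, k)
  pobs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# union-find closure done independently (matrix-power reachability)
oracleComponents <- function(n, edges) {
  adj <- diag(n) > 0
  for (e in edges) { adj[e[1], e[2]] <- TRUE; adj[e[2], e[1]] <- TRUE }
  repeat {
    nxt <- (adj %*% adj) > 0 | adj
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- integer(n)
  cc <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) { cc <- cc + 1L; comp[adj[i, ]] <- cc }
  }
  comp
}

# random DNA string helper for tests
rndDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")

# a small simulation configuration used across tests (fast: ~10 s end to
# end including mapping)
smallConfig <- function(seed = 7, nGenes = 12L, nChromosomes = 3L,
                        chromosomeLength = 350000L,
                        tissues = c("testis", "ovary", "midgut"),
                        libraries = data.frame(
                          library = c("ftes", "bmov", "fmgV"),
                          tissue = c("testis", "ovary", "midgut"),
                          n_ests = c(40L, 40L, 40L),
                          stringsAsFactors = FALSE),
                        clusterPlantSpec = data.frame(
                          tissue = character(), chromosome = integer(),
                          span = integer(), n_genes = integer(),
                          stringsAsFactors = FALSE),
                        ...) {
  simulationConfig(seed = seed, nGenes = nGenes,
                   nChromosomes = nChromosomes,
                   chromosomeLength = chromosomeLength, tissues = tissues,
                   libraries = libraries,
                   clusterPlantSpec = clusterPlantSpec, ...)
}

# construct a SplicedAlignmentSet + TranscriptSet pair directly, for
# gene-build unit tests that should not depend on the aligner
makeEvidence <- function(blocks, statuses, types, seqs = NULL) {
  ids <- names(blocks)
  if (is.null(seqs)) seqs <- setNames(rep("ACGT", length(ids)), ids)
  info <- S4Vectors::DataFrame(
    transcript_id = ids,
    chromosome = vapply(blocks, function(b)
      if (length(b)) as.character(GenomicRanges::seqnames(b))[1]
      else NA_character_, character(1)),
    strand = vapply(blocks, function(b)
      if (length(b)) as.character(GenomicRanges::strand(b))[1]
      else NA_character_, character(1)),
    identity = rep(1, length(ids)), coverage = rep(1, length(ids)),
    n_blocks = lengths(blocks), score = rep(100L, length(ids)),
    status = statuses)
  aln <- new("SplicedAlignmentSet", info = info,
             blocks = GenomicRanges::GRangesList(blocks))
  ts <- Biostrings::DNAStringSet(seqs)
  S4Vectors::mcols(ts) <- S4Vectors::DataFrame(
    clone_id = ids, library = rep("fmgV", length(ids)),
    tissue = rep("midgut", length(ids)), type = types,
    source_gene = rep(NA_character_, length(ids)),
    source_gene2 = rep(NA_character_, length(ids)),
    is_chimera = rep(FALSE, length(ids)),
    trunc_offset = rep(0L, length(ids)))
  list(aln = aln, transcripts = new("TranscriptSet", ts))
}
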