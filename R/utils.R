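# Small internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# shifted geometric sampler: minimum + geometric, with the requested mean
rShiftedGeom <- function(n, mean, min) {
  if (mean <= min) return(rep(as.integer(min), n))
  as.integer(min + rgeom(n, prob = 1 / (mean - min + 1)))
}

# random DNA as a character vector of single bases, GC content ~0.38 by
# default (AT-rich, as in the genome the simulator emulates)
randomBases <- function(n, gc = 0.38) {
  if (n <= 0L) return(character(0))
  sample(DNA_BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# substitute bases at the given positions with a uniformly drawn different base
mutateBases <- function(bases, positions) {
  for (p in positions) {
    bases[p] <- sample(setdiff(DNA_BASES, bases[p]), 1L)
  }
  bases
}

# per-base substitution at rate `rate`
mutateAtRate <- function(bases, rate) {
  if (rate <= 0 || !length(bases)) return(bases)
  hit <- which(runif(length(bases)) < rate)
  mutateBases(bases, hit)
}

revcompChar <- function(bases) {
  rev(chartr("ACGT", "TGCA", bases))
}

# name-preserving coercion to character (as.character() drops names)
asNamedCharacter <- function(x) {
  nm <- names(x)
  s <- as.character(x)
  if (is.null(names(s)) && !is.null(nm)) names(s) <- nm
  s
}

# soft-mask a trailing pure-A run of >= 5 nt (a poly-A tail) with N so the
# aligner cannot chase tail matches through spurious introns; coordinates
# and total length are preserved
maskPolyATail <- function(seq) {
  m <- regexpr("A+$", seq)
  if (m > 0L && attr(m, "match.length") >= 5L) {
    run <- attr(m, "match.length")
    seq <- paste0(substr(seq, 1L, m - 1L), strrep("N", run))
  }
  seq
}

# ---- union-find over 1..n ----
ufNew <- function(n) seq_len(n)

ufFind <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

ufUnionAll <- function(n, edges_i, edges_j) {
  parent <- seq_len(n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  for (k in seq_along(edges_i)) {
    ri <- find(edges_i[k]); rj <- find(edges_j[k])
    if (ri != rj) parent[ri] <- rj
  }
  vapply(seq_len(n), find, integer(1))
}

# connected-component labels (1-based, in order of first appearance)
componentsFromEdges <- function(n, edges_i, edges_j) {
  roots <- ufUnionAll(n, edges_i, edges_j)
  match(roots, unique(roots))
}

#' Default simulation configuration
#'
#' Constructs a [SimulationConfig-class]. The defaults define the package's
#' reference study conditions: a 4-chromosome, 4.8-Mb genome (chromosome 1
#' Z-like) carrying 200 genes whose exon/intron structure follows the
#' empirical means (4.8 exons per transcript, 353-bp exons, 1904-bp
#' transposon-inflated introns), five tissues sampled by six EST libraries
#' (two testis libraries, pooled at the tissue level), a planted 12-gene
#' ovary-specific cluster within 100 kb and a 6-gene midgut cluster, 1.6x
#' testis-specific gene density on the Z-like chromosome, and a 5% chimeric
#' FL-cDNA fraction.
#'
#' @param seed integer seed.
#' @param nGenes,nChromosomes,chromosomeLength genome scale.
#' @param tissues,libraries tissue universe and EST library manifest
#'   (data.frame `library`, `tissue`, `n_ests`).
#' @param clusterPlantSpec data.frame (`tissue`, `chromosome`, `span`,
#'   `n_genes`) of planted clusters; pass a zero-row data.frame for none.
#' @param ... overrides for any other [SimulationConfig-class] slot.
#' @return a validated [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(seed = 1, nGenes = 20)
#' @export
simulationConfig <- function(seed = 1L,
                             nGenes = 200L,
                             nChromosomes = 4L,
                             chromosomeLength = 1200000L,
                             tissues = c("testis", "ovary", "midgut",
                                         "fat_body", "brain"),
                             libraries = data.frame(
                               library = c("ftes", "bmte", "bmov", "fmgV",
                                           "ffbm", "fner"),
                               tissue = c("testis", "testis", "ovary",
                                          "midgut", "fat_body", "brain"),
                               n_ests = c(200L, 200L, 400L, 400L, 400L, 400L),
                               stringsAsFactors = FALSE),
                             clusterPlantSpec = data.frame(
                               tissue = c("ovary", "midgut"),
                               chromosome = c(2L, 3L),
                               span = c(100000L, 80000L),
                               n_genes = c(12L, 6L),
                               stringsAsFactors = FALSE),
                             ...) {
  args <- list(...)
  defaults <- list(
    exonCountMean = 4.8, exonLengthMean = 353, exonLengthMin = 27L,
    intronLengthMean = 1904, intronLengthMin = 34L,
    teFraction = 0.35, tissueSpecificFraction = 0.3,
    specificityLeak = 0.005, clusterDupFraction = 0.5,
    testisZEnrichment = 1.6, estErrorRate = 0.005,
    estTruncationMean = 20, estReadLength = 500L,
    chimeraRate = 0.05, polyaMin = 10L, polyaMean = 18,
    mrnaFraction = 0.1, modelFraction = 0.7)
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown))
    stop("unknown configuration parameter(s): ", paste(unknown, collapse = ", "))
  defaults[names(args)] <- args
  intslots <- c("exonLengthMin", "intronLengthMin", "estReadLength", "polyaMin")
  for (s in intslots) defaults[[s]] <- as.integer(defaults[[s]])
  do.call(new, c(list("SimulationConfig",
                      seed = as.integer(seed),
                      nChromosomes = as.integer(nChromosomes),
                      chromosomeLength = as.integer(chromosomeLength),
                      nGenes = as.integer(nGenes),
                      tissues = tissues,
                      libraries = libraries,
                      clusterPlantSpec = clusterPlantSpec),
                 defaults))
}
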