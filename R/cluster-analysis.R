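# Tissue-specific chromosomal gene clusters: detection by the 100-kb
# chaining rule, Fisher exact adjacency test, duplication fractions and
# chromosome density enrichment.

#' Detect tissue-specific gene clusters
#'
#' Per tissue and chromosome, loci are chained when the genomic gap
#' between consecutive same-tissue intervals (end of one to start of the
#' next) is at most `clusterGap`; chains of two or more loci become
#' clusters. Gaps, not midpoints, are used so the rule is well defined for
#' long genes.
#'
#' @param calls data.frame with `locus_id`, `chromosome`, `start`, `end`,
#'   `specific_tissue` (`NA` for non-specific loci), e.g. from
#'   [tissueCallTable()].
#' @param clusterGap maximum gap in bp, default 100000.
#' @return `DataFrame` with `cluster_id`, `tissue`, `chromosome`, `start`,
#'   `end`, `span`, `n_members` and `members` (`CharacterList`, ordered by
#'   position).
#' @export
detectClusters <- function(calls, clusterGap = 100000L) {
  sp <- calls[!is.na(calls$specific_tissue), , drop = FALSE]
  rows <- list(); memb <- list(); n <- 0L
  if (nrow(sp)) {
    sp <- sp[order(sp$specific_tissue, sp$chromosome, sp$start), , drop = FALSE]
    for (grp in split(sp, paste(sp$specific_tissue, sp$chromosome, sep = "\r"))) {
      grp <- grp[order(grp$start), , drop = FALSE]
      gap <- grp$start[-1L] - grp$end[-nrow(grp)]
      chain <- cumsum(c(0L, as.integer(gap > clusterGap)))
      for (ch in split(seq_len(nrow(grp)), chain)) {
        if (length(ch) < 2L) next
        n <- n + 1L
        g <- grp[ch, ]
        memb[[n]] <- g$locus_id
        rows[[n]] <- data.frame(
          tissue = g$specific_tissue[1L], chromosome = g$chromosome[1L],
          start = min(g$start), end = max(g$end),
          span = max(g$end) - min(g$start) + 1L,
          n_members = length(ch), stringsAsFactors = FALSE)
      }
    }
  }
  if (!n)
    return(DataFrame(cluster_id = character(), tissue = character(),
                     chromosome = character(), start = integer(),
                     end = integer(), span = integer(),
                     n_members = integer(), members = CharacterList()))
  df <- do.call(rbind, rows)
  ord <- order(df$tissue, df$chromosome, df$start)
  df <- df[ord, , drop = FALSE]
  memb <- memb[ord]
  DataFrame(cluster_id = sprintf("cl%03d", seq_len(n)),
            tissue = df$tissue, chromosome = df$chromosome,
            start = df$start, end = df$end, span = df$span,
            n_members = df$n_members, members = CharacterList(memb))
}

#' Summarize tissue-specific clustering per tissue
#'
#' Produces the per-tissue summary table: number of tissue-specific genes,
#' number and integer-percent fraction in clusters, number of clusters,
#' and (when duplication labels are supplied) the fraction of clustered
#' genes that are duplicated. A `Total` row sums the per-tissue rows;
#' fractions are recomputed from the summed counts. Fractions are `NA`
#' when their denominator is zero.
#'
#' @param calls tissue-call table (see [detectClusters()]).
#' @param clusters result of [detectClusters()].
#' @param duplicatedIds optional character vector of locus ids labelled as
#'   duplicated (members of within-cluster duplication families).
#' @return data.frame with one row per tissue plus `Total`.
#' @export
summarizeClusters <- function(calls, clusters, duplicatedIds = character(0)) {
  tissues <- sort(unique(stats::na.omit(calls$specific_tissue)))
  rows <- lapply(tissues, function(tis) {
    nSpec <- sum(calls$specific_tissue == tis, na.rm = TRUE)
    cl <- clusters[clusters$tissue == tis, , drop = FALSE]
    clMembers <- unlist(cl$members)
    nClust <- length(clMembers)
    nDup <- sum(clMembers %in% duplicatedIds)
    data.frame(tissue = tis, n_specific = nSpec, n_clustered = nClust,
               pct_clustered = if (nSpec > 0) round(100 * nClust / nSpec)
                               else NA_real_,
               n_clusters = nrow(cl),
               n_duplicated = nDup,
               fraction_duplicated = if (nClust > 0) round(nDup / nClust, 2)
                                     else NA_real_,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(tissue = character(), n_specific = integer(),
                     n_clustered = integer(), pct_clustered = numeric(),
                     n_clusters = integer(), n_duplicated = integer(),
                     fraction_duplicated = numeric(), stringsAsFactors = FALSE)
  tot <- data.frame(
    tissue = "Total", n_specific = sum(df$n_specific),
    n_clustered = sum(df$n_clustered),
    pct_clustered = if (sum(df$n_specific) > 0)
      round(100 * sum(df$n_clustered) / sum(df$n_specific)) else NA_real_,
    n_clusters = sum(df$n_clusters),
    n_duplicated = sum(df$n_duplicated),
    fraction_duplicated = if (sum(df$n_clustered) > 0)
      round(sum(df$n_duplicated) / sum(df$n_clustered), 2) else NA_real_,
    stringsAsFactors = FALSE)
  rbind(df, tot)
}

#' Build the adjacency contingency table for the clustering test
#'
#' Over all ordered pairs of genomically adjacent loci on each chromosome,
#' cross-tabulates whether the first locus is tissue-specific against
#' whether the second is tissue-specific. Under the null of no positional
#' clustering, a locus's specificity is independent of its neighbour's, so
#' both rows share one match rate; positional clustering of specific genes
#' inflates the specific/specific cell.
#'
#' The published test never states its 2x2 construction, so it is
#' configurable here. The default (`matchMode = "any"`) asks whether the
#' second locus is specific for any tissue in both rows, which keeps the
#' two rows comparable and the test calibrated. `matchMode = "same"`
#' instead asks, when the first locus is specific, whether the second is
#' specific for the *same* tissue; this sharpens the biological question
#' but makes the row match rates structurally unequal (a specific
#' neighbour matches only 1/n-tissues of the time under the null), so it
#' is not a calibrated independence test and is provided for exploration
#' only. Chromosomes with fewer than two loci contribute nothing.
#'
#' @param calls tissue-call table (all loci with coordinates, specific or
#'   not).
#' @param matchMode `"any"` (default) or `"same"`, see Details.
#' @return 2x2 integer matrix: rows = first locus specific (yes/no),
#'   columns = second locus matches (yes/no).
#' @export
adjacencyTable <- function(calls, matchMode = c("any", "same")) {
  matchMode <- match.arg(matchMode)
  tab <- matrix(0L, 2L, 2L,
                dimnames = list(first = c("specific", "non_specific"),
                                second = c("match", "no_match")))
  for (grp in split(calls, calls$chromosome)) {
    grp <- grp[order(grp$start), , drop = FALSE]
    if (nrow(grp) < 2L) next
    t1 <- grp$specific_tissue[-nrow(grp)]
    t2 <- grp$specific_tissue[-1L]
    firstSpec <- !is.na(t1)
    match2 <- if (matchMode == "any") !is.na(t2)
              else ifelse(firstSpec, !is.na(t2) & t2 == t1, !is.na(t2))
    tab[1L, 1L] <- tab[1L, 1L] + sum(firstSpec & match2)
    tab[1L, 2L] <- tab[1L, 2L] + sum(firstSpec & !match2)
    tab[2L, 1L] <- tab[2L, 1L] + sum(!firstSpec & match2)
    tab[2L, 2L] <- tab[2L, 2L] + sum(!firstSpec & !match2)
  }
  tab
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value: the sum of hypergeometric probabilities, over
#' all tables with the observed margins, of tables no more probable than
#' the observed one (with the customary relative tolerance for floating
#' point ties). Computed directly from the hypergeometric density. When
#' any margin is zero the table is degenerate and p = 1. No lower floor is
#' imposed on the p-value.
#'
#' @param tab 2x2 matrix or length-4 vector `(a, b, c, d)` of
#'   non-negative counts.
#' @return two-sided p-value.
#' @examples
#' fisherExact2x2(matrix(c(2, 0, 0, 2), 2))
#' @export
fisherExact2x2 <- function(tab) {
  x <- as.integer(tab)
  stopifnot(length(x) == 4L, all(x >= 0L))
  a <- x[1L]; c_ <- x[2L]; b <- x[3L]; d <- x[4L] # matrix is column-major
  m <- a + b      # row 1 margin
  n <- c_ + d     # row 2 margin
  k <- a + c_     # column 1 margin
  if (m == 0L || n == 0L || k == 0L || (b + d) == 0L) return(1)
  supp <- max(0L, k - n):min(k, m)
  probs <- dhyper(supp, m, n, k)
  pobs <- dhyper(a, m, n, k)
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

#' Duplication fraction within a gene cluster
#'
#' A cluster member counts as duplicated when it links to at least one
#' other member by sequence similarity: protein-level identity of at
#' least `aaIdentity` over at least `coverage` of the shorter protein when
#' both members have detectable ORFs, else nucleotide identity of at least
#' `ntIdentity` over at least `coverage` of the shorter sequence.
#'
#' @param memberSeqs named character vector or `DNAStringSet` of the
#'   cluster members' transcript sequences; members with missing sequence
#'   are excluded.
#' @param aaIdentity,ntIdentity,coverage thresholds (defaults 0.4, 0.7,
#'   0.5).
#' @return list `fraction` (duplicated members / cluster size),
#'   `n_duplicated`, `duplicated` (member ids).
#' @export
duplicationFraction <- function(memberSeqs, aaIdentity = 0.4,
                                ntIdentity = 0.7, coverage = 0.5) {
  seqs <- asNamedCharacter(memberSeqs)
  seqs <- seqs[!is.na(seqs) & nchar(seqs) > 0L]
  ids <- names(seqs)
  nM <- length(seqs)
  if (nM < 2L)
    return(list(fraction = 0, n_duplicated = 0L, duplicated = character(0)))
  orfs <- lapply(seqs, detectOrf)
  prots <- vapply(seq_len(nM), function(i) {
    o <- orfs[[i]]
    if (is.null(o)) return(NA_character_)
    cds <- substr(seqs[i], o$start, o$end - 3L)
    as.character(suppressWarnings(translate(DNAString(cds))))
  }, character(1))
  linkPair <- function(s1, s2, idThr, type) {
    short <- min(nchar(s1), nchar(s2))
    al <- if (type == "aa")
      pairwiseAlignment(Biostrings::AAString(s1), Biostrings::AAString(s2),
                        type = "local", substitutionMatrix = "BLOSUM62",
                        gapOpening = 10, gapExtension = 0.5)
    else
      pairwiseAlignment(DNAString(s1), DNAString(s2), type = "local",
                        substitutionMatrix = linkageSubstMat(),
                        gapOpening = 5, gapExtension = 2)
    cols <- nchar(as.character(Biostrings::alignedPattern(al)))
    if (cols < coverage * short) return(FALSE)
    Biostrings::pid(al, type = "PID1") / 100 >= idThr
  }
  dup <- logical(nM)
  for (i in seq_len(nM - 1L)) for (j in (i + 1L):nM) {
    linked <- if (!is.na(prots[i]) && !is.na(prots[j]))
      linkPair(prots[i], prots[j], aaIdentity, "aa")
    else
      linkPair(seqs[i], seqs[j], ntIdentity, "nt")
    if (linked) { dup[i] <- TRUE; dup[j] <- TRUE }
  }
  list(fraction = sum(dup) / nM, n_duplicated = sum(dup),
       duplicated = ids[dup])
}

#' Tissue-specific gene density ratio of one chromosome
#'
#' Per-length density of the tissue's specific genes on the chromosome,
#' divided by their genome-wide per-length density.
#'
#' @param calls tissue-call table.
#' @param tissue tissue name.
#' @param chromosome chromosome name.
#' @param chromLengths named numeric vector of chromosome lengths (bp),
#'   covering every chromosome of the genome.
#' @return numeric ratio (1 = average density).
#' @export
chromosomeDensityRatio <- function(calls, tissue, chromosome, chromLengths) {
  spec <- calls[!is.na(calls$specific_tissue) &
                  calls$specific_tissue == tissue, , drop = FALSE]
  nTot <- nrow(spec)
  if (nTot == 0L) stop("no ", tissue, "-specific genes genome-wide")
  if (!chromosome %in% names(chromLengths))
    stop("unknown chromosome: ", chromosome)
  nChr <- sum(spec$chromosome == chromosome)
  (nChr / chromLengths[[chromosome]]) /
    (nTot / sum(as.numeric(chromLengths)))
}
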