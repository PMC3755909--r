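# 5' EST clustering: group ESTs into contigs/singletons by a local-identity
# rule and pick the most-upstream clone of each contig as the FL-cDNA
# candidate.

# substitution matrix for the linkage alignment: +1 match, -1 mismatch,
# N matches nothing (always -1)
linkageSubstMat <- function() {
  b <- c(DNA_BASES, "N")
  m <- matrix(-1, 5, 5, dimnames = list(b, b))
  diag(m) <- 1
  m["N", "N"] <- -1
  m
}

#' Pairwise EST linkage by the identity rule
#'
#' Two sequences are linked when their best local alignment
#' (match +1, mismatch -1, gap -2) contains a window of `minSpan` aligned
#' columns in which strictly more than `minIdentity` of the columns match.
#' `N` never matches. The reported offset is the signed shift of `a`'s 5'
#' end relative to `b`'s in that alignment: positive when `a` extends
#' further upstream.
#'
#' @param a,b character or `DNAString` sequences over A, C, G, T, N.
#' @param rule an [IdentityRule-class].
#' @return list with elements `linked` (logical) and `offset` (integer bp;
#'   `NA` when unlinked).
#' @examples
#' s <- paste(sample(c("A","C","G","T"), 150, TRUE), collapse = "")
#' pairwiseLinkage(s, substring(s, 21), IdentityRule())
#' @export
pairwiseLinkage <- function(a, b, rule = IdentityRule()) {
  validObject(rule)
  a <- as.character(a); b <- as.character(b)
  if (nchar(a) < rule@minSpan || nchar(b) < rule@minSpan)
    return(list(linked = FALSE, offset = NA_integer_))
  al <- pairwiseAlignment(DNAString(a), DNAString(b), type = "local",
                          substitutionMatrix = linkageSubstMat(),
                          gapOpening = 0, gapExtension = 2)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ncol <- length(pa)
  if (ncol < rule@minSpan) return(list(linked = FALSE, offset = NA_integer_))
  match <- as.integer(pa == pb & pa != "-" & pa != "N")
  cs <- c(0L, cumsum(match))
  w <- rule@minSpan
  winMatches <- cs[(w + 1L):(ncol + 1L)] - cs[1L:(ncol - w + 1L)]
  if (max(winMatches) <= rule@minIdentity * w)
    return(list(linked = FALSE, offset = NA_integer_))
  off <- start(Biostrings::pattern(al)) - start(Biostrings::subject(al))
  list(linked = TRUE, offset = as.integer(off))
}

# shift-invariant k-mer sampling prefilter: candidate pairs are those
# sharing >= minShared sampled 12-mers (sampled by sequence value -- kmers
# ending in "AC" -- so truncated copies sample the same positions). Each
# pair also carries the modal positional shift of its shared k-mers, used
# as the offset hint for the fast ungapped linkage check.
linkageCandidatePairs <- function(seqs, minShared = 2L) {
  n <- length(seqs)
  k <- 12L
  idL <- vector("list", n); kmL <- vector("list", n); posL <- vector("list", n)
  for (i in seq_len(n)) {
    s <- seqs[i]
    L <- nchar(s)
    if (L < k) next
    starts <- 1:(L - k + 1L)
    km <- substring(s, starts, starts + k - 1L)
    sel <- substring(km, k - 1L, k) == "AC"
    km <- km[sel]; pos <- starts[sel]
    first <- !duplicated(km)
    idL[[i]] <- rep(i, sum(first)); kmL[[i]] <- km[first]
    posL[[i]] <- pos[first]
  }
  ids <- unlist(idL, use.names = FALSE)
  kms <- unlist(kmL, use.names = FALSE)
  poss <- unlist(posL, use.names = FALSE)
  empty <- list(i = integer(0), j = integer(0), offsetHint = integer(0))
  if (!length(kms)) return(empty)
  o <- order(kms)
  ids <- ids[o]; kms <- kms[o]; poss <- poss[o]
  grp <- cumsum(!duplicated(kms))
  byId <- split(ids, grp)
  byPos <- split(poss, grp)
  keyL <- list(); difL <- list(); nb <- 0L
  for (g in which(lengths(byId) >= 2L)) {
    v <- byId[[g]]; p <- byPos[[g]]
    if (length(unique(v)) < 2L) next
    cb <- combn(seq_along(v), 2L)
    a <- v[cb[1L, ]]; b <- v[cb[2L, ]]
    pa <- p[cb[1L, ]]; pb <- p[cb[2L, ]]
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    tmp <- pa[swap]; pa[swap] <- pb[swap]; pb[swap] <- tmp
    ok <- a != b
    nb <- nb + 1L
    keyL[[nb]] <- (a[ok] - 1) * n + b[ok]
    difL[[nb]] <- pa[ok] - pb[ok]
  }
  if (!nb) return(empty)
  key <- unlist(keyL, use.names = FALSE)
  dif <- unlist(difL, use.names = FALSE)
  byPair <- split(dif, key)
  byPair <- byPair[lengths(byPair) >= minShared]
  if (!length(byPair)) return(empty)
  keep <- as.numeric(names(byPair))
  i <- floor((keep - 1) / n) + 1
  j <- keep - (i - 1) * n
  hint <- vapply(byPair, function(d) {
    t <- table(d)
    as.integer(names(t)[which.max(t)])
  }, integer(1))
  list(i = as.integer(round(i)), j = as.integer(round(j)),
       offsetHint = unname(hint))
}

# ungapped linkage check of a vs b at a known shift (a[i] pairs b[i - d]):
# sufficient for linkage when it passes, since an ungapped overlap is a
# valid local alignment under the rule
ungappedLinkage <- function(ca, cb, d, rule) {
  la <- length(ca); lb <- length(cb)
  iLo <- max(1L, 1L + d); iHi <- min(la, lb + d)
  if (iHi - iLo + 1L < rule@minSpan) return(FALSE)
  av <- ca[iLo:iHi]; bv <- cb[(iLo - d):(iHi - d)]
  m <- as.integer(av == bv & av != "N")
  cs <- c(0L, cumsum(m))
  w <- rule@minSpan
  nm <- length(m)
  max(cs[(w + 1L):(nm + 1L)] - cs[1L:(nm - w + 1L)]) > rule@minIdentity * w
}

#' Cluster 5' ESTs into contigs and singletons
#'
#' Builds the pairwise linkage graph under the identity rule (a
#' shift-invariant k-mer prefilter limits which pairs are aligned; for 60 or
#' fewer records all pairs are aligned) and takes its connected components
#' as contigs: single-linkage closure, matching the assembly semantics of
#' pooling clones that read the same transcript. Member 5' offsets within a
#' contig are propagated along linkage edges and normalized so the most
#' upstream member sits at offset 0; the representative of each contig is
#' its most upstream member (ties broken toward the lexicographically
#' smallest clone id).
#'
#' The result is canonicalized (members sorted by id, contigs ordered by
#' their smallest member id) so clustering is invariant to input order.
#'
#' @param records a named `DNAStringSet`/[TranscriptSet-class] or named
#'   character vector of 5' EST sequences.
#' @param rule an [IdentityRule-class].
#' @return `DataFrame` with columns `contig_id`, `representative`,
#'   `n_members`, `members` (`CharacterList`) and `offsets`
#'   (`IntegerList`, parallel to `members`).
#' @export
clusterEsts <- function(records, rule = IdentityRule()) {
  seqs <- asNamedCharacter(records)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("est%04d", seq_along(seqs))
  n <- length(seqs)
  if (n == 0L)
    return(DataFrame(contig_id = character(), representative = character(),
                     n_members = integer(),
                     members = CharacterList(),
                     offsets = IRanges::IntegerList()))
  cand <- if (n <= 60L) {
    if (n >= 2L) {
      cb <- combn(n, 2L)
      list(i = cb[1L, ], j = cb[2L, ],
           offsetHint = rep(NA_integer_, ncol(cb)))
    } else list(i = integer(0), j = integer(0), offsetHint = integer(0))
  } else linkageCandidatePairs(seqs)
  chars <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  eiL <- integer(length(cand$i)); ejL <- integer(length(cand$i))
  eoL <- integer(length(cand$i)); ne <- 0L
  for (r in seq_along(cand$i)) {
    i <- cand$i[r]; j <- cand$j[r]
    d <- cand$offsetHint[r]
    if (!is.na(d) && ungappedLinkage(chars[[i]], chars[[j]], d, rule)) {
      ne <- ne + 1L
      eiL[ne] <- i; ejL[ne] <- j; eoL[ne] <- d
      next
    }
    lk <- pairwiseLinkage(seqs[i], seqs[j], rule)
    if (lk$linked) {
      ne <- ne + 1L
      eiL[ne] <- i; ejL[ne] <- j; eoL[ne] <- lk$offset
    }
  }
  ei <- eiL[seq_len(ne)]; ej <- ejL[seq_len(ne)]; eo <- eoL[seq_len(ne)]
  comp <- componentsFromEdges(n, ei, ej)

  # propagate 5' positions along linkage edges (BFS per component);
  # offset(a, b) = pos(b) - pos(a)
  pos <- rep(NA_real_, n)
  adj <- vector("list", n)
  for (r in seq_along(ei)) {
    adj[[ei[r]]] <- c(adj[[ei[r]]], list(c(ej[r], eo[r])))
    adj[[ej[r]]] <- c(adj[[ej[r]]], list(c(ei[r], -eo[r])))
  }
  for (cc in unique(comp)) {
    nodes <- which(comp == cc)
    root <- nodes[order(ids[nodes])[1L]]
    pos[root] <- 0
    queue <- root
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      for (e in adj[[u]]) {
        v <- e[1L]
        if (is.na(pos[v])) { pos[v] <- pos[u] + e[2L]; queue <- c(queue, v) }
      }
    }
    pos[nodes] <- pos[nodes] - min(pos[nodes])
  }

  ord <- order(vapply(split(ids, comp), function(x) sort(x)[1L], character(1)))
  groups <- unname(split(seq_len(n), comp)[ord])
  contigId <- sprintf("ctg%04d", seq_along(groups))
  memb <- CharacterList(lapply(groups, function(g) ids[g][order(ids[g])]))
  offs <- IRanges::IntegerList(lapply(groups, function(g) {
    o <- as.integer(pos[g]); o[order(ids[g])]
  }))
  rep_ <- vapply(groups, function(g) {
    o <- pos[g]
    cand <- ids[g][o == min(o)]
    min(cand)
  }, character(1))
  DataFrame(contig_id = contigId, representative = unname(rep_),
            n_members = lengths(groups), members = memb, offsets = offs)
}

#' Select FL-cDNA candidate clones from EST contigs
#'
#' Per contig, the member whose aligned 5' end is most upstream (smallest
#' contig offset; ties broken toward the lexicographically smallest clone
#' id). Singletons are their own candidates.
#'
#' @param contigs the `DataFrame` returned by [clusterEsts()].
#' @return character vector of candidate clone ids, one per contig.
#' @export
selectRepresentatives <- function(contigs) {
  vapply(seq_len(nrow(contigs)), function(r) {
    m <- contigs$members[[r]]
    o <- contigs$offsets[[r]]
    cand <- m[o == min(o)]
    min(cand)
  }, character(1))
}
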