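# Gene build: partition the evidence into gene sets A (FL-cDNA/mRNA/model
# supported loci), B (EST-only mapped loci, ids prefixed "e") and C
# (unmappable sequence clusters, ids prefixed "c"), and compute the
# transcript-level (ORF, poly-A) and structure-level (exon/intron)
# statistics of the build.

# transitive closure of >=1 bp same-strand exon overlap among GRangesList
# elements; returns integer component labels
exonOverlapComponents <- function(exonsGRL) {
  n <- length(exonsGRL)
  if (n == 0L) return(integer(0))
  u <- unlist(exonsGRL, use.names = FALSE)
  owner <- rep(seq_len(n), lengths(exonsGRL))
  hits <- GenomicRanges::findOverlaps(u, u, ignore.strand = FALSE)
  qi <- owner[S4Vectors::queryHits(hits)]
  si <- owner[S4Vectors::subjectHits(hits)]
  keep <- qi < si
  componentsFromEdges(n, qi[keep], si[keep])
}

# canonical exon-chain signature used for isoform counting
exonChainSignature <- function(gr) {
  gr <- sort(gr)
  paste(as.character(seqnames(gr))[1L], as.character(strand(gr))[1L],
        paste(start(gr), end(gr), sep = "-", collapse = ","))
}

#' Build the evidence-partitioned gene sets
#'
#' Groups mapped FL-cDNA, public-mRNA and predicted-model evidence into
#' class-A loci by transitive closure of same-strand exon overlap
#' (at least 1 bp); attaches mapped ESTs that overlap a class-A locus;
#' groups the remaining mapped ESTs into class-B loci by the same closure;
#' clusters unmapped transcripts into class-C loci with the EST linkage
#' rule (no coordinates); and excludes chimeric clones from locus building
#' while retaining them in the assignment table. Every input transcript is
#' assigned to exactly one of {A locus, B locus, C locus,
#' chimeric_excluded}.
#'
#' Isoform counts per class-A locus are the number of distinct exon-chain
#' patterns among its FL-cDNA members.
#'
#' @param alignments a [SplicedAlignmentSet-class] covering all transcripts.
#' @param transcripts the [TranscriptSet-class] that was mapped.
#' @param models `GRangesList` of predicted gene-model exons (may be
#'   empty); models with coordinates outside the aligned chromosome set
#'   are rejected with a warning.
#' @param rule [IdentityRule-class] used for class-C sequence clustering.
#' @return a [GeneLocusSet-class].
#' @export
buildGeneSets <- function(alignments, transcripts, models = GRangesList(),
                          rule = IdentityRule()) {
  stopifnot(is(alignments, "SplicedAlignmentSet"))
  info <- alignments@info
  blocks <- alignments@blocks
  md <- mcols(transcripts)
  type <- setNames(as.character(md$type), md$clone_id)

  if (length(models)) {
    chroms <- unique(stats::na.omit(info$chromosome))
    bad <- vapply(models, function(gr)
      length(gr) == 0L ||
        (length(chroms) > 0L &&
           !all(as.character(seqnames(gr)) %in% chroms)), logical(1))
    if (any(bad)) {
      warning("rejected ", sum(bad), " model(s) outside assembly coordinates")
      models <- models[!bad]
    }
  }

  mapped <- info$transcript_id[info$status == "mapped"]
  chimeric <- info$transcript_id[info$status == "chimeric"]
  unmapped <- info$transcript_id[startsWith(info$status, "unmapped")]

  strongIds <- mapped[type[mapped] %in% c("FLC", "mRNA")]
  estIds <- mapped[type[mapped] == "EST"]

  evidence <- c(blocks[strongIds], models)
  evNames <- c(strongIds, names(models))
  comp <- exonOverlapComponents(evidence)

  lociList <- list()
  assignment <- list()
  addAssign <- function(id, kind, locus, cls)
    assignment[[length(assignment) + 1L]] <<- data.frame(
      id = id, kind = kind, locus_id = locus, class = cls,
      stringsAsFactors = FALSE)

  # ---- class A ----
  nA <- 0L
  aExons <- list(); aMembers <- list(); aRows <- list()
  if (length(evidence)) {
    ord <- order(vapply(split(evNames, comp), min, character(1)))
    groups <- split(seq_along(evidence), comp)[ord]
    nA <- length(groups)
    for (gi in seq_len(nA)) {
      g <- groups[[gi]]
      ex <- GenomicRanges::reduce(unlist(evidence[g], use.names = FALSE))
      mem <- sort(evNames[g])
      flcMem <- mem[!is.na(type[mem]) & type[mem] == "FLC"]
      iso <- if (length(flcMem))
        length(unique(vapply(blocks[flcMem], exonChainSignature,
                             character(1)))) else 0L
      aExons[[gi]] <- ex
      aMembers[[gi]] <- mem
      aRows[[gi]] <- data.frame(
        locus_id = sprintf("g%04d", gi), class = "A",
        chromosome = as.character(seqnames(ex))[1L],
        strand = as.character(strand(ex))[1L],
        start = min(start(ex)), end = max(end(ex)),
        n_members = length(mem), isoform_count = iso,
        stringsAsFactors = FALSE)
    }
  }

  # attach mapped ESTs overlapping a class-A locus (same strand, >=1 bp exon
  # overlap)
  estToA <- rep(NA_integer_, length(estIds))
  if (length(estIds) && nA > 0L) {
    aU <- GRangesList(aExons)
    uA <- unlist(aU, use.names = FALSE)
    ownerA <- rep(seq_len(nA), lengths(aU))
    uE <- unlist(blocks[estIds], use.names = FALSE)
    ownerE <- rep(seq_along(estIds), lengths(blocks[estIds]))
    hits <- GenomicRanges::findOverlaps(uE, uA, ignore.strand = FALSE)
    if (length(hits)) {
      e <- ownerE[S4Vectors::queryHits(hits)]
      a <- ownerA[S4Vectors::subjectHits(hits)]
      first <- !duplicated(e)
      estToA[e[first]] <- a[first]
    }
  }
  for (k in which(!is.na(estToA))) {
    gi <- estToA[k]
    aMembers[[gi]] <- sort(c(aMembers[[gi]], estIds[k]))
    aRows[[gi]]$n_members <- aRows[[gi]]$n_members + 1L
    addAssign(estIds[k], "EST", aRows[[gi]]$locus_id, "A")
  }
  for (gi in seq_len(nA)) {
    for (mid in setdiff(aMembers[[gi]], estIds))
      addAssign(mid, if (mid %in% names(models)) "model" else type[[mid]],
                aRows[[gi]]$locus_id, "A")
  }

  # ---- class B: remaining mapped ESTs ----
  bIds <- estIds[is.na(estToA)]
  bExons <- list(); bMembers <- list(); bRows <- list()
  if (length(bIds)) {
    compB <- exonOverlapComponents(blocks[bIds])
    ord <- order(vapply(split(bIds, compB), min, character(1)))
    groups <- split(seq_along(bIds), compB)[ord]
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      ex <- GenomicRanges::reduce(unlist(blocks[bIds[g]], use.names = FALSE))
      mem <- sort(bIds[g])
      bExons[[gi]] <- ex
      bMembers[[gi]] <- mem
      bRows[[gi]] <- data.frame(
        locus_id = sprintf("e%04d", gi), class = "B",
        chromosome = as.character(seqnames(ex))[1L],
        strand = as.character(strand(ex))[1L],
        start = min(start(ex)), end = max(end(ex)),
        n_members = length(mem), isoform_count = 0L,
        stringsAsFactors = FALSE)
      for (mid in mem) addAssign(mid, "EST", bRows[[gi]]$locus_id, "B")
    }
  }

  # ---- class C: unmapped transcripts, sequence-linkage clusters ----
  cMembers <- list(); cRows <- list()
  if (length(unmapped)) {
    cseqs <- asNamedCharacter(transcripts)[match(unmapped, md$clone_id)]
    names(cseqs) <- unmapped
    ctg <- clusterEsts(cseqs, rule)
    for (gi in seq_len(nrow(ctg))) {
      mem <- ctg$members[[gi]]
      cMembers[[gi]] <- mem
      cRows[[gi]] <- data.frame(
        locus_id = sprintf("c%04d", gi), class = "C",
        chromosome = NA_character_, strand = NA_character_,
        start = NA_integer_, end = NA_integer_,
        n_members = length(mem), isoform_count = 0L,
        stringsAsFactors = FALSE)
      for (mid in mem) addAssign(mid, type[[mid]], cRows[[gi]]$locus_id, "C")
    }
  }

  for (id in chimeric)
    addAssign(id, type[[id]], NA_character_, "chimeric_excluded")

  loci <- do.call(rbind, c(aRows, bRows, cRows))
  if (is.null(loci))
    loci <- data.frame(locus_id = character(), class = character(),
                       chromosome = character(), strand = character(),
                       start = integer(), end = integer(),
                       n_members = integer(), isoform_count = integer(),
                       stringsAsFactors = FALSE)
  exons <- GRangesList(c(aExons, bExons))
  if (length(exons) < nrow(loci))
    exons <- c(exons, GRangesList(replicate(nrow(loci) - length(exons),
                                            GRanges())))
  names(exons) <- loci$locus_id
  asg <- if (length(assignment)) do.call(rbind, assignment) else
    data.frame(id = character(), kind = character(), locus_id = character(),
               class = character(), stringsAsFactors = FALSE)
  new("GeneLocusSet",
      loci = DataFrame(loci),
      members = CharacterList(c(aMembers, bMembers, cMembers)),
      exons = exons,
      assignment = DataFrame(asg))
}

#' Detect the longest forward-strand open reading frame
#'
#' Scans the three forward reading frames for the longest ATG-initiated,
#' stop-terminated reading frame; reports it only when the encoded protein
#' (excluding the stop) is at least `minOrfAa` amino acids, i.e. strictly
#' longer than `minOrfAa - 1`. The default of 31 implements "longer than
#' 30 amino acids". FL-cDNA clones are oriented, so reverse-strand frames
#' are not searched.
#'
#' @param sequence character or `DNAString`.
#' @param minOrfAa minimum protein length in amino acids (default 31).
#' @return list `(start, end, frame, aa_length)` in 1-based nucleotide
#'   coordinates (end = last base of the stop codon), or `NULL`.
#' @export
detectOrf <- function(sequence, minOrfAa = 31L) {
  s <- as.character(sequence)
  L <- nchar(s)
  best <- NULL
  for (frame in 0:2) {
    ncod <- (L - frame) %/% 3L
    if (ncod < 2L) next
    starts <- frame + 1L + 3L * (0:(ncod - 1L))
    codons <- substring(s, starts, starts + 2L)
    isStart <- codons == "ATG"
    isStop <- codons %in% c("TAA", "TAG", "TGA")
    stopPos <- which(isStop)
    for (a in which(isStart)) {
      nxt <- stopPos[stopPos > a]
      if (!length(nxt)) next
      aa <- nxt[1L] - a
      if (aa >= minOrfAa && (is.null(best) || aa > best$aa_length)) {
        best <- list(start = starts[a], end = starts[nxt[1L]] + 2L,
                     frame = frame, aa_length = aa)
      }
    }
  }
  best
}

#' Detect a terminal poly-A tail
#'
#' TRUE when the final 15 nt of the sequence contain a run of at least 10
#' A's broken by at most one non-A base.
#'
#' @param sequence character or `DNAString`.
#' @return logical.
#' @export
detectPolya <- function(sequence) {
  s <- as.character(sequence)
  L <- nchar(s)
  if (L < 10L) return(FALSE)
  tail15 <- substr(s, max(1L, L - 14L), L)
  b <- strsplit(tail15, "")[[1]] == "A"
  n <- length(b)
  for (st in seq_len(n - 9L)) {
    for (en in seq(st + 9L, n)) {
      if (sum(!b[st:en]) <= 1L && sum(b[st:en]) >= 10L) return(TRUE)
    }
  }
  FALSE
}

#' Annotate transcript features (ORF and poly-A)
#'
#' @param transcripts a [TranscriptSet-class] or named `DNAStringSet`.
#' @param minOrfAa passed to [detectOrf()].
#' @return `DataFrame` with `transcript_id`, `orf_start`, `orf_end`,
#'   `orf_frame`, `aa_length`, `has_orf`, `has_polya`.
#' @export
transcriptFeatures <- function(transcripts, minOrfAa = 31L) {
  seqs <- asNamedCharacter(transcripts)
  ids <- names(seqs)
  orfs <- lapply(seqs, detectOrf, minOrfAa = minOrfAa)
  DataFrame(
    transcript_id = ids,
    orf_start = vapply(orfs, function(o) if (is.null(o)) NA_integer_ else o$start, integer(1)),
    orf_end = vapply(orfs, function(o) if (is.null(o)) NA_integer_ else o$end, integer(1)),
    orf_frame = vapply(orfs, function(o) if (is.null(o)) NA_integer_ else o$frame, integer(1)),
    aa_length = vapply(orfs, function(o) if (is.null(o)) NA_integer_ else o$aa_length, integer(1)),
    has_orf = !vapply(orfs, is.null, logical(1)),
    has_polya = vapply(seqs, detectPolya, logical(1), USE.NAMES = FALSE))
}

#' Exon/intron statistics of a set of transcript structures
#'
#' Computes the standard structure table: total exon count, exons per
#' transcript (mean/median), and max/mean/median/min of exon and intron
#' lengths. Introns are the gaps between consecutive exon blocks of one
#' transcript; single-exon transcripts contribute no intron.
#'
#' @param structures `GRangesList` of exon blocks per transcript (e.g.
#'   `exonBlocks()` of mapped transcripts, or truth exons).
#' @return list with elements `n_transcripts`, `total_exons`,
#'   `exons_per_transcript` (mean, median), `exon_length` and
#'   `intron_length` (max, mean, median, min; all `NA` when no intron).
#' @export
exonIntronStats <- function(structures) {
  nEx <- lengths(structures)
  u <- unlist(structures, use.names = FALSE)
  exLen <- width(u)
  intronLens <- unlist(lapply(structures, function(gr) {
    if (length(gr) < 2L) return(numeric(0))
    gr <- sort(gr)
    start(gr)[-1L] - end(gr)[-length(gr)] - 1L
  }), use.names = FALSE)
  s4 <- function(x) if (length(x))
    list(max = max(x), mean = mean(x), median = stats::median(x), min = min(x))
  else list(max = NA_real_, mean = NA_real_, median = NA_real_, min = NA_real_)
  list(n_transcripts = length(structures),
       total_exons = sum(nEx),
       exons_per_transcript = list(mean = if (length(nEx)) mean(nEx) else NA_real_,
                                   median = if (length(nEx)) stats::median(nEx) else NA_real_),
       exon_length = s4(exLen),
       intron_length = s4(intronLens))
}
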