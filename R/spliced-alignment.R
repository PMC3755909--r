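# Transcript-to-genome spliced mapping: an exact k-mer seed prefilter to
# locate candidate genomic windows (standing in for the BLASTN prescreen of
# the original protocol), a splice-aware local DP inside each window, and
# chimera classification from the window placements.

#' Locate candidate genomic windows for transcripts
#'
#' Samples k-mer seeds along each transcript (both orientations), finds
#' their exact genomic matches, and chains hits on the same chromosome and
#' orientation whose genomic gap is at most `maxIntron` into candidate
#' windows. Each window is extended to cover the unseeded remainder of the
#' transcript and padded by `windowPad`. Transcripts shorter than `seedK`
#' or without any genomic seed hit get no window and are provisionally
#' unmapped.
#'
#' @param transcripts named `DNAStringSet`/[TranscriptSet-class] or named
#'   character vector.
#' @param genome named `DNAStringSet` of chromosomes.
#' @param thresholds a [MappingThresholds-class].
#' @return data.frame with columns `transcript_id`, `chromosome`, `strand`,
#'   `wstart`, `wend`, `n_hits`.
#' @export
seedPrefilter <- function(transcripts, genome, thresholds = MappingThresholds()) {
  seqs <- asNamedCharacter(transcripts)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("t%05d", seq_along(seqs))
  k <- thresholds@seedK
  stride <- thresholds@seedStride
  chromLens <- setNames(Biostrings::width(genome), names(genome))

  seedSeq <- character(0); seedTid <- integer(0)
  seedOri <- character(0); seedTpos <- integer(0)
  tooShort <- character(0)
  for (i in seq_along(seqs)) {
    L <- nchar(seqs[i])
    if (L < k) { tooShort <- c(tooShort, ids[i]); next }
    starts <- unique(c(seq(1L, L - k + 1L, by = stride), L - k + 1L))
    for (ori in c("+", "-")) {
      s <- if (ori == "+") seqs[i] else
        as.character(reverseComplement(DNAString(seqs[i])))
      km <- substring(s, starts, starts + k - 1L)
      ok <- !grepl("[^ACGT]", km)
      seedSeq <- c(seedSeq, km[ok])
      seedTid <- c(seedTid, rep(i, sum(ok)))
      seedOri <- c(seedOri, rep(ori, sum(ok)))
      seedTpos <- c(seedTpos, starts[ok])
    }
  }
  if (length(tooShort))
    warning("transcript(s) shorter than seedK left unmapped: ",
            paste(utils::head(tooShort, 5L), collapse = ", "))
  empty <- data.frame(transcript_id = character(), chromosome = character(),
                      strand = character(), wstart = integer(),
                      wend = integer(), n_hits = integer(),
                      stringsAsFactors = FALSE)
  if (!length(seedSeq)) return(empty)

  pd <- Biostrings::PDict(DNAStringSet(seedSeq))
  hits <- list(); nh <- 0L
  for (cn in names(genome)) {
    mi <- Biostrings::matchPDict(pd, genome[[cn]])
    st <- Biostrings::startIndex(mi)
    len <- lengths(st)
    len[len > 50L] <- 0L # repeat-derived seeds are uninformative
    use <- which(len > 0L)
    if (!length(use)) next
    nh <- nh + 1L
    hits[[nh]] <- data.frame(
      pat = rep(use, len[use]),
      gpos = unlist(st[use], use.names = FALSE),
      chrom = cn, stringsAsFactors = FALSE)
  }
  if (!nh) return(empty)
  hits <- do.call(rbind, hits)
  hits$tid <- seedTid[hits$pat]
  hits$ori <- seedOri[hits$pat]
  hits$tpos <- seedTpos[hits$pat]

  out <- list(); no <- 0L
  key <- paste(hits$tid, hits$ori, hits$chrom)
  for (grp in split(seq_len(nrow(hits)), key)) {
    h <- hits[grp, ]
    h <- h[order(h$gpos), ]
    brk <- c(0L, which(diff(h$gpos) > thresholds@maxIntron), nrow(h))
    tid <- h$tid[1L]
    L <- nchar(seqs[tid])
    for (b in seq_len(length(brk) - 1L)) {
      hh <- h[(brk[b] + 1L):brk[b + 1L], ]
      # pad fully only on sides with unseeded transcript sequence (a missed
      # terminal exon may sit beyond a long intron); a side whose terminal
      # seed hit needs only slack for alignment wiggle
      u5 <- min(hh$tpos) - 1L
      u3 <- L - (max(hh$tpos) + k - 1L)
      # tpos is already in the aligned orientation, so u5 is the genomic
      # left side for both strands
      pad5 <- if (u5 <= 24L) 200L + 8L * u5 else thresholds@windowPad
      pad3 <- if (u3 <= 24L) 200L + 8L * u3 else thresholds@windowPad
      ws <- max(1L, min(hh$gpos - hh$tpos + 1L) - pad5)
      we <- min(chromLens[[hh$chrom[1L]]],
                max(hh$gpos + (L - hh$tpos)) + pad3)
      no <- no + 1L
      out[[no]] <- data.frame(
        transcript_id = ids[tid], chromosome = hh$chrom[1L],
        strand = h$ori[1L], wstart = as.integer(ws), wend = as.integer(we),
        n_hits = nrow(hh), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(match(res$transcript_id, ids), res$chromosome, res$wstart), ,
      drop = FALSE]
}

#' Splice-aware alignment of one transcript in one genomic window
#'
#' Runs the three-state local dynamic program (match/mismatch with affine
#' short gaps plus an intron state with a fixed penalty, reduced for
#' GT...AG flanks) of the transcript -- reverse-complemented when
#' `strand == "-"` -- against the window sequence, and reports exon blocks
#' in genome coordinates, percent identity over aligned exon columns, and
#' coverage (aligned transcript length over total length).
#'
#' @param tseq transcript sequence (character or `DNAString`).
#' @param wseq window sequence (plus-strand genomic, character or
#'   `DNAString`).
#' @param wstart genomic start coordinate of the window (1-based).
#' @param strand `"+"` or `"-"`: orientation of the transcript relative to
#'   the plus strand.
#' @param thresholds a [MappingThresholds-class].
#' @return list with `score`, `blocks` (data.frame `gstart`, `gend`,
#'   `tstart`, `tend`; transcript coordinates always refer to the input
#'   transcript's own 5' end), `identity`, `coverage`.
#' @export
spliceAlign <- function(tseq, wseq, wstart = 1L, strand = "+",
                        thresholds = MappingThresholds()) {
  tseq <- as.character(tseq); wseq <- as.character(wseq)
  L <- nchar(tseq)
  W <- nchar(wseq)
  # minus strand: align the transcript as-is against the reverse-complement
  # of the window, so canonical introns read GT...AG in the DP's frame
  gq <- if (strand == "-")
    as.character(reverseComplement(DNAString(wseq))) else wseq
  r <- .spliceAlignCpp(tseq, gq,
                       thresholds@match, thresholds@mismatch,
                       thresholds@gapOpen, thresholds@gapExtend,
                       thresholds@intronPenalty, thresholds@spliceBonus,
                       thresholds@minIntron)
  b <- as.data.frame(r$blocks)
  if (nrow(b)) {
    if (strand == "-") {
      gs <- W - b$gend + 1L
      ge <- W - b$gstart + 1L
      b$gstart <- gs; b$gend <- ge
      b <- b[order(b$gstart), , drop = FALSE]
    }
    b$gstart <- b$gstart + wstart - 1L
    b$gend <- b$gend + wstart - 1L
  }
  cols <- r$matches + r$mismatches + r$gaps
  list(score = r$score, blocks = b,
       identity = if (cols > 0L) r$matches / cols else 0,
       coverage = if (L > 0L) r$aligned_t / L else 0)
}

#' Classify a transcript's window placements as mapped, chimeric or unmapped
#'
#' A clone is considered completely ("perfectly") placed when some subset
#' of its aligned segments on one chromosome and strand, spanning at most
#' `chimeraWindow` of genome, jointly covers at least `chimeraCoverage` of
#' the transcript. A clone with no complete placement whose segments
#' jointly reach `chimeraCoverage` only across incompatible loci is
#' chimeric. Otherwise the ordinary identity/coverage thresholds decide
#' between mapped and unmapped.
#'
#' @param segments data.frame of identity-passing window alignments with
#'   columns `chromosome`, `strand`, `gstart`, `gend`, `tstart`, `tend`
#'   (transcript extent of the segment).
#' @param transcriptLength total transcript length (bp).
#' @param thresholds a [MappingThresholds-class].
#' @return one of `"mapped"`, `"chimeric"`, `"unmapped_low_coverage"`.
#' @export
classifyChimera <- function(segments, transcriptLength,
                            thresholds = MappingThresholds()) {
  if (!nrow(segments)) return("unmapped_low_coverage")
  unionCov <- function(s, e) {
    o <- order(s)
    s <- s[o]; e <- e[o]
    tot <- 0; curS <- s[1L]; curE <- e[1L]
    for (i in seq_along(s)[-1L]) {
      if (s[i] <= curE + 1L) curE <- max(curE, e[i])
      else { tot <- tot + curE - curS + 1L; curS <- s[i]; curE <- e[i] }
    }
    (tot + curE - curS + 1L) / transcriptLength
  }
  bestPlaced <- 0
  for (grp in split(segments, paste(segments$chromosome, segments$strand))) {
    for (a in seq_len(nrow(grp))) {
      lim <- grp$gstart[a] + thresholds@chimeraWindow
      sub <- grp[grp$gstart >= grp$gstart[a] & grp$gend <= lim, , drop = FALSE]
      if (nrow(sub))
        bestPlaced <- max(bestPlaced, unionCov(sub$tstart, sub$tend))
    }
  }
  if (bestPlaced >= thresholds@chimeraCoverage) return("mapped")
  joint <- unionCov(segments$tstart, segments$tend)
  if (joint >= thresholds@chimeraCoverage) return("chimeric")
  if (bestPlaced >= thresholds@minCoverage) return("mapped")
  "unmapped_low_coverage"
}

#' Map transcripts to a genome
#'
#' The full mapping pipeline: seed prefilter, splice-aware DP in each
#' candidate window (at most `maxWindows` highest-seed-count windows per
#' transcript), chimera classification, and status assignment. A
#' transcript with no seed window or whose best alignment falls below the
#' identity threshold is `unmapped_low_homology`; below the coverage
#' threshold, `unmapped_low_coverage`. Among equally scoring placements
#' the forward strand, then the lexicographically first locus, wins.
#'
#' @param transcripts named `DNAStringSet`/[TranscriptSet-class].
#' @param genome named `DNAStringSet`.
#' @param thresholds a [MappingThresholds-class].
#' @param maxWindows alignments attempted per transcript (default 4).
#' @return a [SplicedAlignmentSet-class]; for chimeric transcripts the
#'   blocks of all contributing placements are retained.
#' @export
mapTranscripts <- function(transcripts, genome,
                           thresholds = MappingThresholds(),
                           maxWindows = 4L) {
  seqs <- asNamedCharacter(transcripts)
  ids <- names(seqs)
  if (is.null(ids)) { ids <- sprintf("t%05d", seq_along(seqs)); names(seqs) <- ids }
  # poly-A tails are masked (not trimmed) so they soft-clip cleanly without
  # seeding spurious terminal introns; lengths and coordinates are unchanged
  seqs <- vapply(seqs, maskPolyATail, character(1))
  win <- seedPrefilter(seqs, genome, thresholds)
  chromChar <- setNames(as.character(genome), names(genome))

  n <- length(seqs)
  info <- data.frame(transcript_id = ids, chromosome = NA_character_,
                     strand = NA_character_, identity = NA_real_,
                     coverage = NA_real_, n_blocks = 0L, score = 0L,
                     status = "unmapped_low_homology",
                     stringsAsFactors = FALSE)
  blocksList <- setNames(vector("list", n), ids)
  winByT <- split(win, win$transcript_id)

  for (i in seq_len(n)) {
    tid <- ids[i]
    L <- nchar(seqs[i])
    blocksList[[i]] <- GRanges()
    w <- winByT[[tid]]
    if (is.null(w) || !nrow(w)) next
    if (nrow(w) > maxWindows)
      w <- w[order(-w$n_hits, w$chromosome, w$wstart), ][seq_len(maxWindows), ]
    w <- w[order(w$strand, w$chromosome, w$wstart), ] # "+" before "-"
    alns <- vector("list", nrow(w))
    for (r in seq_len(nrow(w))) {
      ws <- substr(chromChar[[w$chromosome[r]]], w$wstart[r], w$wend[r])
      alns[[r]] <- spliceAlign(seqs[i], ws, w$wstart[r], w$strand[r],
                               thresholds)
    }
    sc <- vapply(alns, `[[`, numeric(1), "score")
    keep <- which(sc > 0)
    if (!length(keep)) next
    bestIdx <- keep[which.max(sc[keep])] # window order is the tie-break
    best <- alns[[bestIdx]]

    idnOK <- which(vapply(alns, `[[`, numeric(1), "identity")
                   >= thresholds@minIdentity & sc > 0)
    if (!length(idnOK)) {
      info$status[i] <- "unmapped_low_homology"
      info$chromosome[i] <- w$chromosome[bestIdx]
      info$strand[i] <- w$strand[bestIdx]
      info$identity[i] <- best$identity
      info$coverage[i] <- best$coverage
      info$score[i] <- best$score
      next
    }
    segs <- do.call(rbind, lapply(idnOK, function(r) {
      b <- alns[[r]]$blocks
      data.frame(chromosome = w$chromosome[r], strand = w$strand[r],
                 gstart = min(b$gstart), gend = max(b$gend),
                 tstart = min(b$tstart), tend = max(b$tend),
                 stringsAsFactors = FALSE)
    }))
    st <- classifyChimera(segs, L, thresholds)
    if (st == "mapped" && best$identity < thresholds@minIdentity)
      st <- "unmapped_low_homology"
    info$chromosome[i] <- w$chromosome[bestIdx]
    info$strand[i] <- w$strand[bestIdx]
    info$identity[i] <- best$identity
    info$coverage[i] <- best$coverage
    info$score[i] <- best$score
    info$n_blocks[i] <- nrow(best$blocks)
    info$status[i] <- st
    if (st == "chimeric") {
      grl <- suppressWarnings(do.call(c, lapply(idnOK, function(r) {
        b <- alns[[r]]$blocks
        GRanges(w$chromosome[r], IRanges(b$gstart, b$gend),
                strand = w$strand[r], tstart = b$tstart, tend = b$tend)
      })))
      blocksList[[i]] <- grl
    } else {
      b <- best$blocks
      blocksList[[i]] <- GRanges(w$chromosome[bestIdx],
                                 IRanges(b$gstart, b$gend),
                                 strand = w$strand[bestIdx],
                                 tstart = b$tstart, tend = b$tend)
    }
  }
  grl <- GRangesList(blocksList)
  new("SplicedAlignmentSet", info = DataFrame(info), blocks = grl)
}
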