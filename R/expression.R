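# Per-locus EST expression profiles and tissue-specificity calls.

#' Count EST support per locus and tissue
#'
#' Pools the ESTs assigned to each locus over the libraries of each
#' tissue, per the library manifest. Developmental stages of the same
#' tissue (multiple libraries with one tissue label) are pooled, so calls
#' are tissue-level, not stage-level.
#'
#' @param geneSets a [GeneLocusSet-class] (its assignment table links ESTs
#'   to loci).
#' @param transcripts the [TranscriptSet-class]; EST records must carry a
#'   `library` metadata column.
#' @param manifest data.frame with columns `library`, `tissue`.
#' @return integer matrix, loci x tissues (all loci, including those with
#'   no EST support).
#' @export
countEstSupport <- function(geneSets, transcripts, manifest) {
  stopifnot(is(geneSets, "GeneLocusSet"))
  asg <- as.data.frame(locusAssignment(geneSets))
  md <- as.data.frame(mcols(transcripts))
  tissues <- unique(manifest$tissue)
  loci <- lociTable(geneSets)$locus_id
  m <- matrix(0L, nrow = length(loci), ncol = length(tissues),
              dimnames = list(loci, tissues))
  ests <- asg[asg$kind == "EST" & !is.na(asg$locus_id), , drop = FALSE]
  if (!nrow(ests)) return(m)
  lib <- md$library[match(ests$id, md$clone_id)]
  unknown <- !(lib %in% manifest$library)
  if (any(unknown))
    stop("EST(s) cite a library missing from the manifest: ",
         paste(utils::head(ests$id[unknown], 5L), collapse = ", "))
  tis <- manifest$tissue[match(lib, manifest$library)]
  tab <- table(factor(ests$locus_id, levels = loci),
               factor(tis, levels = tissues))
  m[] <- as.integer(tab)
  m
}

#' Call tissue-specific loci from expression profiles
#'
#' A locus is tissue-specific when it has strictly more than `minCopies`
#' identical ESTs in total and strictly more than `minFraction` of them
#' derive from a single tissue (equivalently, fewer than
#' `1 - minFraction` from all other tissues combined). Both inequalities
#' are strict: a locus at exactly 90% focal fraction, or with exactly
#' `minCopies` ESTs, is not called.
#'
#' @param profile integer matrix loci x tissues (from [countEstSupport()]),
#'   or a single named count vector.
#' @param minCopies copy threshold, default 3 ("more than three copies").
#' @param minFraction focal-tissue fraction threshold, default 0.9.
#' @return `DataFrame` with `locus_id`, `total`, `specific_tissue` (`NA`
#'   when not specific) and `focal_fraction`.
#' @export
callTissueSpecific <- function(profile, minCopies = 3L, minFraction = 0.9) {
  if (is.null(dim(profile)))
    profile <- matrix(profile, nrow = 1,
                      dimnames = list("locus", names(profile)))
  total <- rowSums(profile)
  top <- max.col(profile, ties.method = "first")
  topCount <- profile[cbind(seq_len(nrow(profile)), top)]
  frac <- ifelse(total > 0, topCount / total, 0)
  specific <- total > minCopies & frac > minFraction
  DataFrame(locus_id = rownames(profile),
            total = as.integer(total),
            specific_tissue = unname(ifelse(specific, colnames(profile)[top],
                                            NA_character_)),
            focal_fraction = as.numeric(unname(frac)))
}

#' Tissue-call table with genomic coordinates
#'
#' Joins tissue-specificity calls onto locus coordinates, producing the
#' table the cluster analyses consume. Class-C loci (no coordinates) are
#' dropped.
#'
#' @param geneSets a [GeneLocusSet-class].
#' @param calls result of [callTissueSpecific()].
#' @return data.frame `locus_id`, `chromosome`, `start`, `end`,
#'   `specific_tissue`.
#' @export
tissueCallTable <- function(geneSets, calls) {
  lo <- as.data.frame(lociTable(geneSets))
  df <- merge(lo[, c("locus_id", "chromosome", "start", "end")],
              as.data.frame(calls)[, c("locus_id", "specific_tissue")],
              by = "locus_id", all.x = TRUE)
  df <- df[!is.na(df$chromosome), , drop = FALSE]
  df[order(df$chromosome, df$start), , drop = FALSE]
}
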