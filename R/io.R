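# Writers/readers for the pipeline's result tables: gene sets as GFF3 +
# membership TSV, expression matrices and cluster summaries as TSV,
# clusters as BED, ortholog tables as TSV.

#' Write a gene locus set to GFF3 and TSV
#'
#' Emits `gene_sets.gff3` (gene and exon features of the class-A/B loci,
#' 1-based inclusive) and `gene_sets.tsv` (one row per locus of any
#' class: id, class, coordinates, member ids, and, when transcript
#' features are supplied, whether any FL-cDNA member has an ORF or a
#' poly-A tail).
#'
#' @param geneSets a [GeneLocusSet-class].
#' @param dir output directory (created if needed).
#' @param features optional result of [transcriptFeatures()].
#' @return `dir`, invisibly.
#' @export
writeGeneSets <- function(geneSets, dir, features = NULL) {
  stopifnot(is(geneSets, "GeneLocusSet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lo <- as.data.frame(lociTable(geneSets))
  ex <- locusExons(geneSets)
  mapped <- which(lo$class %in% c("A", "B"))
  if (length(mapped)) {
    gf <- GRanges(lo$chromosome[mapped],
                  IRanges(lo$start[mapped], lo$end[mapped]),
                  strand = lo$strand[mapped],
                  type = "gene", ID = lo$locus_id[mapped],
                  Parent = NA_character_)
    exu <- unlist(ex[mapped], use.names = FALSE)
    owner <- rep(lo$locus_id[mapped], lengths(ex[mapped]))
    eff <- GRanges(seqnames(exu), IRanges(start(exu), end(exu)),
                   strand = strand(exu), type = "exon",
                   ID = NA_character_, Parent = owner)
    rtracklayer::export(sort(c(gf, eff), ignore.strand = TRUE),
                        file.path(dir, "gene_sets.gff3"), format = "gff3")
  }
  memb <- vapply(locusMembers(geneSets), paste, character(1), collapse = ",")
  tab <- cbind(lo, members = unname(memb))
  if (!is.null(features)) {
    fdf <- as.data.frame(features)
    hasOrf <- vapply(locusMembers(geneSets), function(m)
      any(fdf$has_orf[fdf$transcript_id %in% m]), logical(1))
    hasPolya <- vapply(locusMembers(geneSets), function(m)
      any(fdf$has_polya[fdf$transcript_id %in% m]), logical(1))
    tab$has_orf <- unname(hasOrf)
    tab$has_polya <- unname(hasPolya)
  }
  write.table(tab, file.path(dir, "gene_sets.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write an expression profile matrix as TSV
#'
#' @param profile loci x tissues matrix from [countEstSupport()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeExpressionProfile <- function(profile, path) {
  df <- data.frame(locus_id = rownames(profile), profile,
                   check.names = FALSE, row.names = NULL)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write detected gene clusters as BED and a summary TSV
#'
#' The BED file (0-based half-open, per the format) carries one record
#' per cluster named `tissue|cluster_id`; the TSV is the per-tissue
#' summary of [summarizeClusters()].
#'
#' @param clusters result of [detectClusters()].
#' @param calls the tissue-call table the clusters came from.
#' @param dir output directory.
#' @param duplicatedIds passed to [summarizeClusters()].
#' @return `dir`, invisibly.
#' @export
writeClusters <- function(clusters, calls, dir,
                          duplicatedIds = character(0)) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (nrow(clusters)) {
    gr <- GRanges(clusters$chromosome,
                  IRanges(clusters$start, clusters$end))
    gr$name <- paste(clusters$tissue, clusters$cluster_id, sep = "|")
    gr$score <- clusters$n_members
    rtracklayer::export(gr, file.path(dir, "clusters.bed"), format = "BED")
  } else {
    file.create(file.path(dir, "clusters.bed"))
  }
  write.table(summarizeClusters(calls, clusters, duplicatedIds),
              file.path(dir, "cluster_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read an ortholog-group membership table
#'
#' Expects a TSV with columns `group_id`, `species_id`, `gene_id` (with
#' or without a header line).
#'
#' @param path input file.
#' @return data.frame with the three columns.
#' @export
readOrthologTable <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  hasHeader <- identical(first, c("group_id", "species_id", "gene_id"))
  df <- read.delim(path, header = hasHeader, stringsAsFactors = FALSE)
  if (!hasHeader) names(df) <- c("group_id", "species_id", "gene_id")
  df
}
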