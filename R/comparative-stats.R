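# Ortholog-group summaries and correlation helpers for cross-species
# comparison of the gene build.

#' Categorize ortholog groups by species composition
#'
#' Assigns each group exactly one category from its set of represented
#' species: `species_specific` (one species), `lepidoptera_specific`
#' (two or more species, all within the lepidopteran set),
#' `insect_common` (every species of the insect set present; subtype
#' `1:1` when each has exactly one gene, else `N:N`), and `other`.
#' Species sets come from configuration, not hard-coding, so reduced
#' synthetic species universes work unchanged.
#'
#' @param table data.frame with columns `group_id`, `species_id`,
#'   `gene_id`; a gene may appear in at most one group.
#' @param insectSet character vector of species defining "insect-common".
#' @param lepidopteraSet character vector of lepidopteran species.
#' @return `DataFrame` with `group_id`, `category`, `subtype` (`1:1`/`N:N`
#'   for insect-common, the species id for species-specific, the sorted
#'   species pair for two-species lepidopteran groups, else `NA`).
#' @export
categorizeGroups <- function(table, insectSet, lepidopteraSet) {
  stopifnot(all(c("group_id", "species_id", "gene_id") %in% names(table)))
  if (anyDuplicated(table$gene_id))
    stop("a gene appears in more than one ortholog group")
  if (!nrow(table)) stop("empty ortholog table")
  groups <- split(table, table$group_id)
  res <- lapply(groups, function(g) {
    sp <- unique(g$species_id)
    if (length(sp) == 1L)
      return(c("species_specific", sp))
    if (all(sp %in% lepidopteraSet)) {
      sub <- if (length(sp) == 2L) paste(sort(sp), collapse = "-")
             else NA_character_
      return(c("lepidoptera_specific", sub))
    }
    if (all(insectSet %in% sp)) {
      perSp <- table(g$species_id[g$species_id %in% insectSet])
      return(c("insect_common", if (all(perSp == 1L)) "1:1" else "N:N"))
    }
    c("other", NA_character_)
  })
  DataFrame(group_id = names(groups),
            category = vapply(res, `[`, character(1), 1L),
            subtype = vapply(res, `[`, character(1), 2L))
}

#' Per-species ortholog/paralog summary
#'
#' For each species and category: the number of ortholog groups in which
#' the species is represented, its gene count within them, and the
#' genes-per-group ratio (the paralog-expansion index). Also reports the
#' ratios of species-specific group counts of a reference species to each
#' other species.
#'
#' @param table data.frame `group_id`, `species_id`, `gene_id`.
#' @param categories result of [categorizeGroups()].
#' @param refSpecies species used as numerator of the species-specific
#'   group-count ratios (default: the species with the most
#'   species-specific groups).
#' @return list with `summary` (data.frame `species`, `category`,
#'   `n_groups`, `n_genes`, `genes_per_group`) and `speciesSpecificRatios`
#'   (named numeric; `NA` where the denominator is zero).
#' @export
summarizeSpecies <- function(table, categories, refSpecies = NULL) {
  cat_ <- setNames(categories$category, categories$group_id)
  table$category <- cat_[table$group_id]
  species <- sort(unique(table$species_id))
  cats <- c("insect_common", "lepidoptera_specific", "species_specific",
            "other")
  rows <- list(); n <- 0L
  for (sp in species) for (cc in cats) {
    sub <- table[table$species_id == sp & table$category == cc, , drop = FALSE]
    n <- n + 1L
    ng <- length(unique(sub$group_id))
    rows[[n]] <- data.frame(
      species = sp, category = cc, n_groups = ng, n_genes = nrow(sub),
      genes_per_group = if (ng > 0L) round(nrow(sub) / ng, 2) else NA_real_,
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, rows)
  ssCount <- vapply(species, function(sp)
    sum(summary$n_groups[summary$species == sp &
                           summary$category == "species_specific"]),
    numeric(1))
  if (is.null(refSpecies)) refSpecies <- species[which.max(ssCount)]
  others <- setdiff(species, refSpecies)
  ratios <- vapply(others, function(sp)
    if (ssCount[[sp]] > 0) ssCount[[refSpecies]] / ssCount[[sp]] else NA_real_,
    numeric(1))
  names(ratios) <- if (length(others)) paste0(refSpecies, "/", others)
                   else character(0)
  list(summary = summary, speciesSpecificRatios = ratios)
}

#' Pearson correlation with a t-distribution p-value
#'
#' Pearson's r between two numeric vectors with the two-sided p-value
#' from the t distribution on n - 2 degrees of freedom, as used when
#' relating mean intron length to genome size across species.
#'
#' @param xs,ys numeric vectors of equal length >= 3.
#' @return list `(r, p, n)`.
#' @export
pearsonCorrelation <- function(xs, ys) {
  stopifnot(length(xs) == length(ys), length(xs) >= 3L)
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
    stop("zero variance: correlation undefined")
  ct <- cor.test(xs, ys, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(xs))
}
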