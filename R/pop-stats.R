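## Allele-frequency summaries across germplasm groups and the 2x2
## market-class contingency test.

#' Integer percentage with ties rounded away from zero
#'
#' `100 * carriers / total` rounded to the nearest integer, ties away from
#' zero — the rounding under which published germplasm-survey percentages
#' (e.g. 2/41 -> 5%, 11/13 -> 85%) reproduce from their counts.
#'
#' @param carriers Non-negative count of carrier accessions.
#' @param total Positive total count.
#'
#' @return Integer percentage.
#' @export
percent <- function(carriers, total) {
  if (length(total) != 1 || is.na(total) || total < 1) {
    stop("total must be a single count >= 1")
  }
  if (any(carriers < 0) || any(carriers > total)) {
    stop("carriers must lie in [0, total]")
  }
  as.integer(floor(100 * carriers / total + 0.5))
}

#' Per-group carrier frequency of a focal allele
#'
#' Counts, per group, the accessions carrying the focal allele among
#' accessions with a non-missing genotype, and reports integer percentages
#' ([percent()]). Groups with no genotyped accession get `NA` percent.
#'
#' @param metadata `data.frame` of germplasm metadata.
#' @param focal_allele The allele whose carriers are counted (e.g. `"C"`).
#' @param genotype_col Name of the genotype column (default `"allele"`).
#' @param group_col Name of the grouping column (default `"group"`).
#' @param alleles Permitted genotype symbols (default `c("C", "A")`); `NA` or
#'   `""` denote missing. Any other symbol is an error naming the offender.
#'
#' @return A `data.frame` with columns `group`, `carriers`, `total`,
#'   `percent`.
#' @export
group_allele_frequency <- function(metadata, focal_allele,
                                   genotype_col = "allele",
                                   group_col = "group",
                                   alleles = c("C", "A")) {
  if (!genotype_col %in% names(metadata)) {
    stop("no genotype column '", genotype_col, "'")
  }
  if (!group_col %in% names(metadata)) {
    stop("no grouping column '", group_col, "'")
  }
  g <- metadata[[genotype_col]]
  g[g == ""] <- NA_character_
  unknown <- setdiff(unique(g[!is.na(g)]), alleles)
  if (length(unknown) > 0) {
    stop("unknown genotype symbol(s): ", paste(unknown, collapse = ", "))
  }
  if (!focal_allele %in% alleles) {
    stop("focal allele '", focal_allele, "' not among permitted symbols")
  }
  groups <- unique(metadata[[group_col]])
  rows <- lapply(groups, function(grp) {
    sel <- metadata[[group_col]] == grp & !is.na(g)
    total <- sum(sel)
    carriers <- sum(g[sel] == focal_allele)
    data.frame(group = grp, carriers = carriers, total = total,
               percent = if (total >= 1) percent(carriers, total) else NA_integer_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Pearson's statistic without continuity correction (the convention under
#' which a published trait-class x allele-class table of 41 varieties yields
#' 8.497), with 1 degree of freedom. A warning is emitted when any expected
#' count is below 5.
#'
#' @param table 2x2 numeric matrix of non-negative counts (rows = trait
#'   classes, columns = allele classes).
#'
#' @return A list with `statistic`, `p_value`, `df` (always 1) and
#'   `expected` (the expected-count matrix).
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("test undefined: zero row or column margin")
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected < 5)) {
    warning("expected count below 5; chi-square approximation may be poor")
  }
  ht <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic),
       p_value = unname(ht$p.value),
       df = 1L,
       expected = expected)
}
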