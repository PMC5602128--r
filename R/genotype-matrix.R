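## Genotype calls are stored as an integer matrix (accessions x sites):
## 0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternate,
## NA = missing. Sites carry VCF-style 1-based coordinates.

GT_HOM_REF <- 0L
GT_HET <- 1L
GT_HOM_ALT <- 2L

#' Construct a genotype matrix
#'
#' Container for biallelic SNP calls of a diversity panel: an accessions x
#' sites grid of genotype classes plus a site table with VCF-style
#' coordinates.
#'
#' @param calls Integer matrix, rows = accessions, columns = sites; entries
#'   0 (hom-ref), 1 (het), 2 (hom-alt) or `NA` (missing).
#' @param sites `data.frame` with columns `site_id`, `gene`, `contig`,
#'   `position` (1-based), `ref`, `alt`; one row per column of `calls`.
#' @param accessions Character vector of accession names, one per row of
#'   `calls`.
#'
#' @return An object of class `genotype_matrix` with elements `calls`,
#'   `sites` and `accessions`.
#' @export
genotype_matrix <- function(calls, sites, accessions) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  accessions <- as.character(accessions)
  required <- c("site_id", "gene", "contig", "position", "ref", "alt")
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols) > 0) {
    stop("site table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(calls) != length(accessions)) {
    stop("calls has ", nrow(calls), " rows but ", length(accessions),
         " accession names")
  }
  if (ncol(calls) != nrow(sites)) {
    stop("calls has ", ncol(calls), " columns but ", nrow(sites), " sites")
  }
  if (anyDuplicated(accessions)) stop("duplicated accession names")
  if (anyDuplicated(sites$site_id)) stop("duplicated site identifiers")
  bad <- calls[!is.na(calls)]
  if (length(bad) > 0 && !all(bad %in% c(0L, 1L, 2L))) {
    stop("genotype codes must be 0, 1, 2 or NA")
  }
  if (any(sites$position < 1)) stop("positions must be >= 1 (1-based, as in VCF)")
  if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
  dimnames(calls) <- list(accessions, sites$site_id)
  structure(list(calls = calls, sites = sites, accessions = accessions),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", length(x$accessions), " accessions x ",
      nrow(x$sites), " sites\n", sep = "")
  cat("  genes: ", paste(unique(x$sites$gene), collapse = ", "), "\n", sep = "")
  n <- length(x$calls)
  if (n > 0) {
    cat(sprintf("  calls: %.1f%% hom-ref, %.1f%% het, %.1f%% hom-alt, %.1f%% missing\n",
                100 * sum(x$calls == 0L, na.rm = TRUE) / n,
                100 * sum(x$calls == 1L, na.rm = TRUE) / n,
                100 * sum(x$calls == 2L, na.rm = TRUE) / n,
                100 * sum(is.na(x$calls)) / n))
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix
#'
#' @param x A [genotype_matrix()].
#' @param accessions Accession names or indices to keep (default all).
#' @param sites Site identifiers or indices to keep (default all).
#'
#' @return A `genotype_matrix` restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(x, accessions = NULL, sites = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  ai <- if (is.null(accessions)) seq_along(x$accessions) else {
    if (is.character(accessions)) {
      idx <- match(accessions, x$accessions)
      if (anyNA(idx)) stop("unknown accession: ",
                           paste(accessions[is.na(idx)], collapse = ", "))
      idx
    } else accessions
  }
  si <- if (is.null(sites)) seq_len(nrow(x$sites)) else {
    if (is.character(sites)) {
      idx <- match(sites, x$sites$site_id)
      if (anyNA(idx)) stop("unknown site: ",
                           paste(sites[is.na(idx)], collapse = ", "))
      idx
    } else sites
  }
  genotype_matrix(x$calls[ai, si, drop = FALSE],
                  x$sites[si, , drop = FALSE],
                  x$accessions[ai])
}
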