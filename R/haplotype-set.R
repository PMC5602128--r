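#' Construct a haplotype set
#'
#' A haplotype is an ordered allele string over a common site list, written
#' with `"R"` for the reference and `"A"` for the alternate allele, together
#' with the accessions that carry it.
#'
#' @param alleles Character vector of allele strings (all the same length,
#'   letters `R`/`A`).
#' @param names Haplotype names; defaults to `H1`, `H2`, ...
#' @param members List of character vectors (accession names per haplotype),
#'   or `NULL` for founder-style sets without membership.
#' @param site_ids Optional character vector of site identifiers the string
#'   positions refer to.
#'
#' @return An object of class `haplotype_set`: a list with `name`, `alleles`,
#'   `members` and `site_ids`.
#' @export
haplotype_set <- function(alleles, names = NULL,
                          members = NULL, site_ids = NULL) {
  alleles <- as.character(alleles)
  if (length(alleles) == 0) stop("need at least one haplotype")
  len <- unique(nchar(alleles))
  if (length(len) != 1) stop("allele strings must all have the same length")
  if (any(!grepl("^[RA]+$", alleles))) {
    stop("allele strings must use only the letters R and A")
  }
  if (is.null(names)) names <- paste0("H", seq_along(alleles))
  names <- as.character(names)
  if (length(names) != length(alleles)) stop("one name per haplotype required")
  if (anyDuplicated(names)) stop("haplotype names must be unique")
  if (is.null(members)) members <- rep(list(character(0)), length(alleles))
  if (length(members) != length(alleles)) stop("one member set per haplotype")
  all_members <- unlist(members)
  if (anyDuplicated(all_members)) {
    stop("member sets must be disjoint across haplotypes")
  }
  if (!is.null(site_ids) && length(site_ids) != len) {
    stop("site_ids length must equal the allele-string length")
  }
  structure(list(name = names, alleles = alleles,
                 members = members, site_ids = site_ids),
            class = "haplotype_set")
}

#' @export
length.haplotype_set <- function(x) length(x$alleles)

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set: ", length(x$alleles), " haplotypes over ",
      nchar(x$alleles[1]), " sites\n", sep = "")
  n <- vapply(x$members, length, integer(1))
  df <- data.frame(name = x$name, alleles = x$alleles, n_members = n)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.haplotype_set <- function(x, ...) {
  data.frame(name = x$name,
             alleles = x$alleles,
             n_members = vapply(x$members, length, integer(1)),
             members = vapply(x$members, paste, character(1), collapse = ","),
             stringsAsFactors = FALSE)
}
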