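## Core haplotype inference: MAF/homozygosity filters, per-accession allele
## reconstruction, haplotype enumeration, informative-SNP selection and
## panel typing.

#' Minor-allele frequency of one site
#'
#' Computed over allele counts of non-missing calls: a homozygote contributes
#' two copies of one allele, a heterozygote one copy of each. Returns 0 when
#' every call at the site is missing.
#'
#' @param matrix A [genotype_matrix()].
#' @param site Site identifier (character) or column index.
#'
#' @return Minor-allele frequency in `[0, 0.5]`.
#' @export
site_allele_frequency <- function(matrix, site) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  j <- if (is.character(site)) match(site, matrix$sites$site_id) else site
  if (is.na(j) || j < 1 || j > ncol(matrix$calls)) stop("unknown site: ", site)
  site_maf(matrix$calls[, j])
}

site_maf <- function(col) {
  n_ref <- 2L * sum(col == 0L, na.rm = TRUE) + sum(col == 1L, na.rm = TRUE)
  n_alt <- 2L * sum(col == 2L, na.rm = TRUE) + sum(col == 1L, na.rm = TRUE)
  tot <- n_ref + n_alt
  if (tot == 0L) return(0)
  min(n_ref, n_alt) / tot
}

all_site_mafs <- function(matrix) {
  vapply(seq_len(ncol(matrix$calls)),
         function(j) site_maf(matrix$calls[, j]), numeric(1))
}

#' Filter a panel by site MAF and accession homozygosity
#'
#' Two passes, in order: (1) drop sites whose minor-allele frequency is not
#' strictly greater than `maf_min`; (2) over the kept sites, drop accessions
#' whose fraction of homozygous calls among non-missing calls is not strictly
#' greater than `hom_min` (accessions with no non-missing call count as
#' fraction 0). Thresholds are strict because the survey design keeps sites
#' with frequency >5% and accessions with >80% homozygous calls.
#'
#' @param matrix A [genotype_matrix()].
#' @param maf_min Site minor-allele-frequency threshold (default 0.05).
#' @param hom_min Accession homozygosity threshold (default 0.80).
#'
#' @return A list with `matrix` (the filtered [genotype_matrix()]) and
#'   `report` (class `filter_report`: kept/input counts, per-site MAF and
#'   per-accession homozygosity maps).
#' @export
filter_panel <- function(matrix, maf_min = 0.05, hom_min = 0.80) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  if (length(matrix$accessions) == 0 || nrow(matrix$sites) == 0) {
    stop("empty genotype matrix")
  }
  if (maf_min < 0 || maf_min > 1 || hom_min < 0 || hom_min > 1) {
    stop("thresholds must lie in [0, 1]")
  }
  maf <- setNames(all_site_mafs(matrix), matrix$sites$site_id)
  keep_sites <- which(maf > maf_min)
  if (length(keep_sites) == 0) {
    stop("all sites filtered out at maf_min = ", maf_min)
  }
  kept <- subset_genotypes(matrix, sites = keep_sites)
  hom_frac <- apply(kept$calls, 1L, function(row) {
    nm <- sum(!is.na(row))
    if (nm == 0L) return(0)
    sum(row == 0L | row == 2L, na.rm = TRUE) / nm
  })
  hom_frac <- setNames(hom_frac, matrix$accessions)
  keep_acc <- which(hom_frac > hom_min)
  if (length(keep_acc) == 0) {
    stop("all accessions filtered out at hom_min = ", hom_min)
  }
  out <- subset_genotypes(kept, accessions = keep_acc)
  truth <- attr(matrix, "truth")
  if (!is.null(truth)) {
    attr(out, "truth") <- list(
      founder_of = truth$founder_of[out$accessions],
      clean = truth$clean[out$accessions])
  }
  report <- structure(list(
    sites_in = nrow(matrix$sites), sites_kept = length(keep_sites),
    accessions_in = length(matrix$accessions),
    accessions_kept = length(keep_acc),
    site_maf = maf, accession_homozygosity = hom_frac,
    maf_min = maf_min, hom_min = hom_min), class = "filter_report")
  list(matrix = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:\n")
  cat(sprintf("  sites:      %d -> %d (MAF > %g)\n",
              x$sites_in, x$sites_kept, x$maf_min))
  cat(sprintf("  accessions: %d -> %d (homozygosity > %g)\n",
              x$accessions_in, x$accessions_kept, x$hom_min))
  invisible(x)
}

#' Reconstruct per-accession haplotype strings
#'
#' Accessions homozygous at every site yield a complete allele string
#' (hom-ref -> `R`, hom-alt -> `A`). Accessions with any heterozygous or
#' missing call over the site list are reported as unassigned, with the
#' offending sites listed; no imputation is attempted.
#'
#' @param matrix A (typically filtered) [genotype_matrix()].
#'
#' @return A list with `strings` (named character vector, one complete allele
#'   string per resolvable accession), `unassigned` (named list of offending
#'   site-id vectors) and `site_ids`.
#' @export
reconstruct_haplotypes <- function(matrix) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  strings <- character(0)
  unassigned <- list()
  for (i in seq_along(matrix$accessions)) {
    row <- matrix$calls[i, ]
    bad <- which(is.na(row) | row == 1L)
    if (length(bad) > 0) {
      unassigned[[matrix$accessions[i]]] <- matrix$sites$site_id[bad]
    } else {
      strings[[matrix$accessions[i]]] <-
        paste(ifelse(row == 0L, "R", "A"), collapse = "")
    }
  }
  list(strings = strings, unassigned = unassigned,
       site_ids = matrix$sites$site_id)
}

#' Enumerate distinct haplotypes
#'
#' Groups identical allele strings and names the haplotypes `H1`, `H2`, ...
#' in descending member count; ties are broken by first occurrence in the
#' input order, so output is reproducible.
#'
#' @param strings Named character vector of per-accession allele strings (as
#'   from [reconstruct_haplotypes()]).
#' @param site_ids Optional site identifiers for the string positions.
#'
#' @return A [haplotype_set()] whose member sets partition the accessions.
#' @export
enumerate_haplotypes <- function(strings, site_ids = NULL) {
  if (length(strings) == 0) stop("no haplotype strings to enumerate")
  uniq <- unique(strings)
  members <- lapply(uniq, function(s) names(strings)[strings == s])
  counts <- vapply(members, length, integer(1))
  ord <- order(-counts, match(uniq, strings))  # ties: first occurrence
  haplotype_set(uniq[ord], names = paste0("H", seq_along(uniq)),
                members = members[ord], site_ids = site_ids)
}

## Accession-weighted alternate-allele frequency per site of a haplotype set.
hap_site_freqs <- function(haplotypes) {
  w <- vapply(haplotypes$members, length, integer(1))
  w[w == 0L] <- 1L                       # founder-style sets: equal weights
  mat <- do.call(rbind, strsplit(haplotypes$alleles, ""))
  alt <- colSums((mat == "A") * w) / sum(w)
  pmin(alt, 1 - alt)
}

#' Select an informative SNP subset
#'
#' Candidate sites are those with accession-weighted minor-allele frequency
#' strictly above `maf_min` (the survey used >30%). The greedy method adds,
#' at each step, the site distinguishing the largest number of
#' still-unresolved haplotype pairs (ties: larger MAF, then left-most
#' position), stopping after `k` sites or when no pair gains. The exhaustive
#' method (available for <= 12 candidates) searches all subsets of size up to
#' `k` and is intended as a small-instance oracle.
#'
#' @param haplotypes A [haplotype_set()].
#' @param maf_min Candidate minor-allele-frequency threshold (default 0.30).
#' @param k Maximum subset size.
#' @param method `"greedy"` (default) or `"exhaustive"`.
#'
#' @return A list with `sites` (selected positions, 1-based indices into the
#'   site list), `site_ids` (if the set carries them), `unresolved` (number of
#'   haplotype pairs not distinguished by the subset) and `candidates`.
#' @export
select_informative_snps <- function(haplotypes, maf_min = 0.30, k,
                                    method = c("greedy", "exhaustive")) {
  stopifnot(inherits(haplotypes, "haplotype_set"))
  method <- match.arg(method)
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  maf <- hap_site_freqs(haplotypes)
  candidates <- which(maf > maf_min)
  if (length(candidates) == 0) {
    stop("no candidate sites with MAF > ", maf_min)
  }
  mat <- do.call(rbind, strsplit(haplotypes$alleles, ""))
  n_h <- nrow(mat)
  pairs <- if (n_h >= 2) combn(n_h, 2) else matrix(integer(0), nrow = 2)
  ## distinguishes[j, p]: does candidate j split pair p?
  dist_mat <- matrix(FALSE, nrow = length(candidates), ncol = ncol(pairs))
  for (jj in seq_along(candidates)) {
    j <- candidates[jj]
    dist_mat[jj, ] <- mat[pairs[1, ], j] != mat[pairs[2, ], j]
  }
  if (method == "exhaustive") {
    if (length(candidates) > 12) {
      stop("exhaustive search limited to <= 12 candidate sites")
    }
    best <- NULL
    for (s in seq_len(min(k, length(candidates)))) {
      for (idx in as.data.frame(combn(length(candidates), s))) {
        unres <- sum(!apply(dist_mat[idx, , drop = FALSE], 2, any))
        if (is.null(best) || unres < best$unresolved) {
          best <- list(idx = idx, unresolved = unres)
        }
      }
      if (!is.null(best) && best$unresolved == 0L) break
    }
    chosen <- candidates[best$idx]
    unresolved <- best$unresolved
  } else {
    chosen <- integer(0)
    resolved <- rep(FALSE, ncol(pairs))
    remaining <- seq_along(candidates)
    while (length(chosen) < k && length(remaining) > 0) {
      gain <- vapply(remaining, function(jj) {
        sum(dist_mat[jj, ] & !resolved)
      }, integer(1))
      if (all(gain == 0L)) break
      ## ties: larger MAF, then left-most position
      best_g <- max(gain)
      tied <- remaining[gain == best_g]
      tied <- tied[order(-maf[candidates[tied]], candidates[tied])]
      pick <- tied[1]
      chosen <- c(chosen, candidates[pick])
      resolved <- resolved | dist_mat[pick, ]
      remaining <- setdiff(remaining, pick)
    }
    unresolved <- sum(!resolved)
  }
  chosen <- sort(chosen)
  list(sites = chosen,
       site_ids = if (!is.null(haplotypes$site_ids))
         haplotypes$site_ids[chosen] else NULL,
       unresolved = as.integer(unresolved),
       candidates = candidates)
}

#' Assign new accessions to reference haplotypes over a SNP subset
#'
#' Each reference haplotype is projected onto the subset; projections that
#' collide yield compound labels such as `"H5/H7"`. Each new accession that is
#' homozygous at every subset site is matched exactly against the projections;
#' unmatched strings receive fresh panel-specific names (`N1`, `N2`, ...);
#' accessions with a heterozygous or missing subset call are unassigned.
#'
#' @param new_matrix A [genotype_matrix()] of the panel to type.
#' @param subset_site_ids Site identifiers of the informative subset; must be
#'   present in both the reference set and `new_matrix`.
#' @param reference A [haplotype_set()] with `site_ids`.
#'
#' @return A `data.frame` with columns `accession`, `subset_string`, `label`,
#'   `status` (`"assigned"`, `"novel"` or `"unassigned"`).
#' @export
assign_to_haplotypes <- function(new_matrix, subset_site_ids, reference) {
  stopifnot(inherits(new_matrix, "genotype_matrix"),
            inherits(reference, "haplotype_set"))
  if (is.null(reference$site_ids)) {
    stop("reference haplotype set carries no site identifiers")
  }
  ref_idx <- match(subset_site_ids, reference$site_ids)
  if (anyNA(ref_idx)) {
    stop("subset sites missing from reference: ",
         paste(subset_site_ids[is.na(ref_idx)], collapse = ", "))
  }
  new_idx <- match(subset_site_ids, new_matrix$sites$site_id)
  if (anyNA(new_idx)) {
    stop("subset sites missing from new panel: ",
         paste(subset_site_ids[is.na(new_idx)], collapse = ", "))
  }
  proj <- vapply(strsplit(reference$alleles, ""),
                 function(ch) paste(ch[ref_idx], collapse = ""), character(1))
  label_of <- tapply(reference$name, proj, paste, collapse = "/")
  out <- data.frame(accession = new_matrix$accessions,
                    subset_string = NA_character_,
                    label = NA_character_,
                    status = "unassigned",
                    stringsAsFactors = FALSE)
  novel <- character(0)
  for (i in seq_along(new_matrix$accessions)) {
    calls <- new_matrix$calls[i, new_idx]
    if (any(is.na(calls) | calls == 1L)) next
    s <- paste(ifelse(calls == 0L, "R", "A"), collapse = "")
    out$subset_string[i] <- s
    if (s %in% names(label_of)) {
      out$label[i] <- unname(label_of[[s]])
      out$status[i] <- "assigned"
    } else {
      if (!s %in% novel) novel <- c(novel, s)
      out$label[i] <- paste0("N", match(s, novel))
      out$status[i] <- "novel"
    }
  }
  out
}

#' Run the full haplotype pipeline on a genotype matrix
#'
#' Convenience wrapper: [filter_panel()] then [reconstruct_haplotypes()] then
#' [enumerate_haplotypes()].
#'
#' @param matrix A [genotype_matrix()].
#' @param maf_min,hom_min Filter thresholds (see [filter_panel()]).
#'
#' @return A list with `haplotypes` (a [haplotype_set()]), `report`
#'   (the [filter_panel()] report), `strings` and `unassigned`.
#' @export
haplotype_pipeline <- function(matrix, maf_min = 0.05, hom_min = 0.80) {
  flt <- filter_panel(matrix, maf_min = maf_min, hom_min = hom_min)
  rec <- reconstruct_haplotypes(flt$matrix)
  haps <- enumerate_haplotypes(rec$strings, site_ids = rec$site_ids)
  list(haplotypes = haps, report = flt$report,
       strings = rec$strings, unassigned = rec$unassigned)
}
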