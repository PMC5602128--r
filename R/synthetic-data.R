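#' Simulation configuration for synthetic panels
#'
#' Describes the statistical structure of a synthetic exome-capture diversity
#' panel: a small number of founder haplotypes cloned into inbred accessions,
#' with per-call heterozygous and missing corruptions. Defaults emulate a
#' locus-scale survey of ~60 accessions typed at ~40 SNPs across 8 genes.
#'
#' @param n_founder_haplotypes Number of distinct planted haplotypes (>= 2).
#' @param n_sites Number of biallelic SNP sites (>= 1).
#' @param n_accessions Number of accessions in the panel.
#' @param het_rate Per-call probability that a (non-missing) call is turned
#'   heterozygous.
#' @param missing_rate Per-call probability that a call is set missing.
#'   Missing is applied first; a call is never both missing and heterozygous.
#' @param maf_floor Minimum planted founder-level allele frequency per site:
#'   at each site the rarer allele is carried by at least
#'   `ceiling(maf_floor * n_founder_haplotypes)` founders.
#' @param n_genes Number of gene intervals the sites are spread over.
#' @param founder_props Optional numeric vector of founder proportions
#'   (summing to 1) used when assigning accessions to founders; `NULL` gives
#'   a balanced assignment. This is how a major-haplotype share (e.g. one
#'   haplotype carried by a third of accessions) can be planted.
#' @param clean_founder_copy If `TRUE` (default), the first accession assigned
#'   to each founder is exempt from het/missing corruption, so every founder
#'   is represented by at least one fully homozygous accession.
#' @param seed Integer seed; all generators are bit-reproducible given it.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_founder_haplotypes = 14, n_sites = 39,
                       n_accessions = 58, het_rate = 0.05,
                       missing_rate = 0.05, maf_floor = 0.10,
                       n_genes = 8, founder_props = NULL,
                       clean_founder_copy = TRUE, seed = 1L) {
  cfg <- list(n_founder_haplotypes = as.integer(n_founder_haplotypes),
              n_sites = as.integer(n_sites),
              n_accessions = as.integer(n_accessions),
              het_rate = het_rate, missing_rate = missing_rate,
              maf_floor = maf_floor, n_genes = as.integer(n_genes),
              founder_props = founder_props,
              clean_founder_copy = isTRUE(clean_founder_copy),
              seed = as.integer(seed))
  probs <- c(het_rate = het_rate, missing_rate = missing_rate,
             maf_floor = maf_floor)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  }
  counts <- c(cfg$n_founder_haplotypes, cfg$n_sites, cfg$n_accessions,
              cfg$n_genes)
  if (any(is.na(counts)) || any(counts < 1)) stop("counts must be >= 1")
  if (log2(cfg$n_founder_haplotypes) > cfg$n_sites) {
    stop("infeasible: cannot place ", cfg$n_founder_haplotypes,
         " distinct haplotypes on ", cfg$n_sites, " biallelic sites")
  }
  if (!is.null(founder_props)) {
    if (length(founder_props) != cfg$n_founder_haplotypes) {
      stop("founder_props must have one entry per founder haplotype")
    }
    if (abs(sum(founder_props) - 1) > 1e-8 || any(founder_props <= 0)) {
      stop("founder_props must be positive and sum to 1")
    }
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: ", x$n_founder_haplotypes, " founders, ", x$n_sites,
      " sites, ", x$n_accessions, " accessions\n", sep = "")
  cat(sprintf("  het_rate=%.3g missing_rate=%.3g maf_floor=%.3g seed=%d\n",
              x$het_rate, x$missing_rate, x$maf_floor, x$seed))
  invisible(x)
}

#' Generate distinct, segregating founder haplotypes
#'
#' Draws `n_founder_haplotypes` pairwise-distinct allele strings over
#' `n_sites` biallelic sites such that every site segregates (both alleles
#' present among founders) and the rarer planted allele at each site is
#' carried by a fraction of founders of at least `maf_floor`.
#'
#' @param config A [sim_config()].
#'
#' @return A [haplotype_set()] with founder names `F1`, `F2`, ...
#' @export
generate_founder_haplotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_f <- config$n_founder_haplotypes
  n_s <- config$n_sites
  if (n_f < 2) stop("infeasible: sites cannot segregate with fewer than 2 founders")
  k_lo <- max(1L, as.integer(ceiling(config$maf_floor * n_f)))
  k_hi <- min(n_f - 1L, as.integer(floor((1 - config$maf_floor) * n_f)))
  if (k_lo > k_hi) {
    stop("infeasible: maf_floor=", config$maf_floor,
         " admits no segregating allele count for ", n_f, " founders")
  }
  set.seed(config$seed)
  mat <- matrix("R", nrow = n_f, ncol = n_s)
  for (j in seq_len(n_s)) {
    k <- if (k_lo == k_hi) k_lo else sample(k_lo:k_hi, 1L)
    mat[sample.int(n_f, k), j] <- "A"
  }
  ## Resolve duplicate rows by flipping single sites, keeping segregation.
  for (try in seq_len(1000L)) {
    strings <- apply(mat, 1L, paste, collapse = "")
    dup <- which(duplicated(strings))
    if (length(dup) == 0) break
    i <- dup[1L]
    for (j in sample.int(n_s, n_s)) {
      flip <- if (mat[i, j] == "R") "A" else "R"
      old <- mat[i, j]
      mat[i, j] <- flip
      col <- mat[, j]
      if (length(unique(col)) == 2L &&
          !any(apply(mat[-i, , drop = FALSE], 1L, paste, collapse = "") ==
               paste(mat[i, ], collapse = ""))) {
        break
      }
      mat[i, j] <- old
    }
  }
  strings <- apply(mat, 1L, paste, collapse = "")
  if (anyDuplicated(strings)) {
    stop("infeasible: could not generate distinct segregating haplotypes")
  }
  seg <- vapply(seq_len(n_s),
                function(j) length(unique(mat[, j])) == 2L, logical(1))
  if (!all(seg)) stop("infeasible: some sites do not segregate")
  haplotype_set(strings, names = paste0("F", seq_len(n_f)))
}

## Largest-remainder apportionment of n into length(props) integer counts.
apportion <- function(n, props) {
  raw <- n * props
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- raw - counts
    take <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[take] <- counts[take] + 1L
  }
  as.integer(counts)
}

## Deterministic synthetic site table: sites spread over n_genes contiguous
## gene blocks, VCF-style 1-based positions, random distinct ref/alt bases.
synthesize_sites <- function(n_sites, n_genes) {
  n_genes <- min(n_genes, n_sites)
  gene_of <- sort(rep_len(seq_len(n_genes), n_sites))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  pos <- integer(n_sites)
  for (g in seq_len(n_genes)) {
    idx <- which(gene_of == g)
    pos[idx] <- 100L + sort(sample.int(5000L, length(idx)))
  }
  data.frame(site_id = sprintf("S%02d", seq_len(n_sites)),
             gene = paste0("gene", gene_of),
             contig = paste0("gene", gene_of),
             position = pos,
             ref = unname(ref), alt = unname(alt),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic genotype panel from founder haplotypes
#'
#' Assigns each accession a founder haplotype (every founder used at least
#' once), converts founder alleles to homozygous calls, then corrupts calls
#' independently: with probability `missing_rate` a call becomes missing,
#' otherwise with probability `het_rate` it becomes heterozygous. The true
#' founder assignment is recorded in the `"truth"` attribute for recovery
#' testing.
#'
#' @param founders A [haplotype_set()] of founder haplotypes.
#' @param config A [sim_config()]; `n_sites` must equal the founder string
#'   length.
#'
#' @return A [genotype_matrix()] with accessions `acc01`, `acc02`, ... and an
#'   attribute `truth`: a list with `founder_of` (named character vector) and
#'   `clean` (logical vector marking accessions exempt from corruption).
#' @export
generate_panel <- function(founders, config) {
  stopifnot(inherits(founders, "haplotype_set"), inherits(config, "sim_config"))
  n_f <- length(founders)
  n_acc <- config$n_accessions
  n_s <- nchar(founders$alleles[1])
  if (n_s != config$n_sites) {
    stop("founder string length (", n_s, ") != config n_sites (",
         config$n_sites, ")")
  }
  if (n_acc < n_f) {
    stop("n_accessions (", n_acc, ") < number of founders (", n_f,
         "): cannot use every founder at least once")
  }
  set.seed(config$seed + 1L)
  props <- if (is.null(config$founder_props)) rep(1 / n_f, n_f) else config$founder_props
  counts <- apportion(n_acc, props)
  if (any(counts == 0L)) {          # coverage guarantee
    short <- which(counts == 0L)
    for (s in short) {
      donor <- which.max(counts)
      counts[donor] <- counts[donor] - 1L
      counts[s] <- 1L
    }
  }
  assignment <- sample(rep.int(seq_len(n_f), counts))
  accessions <- sprintf("acc%02d", seq_len(n_acc))
  sites <- synthesize_sites(n_s, config$n_genes)
  fmat <- do.call(rbind, strsplit(founders$alleles, ""))
  calls <- matrix(0L, nrow = n_acc, ncol = n_s)
  calls[fmat[assignment, , drop = FALSE] == "A"] <- 2L
  clean <- rep(FALSE, n_acc)
  if (config$clean_founder_copy) {
    clean[match(seq_len(n_f), assignment)] <- TRUE
  }
  u_miss <- matrix(runif(n_acc * n_s), n_acc, n_s)
  u_het <- matrix(runif(n_acc * n_s), n_acc, n_s)
  corruptible <- !clean
  miss <- corruptible & (u_miss < config$missing_rate)
  het <- corruptible & !miss & (u_het < config$het_rate)
  calls[het] <- 1L
  calls[miss] <- NA_integer_
  gm <- genotype_matrix(calls, sites, accessions)
  attr(gm, "truth") <- list(
    founder_of = setNames(founders$name[assignment], accessions),
    clean = setNames(clean, accessions))
  gm
}

#' Generate a random breeding pedigree
#'
#' Founders have unknown parents; each subsequent generation adds lines whose
#' two parents are drawn (distinct) from all earlier lines, so the pedigree is
#' acyclic by construction.
#'
#' @param n_founders Number of founder lines (>= 1).
#' @param n_generations Number of generations of crosses (>= 1).
#' @param seed Integer seed.
#' @param n_per_generation Lines created per generation (default 1 cross).
#'
#' @return A [pedigree()] object.
#' @export
generate_pedigree <- function(n_founders, n_generations, seed,
                              n_per_generation = 1L) {
  n_founders <- as.integer(n_founders)
  n_generations <- as.integer(n_generations)
  n_per_generation <- as.integer(n_per_generation)
  if (n_founders < 1 || n_generations < 1 || n_per_generation < 1) {
    stop("counts must be >= 1")
  }
  if (n_founders < 2) stop("need at least 2 founders to make a cross")
  set.seed(as.integer(seed))
  name <- paste0("FND", seq_len(n_founders))
  p1 <- rep("", n_founders)
  p2 <- rep("", n_founders)
  pool <- name
  for (g in seq_len(n_generations)) {
    for (i in seq_len(n_per_generation)) {
      parents <- sample(pool, 2L)
      child <- sprintf("G%dL%d", g, i)
      name <- c(name, child)
      p1 <- c(p1, parents[1]); p2 <- c(p2, parents[2])
    }
    pool <- name
  }
  pedigree(data.frame(name = name, parent1 = p1, parent2 = p2,
                      stringsAsFactors = FALSE))
}

#' Generate an allele pair of amplicons for CAPS assay testing
#'
#' Builds a random amplicon carrying exactly one occurrence of a restriction
#' motif that spans the SNP position; the second allele differs only at the
#' SNP base, chosen so the motif no longer matches and no new occurrence is
#' created on either strand. This emulates a restriction-site-loss CAPS
#' polymorphism.
#'
#' @param length Amplicon length in bp.
#' @param snp_offset 1-based SNP position within the amplicon.
#' @param motif IUPAC recognition motif (e.g. `"GTNNAC"`).
#' @param cut_offset Bases from the motif 5' end to the top-strand cut.
#' @param seed Integer seed.
#' @param snp_motif_index Optional index of the motif base the SNP should sit
#'   on; must be a non-degenerate base (an `N` position cannot be broken by a
#'   substitution). Default: chosen automatically.
#'
#' @return A list of class `amplicon_pair`: `allele1`, `allele2` (character
#'   sequences), and `truth` with the planted motif, its start, the SNP
#'   offset, and the expected digest fragment lengths for each allele.
#' @export
generate_amplicon_pair <- function(length, snp_offset, motif, cut_offset,
                                   seed, snp_motif_index = NULL) {
  length <- as.integer(length)
  snp_offset <- as.integer(snp_offset)
  motif <- toupper(motif)
  m <- nchar(motif)
  if (snp_offset <= 0 || snp_offset > length) stop("snp_offset out of range")
  if (m > length) stop("motif longer than amplicon")
  mchars <- strsplit(motif, "")[[1]]
  check_iupac(mchars)
  nondeg <- which(mchars %in% c("A", "C", "G", "T"))
  if (length(nondeg) == 0) {
    stop("motif '", motif, "' has no non-degenerate base; ",
         "no single substitution can break it")
  }
  if (!is.null(snp_motif_index)) {
    if (!snp_motif_index %in% nondeg) {
      stop("motif base ", snp_motif_index, " ('", mchars[snp_motif_index],
           "') is degenerate; a SNP there cannot break the site")
    }
    nondeg <- snp_motif_index
  }
  ## motif start candidates placing the SNP on a usable motif base
  starts <- snp_offset - nondeg + 1L
  ok <- starts >= 1L & starts + m - 1L <= length
  if (!any(ok)) stop("cannot place the motif over snp_offset inside the amplicon")
  starts <- starts[ok]
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  for (try in seq_len(200L)) {
    s <- if (length(starts) == 1L) starts else sample(starts, 1L)
    seq1 <- sample(bases, length, replace = TRUE)
    ## concretize the motif (degenerate positions -> random allowed base)
    inst <- vapply(mchars, function(ch) {
      allowed <- strsplit(Biostrings::IUPAC_CODE_MAP[[ch]], "")[[1]]
      if (length(allowed) == 1L) allowed else sample(allowed, 1L)
    }, character(1))
    seq1[s:(s + m - 1L)] <- inst
    a1 <- paste(seq1, collapse = "")
    if (nrow(scan_motif(a1, motif)) != 1L) next
    snp_in_motif <- snp_offset - s + 1L
    old_base <- seq1[snp_offset]
    subs <- setdiff(bases, old_base)
    ## substitution must break the motif at this position and add no new site
    subs <- subs[!vapply(subs, iupac_matches, logical(1),
                         code = mchars[snp_in_motif])]
    a2 <- NULL
    for (b in sample(subs, length(subs))) {
      seq2 <- seq1
      seq2[snp_offset] <- b
      cand <- paste(seq2, collapse = "")
      if (nrow(scan_motif(cand, motif)) == 0L) { a2 <- cand; break }
    }
    if (is.null(a2)) next
    enz <- list(name = "planted", motif = motif, cut_offset = cut_offset)
    truth <- list(motif = motif, cut_offset = cut_offset,
                  motif_start = s, snp_offset = snp_offset,
                  fragments_allele1 = digest(a1, enz),
                  fragments_allele2 = digest(a2, enz))
    return(structure(list(allele1 = a1, allele2 = a2, truth = truth),
                     class = "amplicon_pair"))
  }
  stop("failed to construct an amplicon pair with a unique breakable site")
}

#' Generate a synthetic germplasm metadata table
#'
#' Assigns accessions to groups with counts matching the requested
#' proportions up to largest-remainder rounding, and draws a genotyped allele,
#' country and release year per accession.
#'
#' @param accessions Character vector of accession names.
#' @param group_labels Character vector of group labels.
#' @param proportions Numeric vector (same length as `group_labels`) summing
#'   to 1.
#' @param seed Integer seed.
#' @param alleles Possible genotyped-allele symbols (default `c("C","A")`).
#' @param allele_props Proportions for `alleles` (default uniform).
#'
#' @return A `data.frame` with columns `accession`, `group`, `allele`,
#'   `country`, `year`.
#' @export
generate_metadata <- function(accessions, group_labels, proportions, seed,
                              alleles = c("C", "A"), allele_props = NULL) {
  if (length(group_labels) != length(proportions)) {
    stop("group_labels and proportions must have the same length")
  }
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  n <- length(accessions)
  set.seed(as.integer(seed))
  counts <- apportion(n, proportions)
  group <- sample(rep.int(group_labels, counts))
  if (is.null(allele_props)) allele_props <- rep(1 / length(alleles), length(alleles))
  acounts <- apportion(n, allele_props)
  allele <- sample(rep.int(alleles, acounts))
  countries <- c("AUS", "GBR", "FRA", "JPN", "CAN", "MEX", "CHN")
  data.frame(accession = as.character(accessions),
             group = group,
             allele = allele,
             country = sample(countries, n, replace = TRUE),
             year = sample(1900:2000, n, replace = TRUE),
             stringsAsFactors = FALSE)
}
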