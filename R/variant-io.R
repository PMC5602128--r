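## VCF v4.2 in/out and gene-interval restriction. Coordinates are 1-based
## throughout (VCF convention); intervals are 1-based inclusive.

#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF v4.2 file (via \pkg{vcfR}) and converts diploid GT calls to
#' genotype classes: `0/0` -> hom-ref, `1/1` -> hom-alt, `0/1`/`1/0` -> het,
#' `./.` -> missing. Phased separators (`|`) are accepted, and haploid calls
#' (`0`, `1`) are mapped to the corresponding homozygous class (flow-sorted
#' chromosome data often yields haploid calls). Records that are not biallelic
#' SNPs are skipped with a warning. The gene label of each site is taken from
#' the CHROM column (the convention used by [write_vcf()]).
#'
#' @param path Path to a VCF file.
#'
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("cannot read VCF: no such file '", path, "'")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt_cols <- colnames(v@gt)
  if (is.null(gt_cols) || length(gt_cols) < 2L) {
    stop("VCF has no sample columns")
  }
  samples <- gt_cols[-1L]
  fix <- v@fix   # always a character matrix, unlike getFIX() on 1 record
  if (nrow(fix) == 0L) {
    sites <- data.frame(site_id = character(0), gene = character(0),
                        contig = character(0), position = integer(0),
                        ref = character(0), alt = character(0),
                        stringsAsFactors = FALSE)
    return(genotype_matrix(matrix(integer(0), nrow = length(samples), ncol = 0),
                           sites, samples))
  }
  if (!all(grepl("(^|:)GT($|:)", v@gt[, "FORMAT"]))) {
    stop("VCF records lack the GT format key")
  }
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  biallelic_snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(!biallelic_snp)) {
    warning(sum(!biallelic_snp),
            " record(s) skipped: not biallelic SNPs")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, samples))
  keep <- which(biallelic_snp)
  id <- fix[, "ID"]
  no_id <- is.na(id) | id == "."
  id[no_id] <- paste0(fix[no_id, "CHROM"], ":", fix[no_id, "POS"])
  sites <- data.frame(site_id = id[keep],
                      gene = fix[keep, "CHROM"],
                      contig = fix[keep, "CHROM"],
                      position = as.integer(fix[keep, "POS"]),
                      ref = ref[keep], alt = alt[keep],
                      stringsAsFactors = FALSE)
  calls <- apply(gt[keep, , drop = FALSE], c(1, 2), classify_gt)
  calls <- t(calls)
  genotype_matrix(calls[samples, , drop = FALSE], sites, samples)
}

## One GT string -> genotype class code (see genotype-matrix.R).
classify_gt <- function(g) {
  if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
  alleles <- strsplit(g, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_integer_)
  a <- suppressWarnings(as.integer(alleles))
  if (anyNA(a) || any(!a %in% c(0L, 1L))) {
    warning("unparseable GT '", g, "' treated as missing")
    return(NA_integer_)
  }
  if (length(a) == 1L) return(if (a == 0L) 0L else 2L)   # haploid call
  if (all(a == 0L)) 0L else if (all(a == 1L)) 2L else 1L
}

#' Write a genotype matrix as VCF v4.2
#'
#' Deterministic plain-text emitter: fixed header, CHROM = gene label,
#' ID = site identifier, GT-only FORMAT, missing calls serialized as `./.`.
#' Writing then reading then writing again produces a byte-identical file.
#'
#' @param matrix A [genotype_matrix()].
#' @param path Output path.
#' @param meta Optional character vector of extra `##`-header lines (written
#'   verbatim after the fileformat line, e.g. provenance).
#'
#' @return `path`, invisibly.
#' @export
write_vcf <- function(matrix, path, meta = NULL) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  gt_string <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c("##fileformat=VCFv4.2", meta,
              paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                     paste(matrix$accessions, collapse = "\t")))
  rows <- character(nrow(matrix$sites))
  for (j in seq_len(nrow(matrix$sites))) {
    s <- matrix$sites[j, ]
    calls <- matrix$calls[, j]
    gt <- ifelse(is.na(calls), "./.", gt_string[as.character(calls)])
    rows[j] <- paste(c(s$gene, s$position, s$site_id, s$ref, s$alt,
                       ".", ".", ".", "GT", gt), collapse = "\t")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Restrict a genotype matrix to gene intervals
#'
#' Keeps sites whose (contig, position) fall inside any interval (1-based,
#' inclusive ends) and annotates each kept site with the interval's gene
#' label. Sites are returned ordered by position within contig.
#'
#' @param matrix A [genotype_matrix()].
#' @param intervals `data.frame` with columns `gene`, `contig`, `start`,
#'   `end` (1-based inclusive).
#'
#' @return A [genotype_matrix()] containing only the covered sites.
#' @export
restrict_to_intervals <- function(matrix, intervals) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  intervals <- as.data.frame(intervals, stringsAsFactors = FALSE)
  required <- c("gene", "contig", "start", "end")
  if (!all(required %in% names(intervals))) {
    stop("intervals need columns: ", paste(required, collapse = ", "))
  }
  if (any(intervals$start > intervals$end)) stop("interval start > end")
  ## conflicting overlaps: same contig, overlapping span, different gene label
  if (nrow(intervals) > 1) {
    for (i in seq_len(nrow(intervals) - 1L)) {
      for (j in seq((i + 1L), nrow(intervals))) {
        a <- intervals[i, ]; b <- intervals[j, ]
        if (a$contig == b$contig && a$start <= b$end && b$start <= a$end &&
            a$gene != b$gene) {
          stop("overlapping intervals on contig '", a$contig,
               "' carry conflicting gene labels '", a$gene, "' and '",
               b$gene, "'")
        }
      }
    }
  }
  gene_label <- rep(NA_character_, nrow(matrix$sites))
  for (k in seq_len(nrow(intervals))) {
    hit <- matrix$sites$contig == intervals$contig[k] &
      matrix$sites$position >= intervals$start[k] &
      matrix$sites$position <= intervals$end[k]
    gene_label[hit] <- intervals$gene[k]
  }
  keep <- which(!is.na(gene_label))
  if (length(keep) == 0) {
    stop("no sites fall inside the given intervals")
  }
  sites <- matrix$sites[keep, , drop = FALSE]
  sites$gene <- gene_label[keep]
  ord <- order(sites$contig, sites$position)
  sites <- sites[ord, , drop = FALSE]
  genotype_matrix(matrix$calls[, keep[ord], drop = FALSE], sites,
                  matrix$accessions)
}

#' Write / read a tab-separated table
#'
#' TSV with a header row; optional leading `#` comment lines (used for
#' provenance and for the 1-based-inclusive coordinate declaration of
#' interval tables). [read_table()] skips comment lines.
#'
#' @param rows A `data.frame`.
#' @param path File path.
#' @param comments Optional character vector of comment lines (written with a
#'   leading `"# "`).
#'
#' @return `path` invisibly for the writer; a `data.frame` for the reader.
#' @export
write_table <- function(rows, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  read.delim(path, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Write / read gene-interval tables (1-based inclusive)
#'
#' @param intervals `data.frame` with columns `gene`, `contig`, `start`, `end`.
#' @param path File path.
#' @return `path` invisibly for the writer; a `data.frame` for the reader.
#' @export
write_intervals <- function(intervals, path) {
  write_table(intervals, path,
              comments = "coordinates: 1-based, inclusive ends")
}

#' @rdname write_intervals
#' @export
read_intervals <- function(path) {
  read_table(path)
}
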