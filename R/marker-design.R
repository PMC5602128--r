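## In-silico CAPS (restriction-site gain/loss) and KASP (allele-specific
## primer) assay design for biallelic SNPs.

check_iupac <- function(chars) {
  bad <- setdiff(unique(chars), names(Biostrings::IUPAC_CODE_MAP))
  if (length(bad) > 0) {
    stop("invalid IUPAC code(s): ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

## Does concrete base `base` satisfy IUPAC code `code`?
iupac_matches <- function(base, code) {
  grepl(base, Biostrings::IUPAC_CODE_MAP[[code]], fixed = TRUE)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Scan a sequence for a degenerate recognition motif
#'
#' Reports all 1-based start positions where the IUPAC motif matches the
#' forward strand, plus reverse-complement matches mapped to forward
#' coordinates. For palindromic motifs (equal to their own reverse
#' complement) each site is reported once, on the forward strand.
#'
#' @param sequence DNA string over `A`, `C`, `G`, `T`.
#' @param motif IUPAC motif string.
#'
#' @return A `data.frame` with columns `start` (1-based) and `strand`
#'   (`"+"` or `"-"`), ordered by start.
#' @export
scan_motif <- function(sequence, motif) {
  sequence <- toupper(sequence)
  motif <- toupper(motif)
  if (grepl("[^ACGT]", sequence)) {
    stop("sequence must contain only A, C, G, T")
  }
  check_iupac(strsplit(motif, "")[[1]])
  subj <- Biostrings::DNAString(sequence)
  fwd <- Biostrings::start(
    Biostrings::matchPattern(Biostrings::DNAString(motif), subj,
                             fixed = FALSE))
  rc <- revcomp(motif)
  if (rc == motif) {                       # palindromic: dedupe
    out <- data.frame(start = fwd, strand = rep("+", length(fwd)),
                      stringsAsFactors = FALSE)
  } else {
    rev <- Biostrings::start(
      Biostrings::matchPattern(Biostrings::DNAString(rc), subj,
                               fixed = FALSE))
    out <- data.frame(start = c(fwd, rev),
                      strand = c(rep("+", length(fwd)),
                                 rep("-", length(rev))),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' In-silico restriction digest
#'
#' Cuts the top strand after the `cut_offset`-th motif base at every motif
#' occurrence (reverse-strand occurrences cut after the
#' `length(motif) - cut_offset`-th base, mapping the cut back to forward
#' coordinates) and returns the ordered fragment lengths. A sequence without
#' a site yields a single full-length fragment.
#'
#' @param sequence DNA string.
#' @param enzyme A list (or one-row `data.frame`) with `name`, `motif`,
#'   `cut_offset`.
#'
#' @return Integer vector of fragment lengths, left to right; sums to the
#'   sequence length.
#' @export
digest <- function(sequence, enzyme) {
  motif <- toupper(enzyme$motif)
  cut_offset <- as.integer(enzyme$cut_offset)
  m <- nchar(motif)
  if (cut_offset < 0 || cut_offset > m) {
    stop("cut_offset must lie in [0, motif length]")
  }
  len <- nchar(sequence)
  hits <- scan_motif(sequence, motif)
  if (nrow(hits) == 0) return(len)
  cuts <- ifelse(hits$strand == "+",
                 hits$start + cut_offset - 1L,
                 hits$start + (m - cut_offset) - 1L)
  cuts <- sort(unique(cuts[cuts >= 1L & cuts < len]))
  if (length(cuts) == 0) return(len)
  as.integer(diff(c(0L, cuts, len)))
}

#' Read a restriction-enzyme table
#'
#' TSV with columns `name`, `motif`, `cut_offset`. The packaged default table
#' (`system.file("extdata", "enzymes.tsv", package = "phshap")`) models a few
#' common enzymes, including Hpy166II as a blunt cutter at `GTN^NAC`
#' (`cut_offset = 3`).
#'
#' @param path Path to the table; default the packaged table.
#'
#' @return A `data.frame` with one enzyme per row.
#' @export
read_enzyme_table <- function(path = system.file("extdata", "enzymes.tsv",
                                                 package = "phshap")) {
  tab <- read_table(path)
  required <- c("name", "motif", "cut_offset")
  if (!all(required %in% names(tab))) {
    stop("enzyme table needs columns: ", paste(required, collapse = ", "))
  }
  tab
}

#' Find CAPS assay candidates for a SNP
#'
#' Digests both allele sequences with every enzyme in the table and reports
#' the enzymes whose fragment ladders differ (discriminating assays),
#' annotated with which allele retains (or gains) a cut and ranked by gel
#' resolvability: the smallest band separation a gel must resolve, largest
#' first.
#'
#' @param allele_seq_1,allele_seq_2 Equal-length sequences differing at
#'   exactly one position.
#' @param snp_position 1-based position of the difference.
#' @param enzyme_table `data.frame` as from [read_enzyme_table()].
#'
#' @return A `data.frame` with one row per discriminating enzyme: `enzyme`,
#'   `motif`, `cut_offset`, `fragments_allele1`, `fragments_allele2`
#'   (comma-separated bp ladders), `cut_allele` (which allele has more cuts:
#'   `"allele1"`, `"allele2"` or `"both"`), `min_band_separation`.
#' @export
find_caps_candidates <- function(allele_seq_1, allele_seq_2, snp_position,
                                 enzyme_table = read_enzyme_table()) {
  allele_seq_1 <- toupper(allele_seq_1)
  allele_seq_2 <- toupper(allele_seq_2)
  if (nchar(allele_seq_1) != nchar(allele_seq_2)) {
    stop("allele sequences must have equal length")
  }
  diffs <- which(strsplit(allele_seq_1, "")[[1]] !=
                 strsplit(allele_seq_2, "")[[1]])
  if (length(diffs) != 1) {
    stop("allele sequences must differ at exactly 1 position (found ",
         length(diffs), ")")
  }
  if (diffs != snp_position) {
    stop("sequences differ at position ", diffs, ", not snp_position ",
         snp_position)
  }
  rows <- list()
  for (r in seq_len(nrow(enzyme_table))) {
    enz <- as.list(enzyme_table[r, ])
    f1 <- digest(allele_seq_1, enz)
    f2 <- digest(allele_seq_2, enz)
    if (identical(f1, f2)) next
    sep <- band_separation(f1, f2)
    cut_allele <- if (length(f1) > length(f2)) "allele1"
                  else if (length(f2) > length(f1)) "allele2" else "both"
    rows[[length(rows) + 1L]] <- data.frame(
      enzyme = enz$name, motif = enz$motif, cut_offset = enz$cut_offset,
      fragments_allele1 = paste(f1, collapse = ","),
      fragments_allele2 = paste(f2, collapse = ","),
      cut_allele = cut_allele, min_band_separation = sep,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(enzyme = character(0), motif = character(0),
                      cut_offset = integer(0),
                      fragments_allele1 = character(0),
                      fragments_allele2 = character(0),
                      cut_allele = character(0),
                      min_band_separation = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$min_band_separation, out$enzyme), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Smallest distance between a band unique to one ladder and its nearest
## band in the other ladder — the resolution a gel needs to call the assay.
band_separation <- function(f1, f2) {
  u1 <- setdiff(f1, f2); u2 <- setdiff(f2, f1)
  seps <- c(vapply(u1, function(b) min(abs(b - f2)), numeric(1)),
            vapply(u2, function(b) min(abs(b - f1)), numeric(1)))
  min(seps)
}

## De-facto standard dye tail sequences for allele-specific primers.
DEFAULT_TAILS <- c(FAM = "GAAGGTGACCAAGTTCATGCT",
                   HEX = "GAAGGTCGGAGTCAACGGATT")

#' Design a KASP allele-specific assay
#'
#' Extracts the `primer_length` window ending at the SNP on the stated strand
#' and emits the two allele-specific primers (identical except the final 3'
#' base, which carries the SNP alleles), with the FAM dye tail prepended to
#' the first-listed allele's primer and HEX to the second. A common primer is
#' taken from the opposite strand outside the window.
#'
#' For `orientation = "forward"` the allele-specific primers read the given
#' strand left-to-right and end at `snp_position`; their 3' bases are
#' `ref_allele`/`alt_allele` as given. For `orientation = "reverse"` they
#' read the reverse-complement strand, so their 3' bases are the complements
#' of the given alleles.
#'
#' @param template DNA string (the strand on which `snp_position`,
#'   `ref_allele` and `alt_allele` are expressed).
#' @param snp_position 1-based SNP position on `template`.
#' @param ref_allele,alt_allele The two SNP alleles on the template strand;
#'   `template` must carry `ref_allele` at `snp_position`.
#' @param primer_length Length of the allele-specific primers (default 20).
#' @param orientation `"forward"` or `"reverse"`.
#' @param tails Named character vector of dye-tail sequences; names are the
#'   dye labels (default the standard FAM/HEX tails).
#'
#' @return An object of class `kasp_assay`: allele-specific primer cores and
#'   tailed primers with their dyes, the common primer, orientation and the
#'   amplicon span on the template.
#' @export
design_kasp <- function(template, snp_position, ref_allele, alt_allele,
                        primer_length = 20L, orientation = c("forward", "reverse"),
                        tails = DEFAULT_TAILS) {
  template <- toupper(template)
  orientation <- match.arg(orientation)
  primer_length <- as.integer(primer_length)
  n <- nchar(template)
  snp_position <- as.integer(snp_position)
  ref_allele <- toupper(ref_allele); alt_allele <- toupper(alt_allele)
  if (ref_allele == alt_allele) stop("alleles must differ")
  if (length(tails) != 2 || is.null(names(tails))) {
    stop("tails must be a named vector of two dye-tail sequences")
  }
  have <- substr(template, snp_position, snp_position)
  if (have != ref_allele) {
    stop("template carries '", have, "' at snp_position, not ref_allele '",
         ref_allele, "'")
  }
  if (orientation == "forward") {
    start <- snp_position - primer_length + 1L
    if (start < 1L) stop("primer window runs off the template 5' end")
    core_ref <- substr(template, start, snp_position)
    core_alt <- paste0(substr(core_ref, 1L, primer_length - 1L), alt_allele)
    ## common primer: reverse strand, 3' of the SNP
    if (snp_position + primer_length > n) {
      stop("no room for a common primer 3' of the SNP")
    }
    common <- revcomp(substr(template, n - primer_length + 1L, n))
    amplicon <- c(start, n)
  } else {
    end <- snp_position + primer_length - 1L
    if (end > n) stop("primer window runs off the template 3' end")
    core_ref <- revcomp(substr(template, snp_position, end))
    core_alt <- paste0(substr(core_ref, 1L, primer_length - 1L),
                       revcomp(alt_allele))
    if (snp_position - primer_length < 1L) {
      stop("no room for a common primer 5' of the SNP")
    }
    common <- substr(template, 1L, primer_length)
    amplicon <- c(1L, end)
  }
  ## dye tails must not anneal to the template
  for (d in names(tails)) {
    if (grepl(tails[[d]], template, fixed = TRUE) ||
        grepl(revcomp(tails[[d]]), template, fixed = TRUE)) {
      warning("dye tail ", d, " is complementary to the template")
    }
  }
  structure(list(
    primer_ref_core = core_ref,
    primer_alt_core = core_alt,
    primer_ref = paste0(tails[[1]], core_ref),
    primer_alt = paste0(tails[[2]], core_alt),
    dye_ref = names(tails)[1], dye_alt = names(tails)[2],
    common_primer = common,
    orientation = orientation,
    amplicon_span = amplicon,
    amplicon_length = amplicon[2] - amplicon[1] + 1L),
    class = "kasp_assay")
}

#' @export
print.kasp_assay <- function(x, ...) {
  cat("kasp_assay (", x$orientation, " orientation, amplicon ",
      x$amplicon_length, " bp)\n", sep = "")
  cat("  ", x$dye_ref, " primer: ", x$primer_ref, "\n", sep = "")
  cat("  ", x$dye_alt, " primer: ", x$primer_alt, "\n", sep = "")
  cat("  common primer: ", x$common_primer, "\n", sep = "")
  invisible(x)
}

#' Render fragment ladders as a text gel
#'
#' @param ladders Named list of integer fragment-length vectors (one lane per
#'   name).
#' @return Character vector of gel lines, invisibly; also printed.
#' @export
virtual_gel <- function(ladders) {
  all_frag <- sort(unique(unlist(ladders)), decreasing = TRUE)
  width <- max(nchar(names(ladders)))
  lines <- character(0)
  for (frag in all_frag) {
    marks <- vapply(ladders, function(l) {
      if (frag %in% l) "==" else "  "
    }, character(1))
    lines <- c(lines, sprintf("%5d bp | %s", frag,
                              paste(formatC(marks, width = width),
                                    collapse = " ")))
  }
  header <- sprintf("%8s | %s", "",
                    paste(formatC(names(ladders), width = width),
                          collapse = " "))
  out <- c(header, lines)
  cat(out, sep = "\n")
  invisible(out)
}

#' Write / read FASTA sequences
#'
#' Thin wrappers over \pkg{Biostrings} for the allele-sequence files the
#' assay-design stage consumes and emits.
#'
#' @param seqs Named character vector of sequences (writer).
#' @param path File path.
#' @return Named character vector of sequences (reader); `path` invisibly
#'   (writer).
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}
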