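hpy <- list(name = "Hpy166II", motif = "GTNNAC", cut_offset = 3)

test_that("motif scanning handles degenerate codes and both strands", {
  expect_equal(scan_motif("GTAAAC", "GTNNAC")$start, 1)
  expect_equal(nrow(scan_motif("AAAAAA", "GTNNAC")), 0)
  expect_error(scan_motif("ACGTX", "GT"), "only A, C, G, T")
  expect_error(scan_motif("ACGT", "GZ"), "invalid IUPAC")

  # GTNNAC is its own reverse complement: each site reported once
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString("GTNNAC")))
  expect_equal(rc, "GTNNAC")
  hits <- scan_motif("AAGTTGACAA", "GTNNAC")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$strand, "+")

  # non-palindromic motifs report reverse-strand matches in forward coords
  hits2 <- scan_motif("AAGAATTTAA", "GAATTT")   # fwd at 3
  expect_equal(hits2$start, 3)
  hits3 <- scan_motif(paste0("AA", "AAATTC", "AA"), "GAATTT")  # rc at 3
  expect_equal(hits3$strand, "-")
  expect_equal(hits3$start, 3)
})

test_that("digest fragments are ordered, conserved and count cuts + 1", {
  # planted site: cut after base 605 of an 887 bp amplicon
  amp <- generate_amplicon_pair(887, 608, "GTNNAC", 3, seed = 31,
                                snp_motif_index = 6)
  expect_equal(digest(amp$allele1, hpy), c(605L, 282L))
  expect_equal(digest(amp$allele2, hpy), 887L)

  set.seed(77)
  enzymes <- read_enzyme_table()
  for (i in 1:40) {
    seq <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                 collapse = "")
    enz <- as.list(enzymes[sample.int(nrow(enzymes), 1), ])
    frags <- digest(seq, enz)
    expect_equal(sum(frags), 300L)
    n_cut_positions <- length(unique(ifelse(
      scan_motif(seq, enz$motif)$strand == "+",
      scan_motif(seq, enz$motif)$start + enz$cut_offset - 1L,
      scan_motif(seq, enz$motif)$start + nchar(enz$motif) - enz$cut_offset - 1L)))
    expect_equal(length(frags), n_cut_positions + 1L)
  }
})

test_that("CAPS candidates flag discriminating enzymes and annotate the cut allele", {
  amp <- generate_amplicon_pair(887, 608, "GTNNAC", 3, seed = 31,
                                snp_motif_index = 6)
  assays <- find_caps_candidates(amp$allele1, amp$allele2, 608)
  hrow <- assays[assays$enzyme == "Hpy166II", ]
  expect_equal(nrow(hrow), 1)
  expect_equal(hrow$fragments_allele1, "605,282")
  expect_equal(hrow$fragments_allele2, "887")
  expect_equal(hrow$cut_allele, "allele1")

  # symmetric in allele order
  rev <- find_caps_candidates(amp$allele2, amp$allele1, 608)
  rrow <- rev[rev$enzyme == "Hpy166II", ]
  expect_equal(rrow$fragments_allele2, "605,282")
  expect_equal(rrow$cut_allele, "allele2")
  expect_setequal(assays$enzyme, rev$enzyme)

  # an enzyme whose motif avoids the SNP is not reported
  other <- assays[assays$enzyme != "Hpy166II", ]
  expect_equal(nrow(other), 0)

  expect_error(find_caps_candidates("AAAA", "TTTT", 1), "exactly 1 position")
  expect_error(find_caps_candidates("AAAA", "ATAA", 1), "not snp_position")
})

test_that("gain-of-site CAPS assays are reported symmetrically", {
  # allele2 creates an EcoRI site absent from allele1
  a2 <- paste0("CCCC", "GAATTC", "CCCC")
  a1 <- paste0("CCCC", "GACTTC", "CCCC")
  assays <- find_caps_candidates(a1, a2, 7)
  erow <- assays[assays$enzyme == "EcoRI", ]
  expect_equal(nrow(erow), 1)
  expect_equal(erow$cut_allele, "allele2")
})

test_that("KASP design emits allele-specific primers differing at the 3' base", {
  backbone5 <- paste(rep("ACGGT", 8), collapse = "")
  backbone3 <- paste(rep("TCCAG", 8), collapse = "")
  template <- paste0(backbone5, "CCTTAAGGGCGAAGCAAAAA", backbone3)
  snp_pos <- nchar(backbone5) + 1L
  assay <- design_kasp(template, snp_pos, "C", "A", primer_length = 20,
                       orientation = "reverse")
  expect_equal(assay$primer_ref_core, "TTTTTGCTTCGCCCTTAAGG")
  expect_equal(assay$primer_alt_core, "TTTTTGCTTCGCCCTTAAGT")
  n <- nchar(assay$primer_ref_core)
  expect_identical(substr(assay$primer_ref_core, 1, n - 1),
                   substr(assay$primer_alt_core, 1, n - 1))
  expect_false(substr(assay$primer_ref_core, n, n) ==
               substr(assay$primer_alt_core, n, n))
  # FAM tail on the first-listed allele's primer, HEX on the second
  expect_equal(assay$dye_ref, "FAM")
  expect_equal(assay$dye_alt, "HEX")
  expect_true(startsWith(assay$primer_ref, "GAAGGTGACCAAGTTCATGCT"))
  expect_true(startsWith(assay$primer_alt, "GAAGGTCGGAGTCAACGGATT"))
  # common primer comes from the opposite strand outside the window
  expect_equal(assay$common_primer, substr(template, 1, 20))

  fwd <- design_kasp(template, snp_pos, "C", "A", primer_length = 20,
                     orientation = "forward")
  expect_equal(substr(fwd$primer_ref_core, 20, 20), "C")
  expect_equal(substr(fwd$primer_alt_core, 20, 20), "A")

  expect_error(design_kasp("ACGT", 2, "C", "A", primer_length = 10),
               "runs off")
  expect_error(design_kasp(template, snp_pos, "G", "A"), "not ref_allele")
})

test_that("fasta round-trips and the virtual gel renders every band", {
  seqs <- c(allele1 = "ACGTACGT", allele2 = "ACGTTCGT")
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  expect_equal(read_fasta(f), seqs)
  gel <- capture.output(virtual_gel(list(C = c(605L, 282L), A = 887L)))
  expect_length(gel, 4)  # header + three distinct band sizes
  expect_match(gel[2], "887")
})
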