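## Fixture builders: everything is constructed in code at test time.

make_sites <- function(n, gene = "geneX", start_pos = 100L) {
  data.frame(site_id = sprintf("S%02d", seq_len(n)),
             gene = rep(gene, n), contig = rep(gene, n),
             position = start_pos + 10L * seq_len(n),
             ref = rep("C", n), alt = rep("T", n), stringsAsFactors = FALSE)
}

gm_from_calls <- function(calls, sites = NULL) {
  calls <- as.matrix(calls)
  if (is.null(sites)) sites <- make_sites(ncol(calls))
  genotype_matrix(calls, sites, sprintf("acc%02d", seq_len(nrow(calls))))
}

## A 62-accession x 51-site panel constructed so the standard filters
## (MAF > 5%, homozygosity > 80%) reduce it to 58 accessions x 39 sites:
## sites 40..51 are rare (one hom-alt carrier), accessions 59..62 are
## heterozygous at just over half of the common sites.
make_reduction_panel <- function() {
  calls <- matrix(0L, nrow = 62, ncol = 51)
  calls[1:31, 1:39] <- 2L                       # common sites, MAF ~ 0.5
  calls[1, 40:51] <- 2L                         # rare sites, MAF = 1/62
  for (a in 59:62) calls[a, 1:20] <- 1L         # 19/39 hom fraction < 0.8
  gm_from_calls(calls)
}

## A pedigree with founders, one cross, full sibs and a half sib:
##   F1 x F2 -> child1, child2 (full sibs); F1 x F3 -> half1 (half sib of
##   child1 via F1).
make_family_pedigree <- function() {
  pedigree(data.frame(
    name = c("F1", "F2", "F3", "child1", "child2", "half1"),
    parent1 = c("", "", "", "F1", "F1", "F1"),
    parent2 = c("", "", "", "F2", "F2", "F3"),
    stringsAsFactors = FALSE))
}

## Random small pedigree within a line budget.
random_pedigree <- function(seed, max_lines = 30L) {
  set.seed(seed)
  n_f <- sample(3:6, 1)
  n_gen <- sample(2:4, 1)
  per_gen <- sample(2:5, 1)
  while (n_f + n_gen * per_gen > max_lines) per_gen <- per_gen - 1L
  generate_pedigree(n_founders = n_f, n_generations = n_gen,
                    seed = seed, n_per_generation = per_gen)
}

## Founder haplotypes encoding 0..13 in binary over sites 1..4, plus three
## constant-ish redundant sites; 4 informative sites fully separate all 14.
make_coded_founders <- function() {
  strings <- vapply(0:13, function(v) {
    bits <- as.integer(intToBits(v))[1:4]
    paste(c(ifelse(bits == 1L, "A", "R"),
            ifelse(v %% 2 == 0, "R", "A"),   # duplicates bit 1
            ifelse(v < 7, "R", "A"),
            ifelse(v %% 3 == 0, "A", "R")),
          collapse = "")
  }, character(1))
  haplotype_set(strings, names = paste0("F", 1:14),
                members = lapply(1:14, function(i) sprintf("acc%02d", i)),
                site_ids = sprintf("S%02d", 1:7))
}
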