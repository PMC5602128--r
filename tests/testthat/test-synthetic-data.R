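test_that("sim_config validates probabilities, counts and feasibility", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(het_rate = 1.5), "probabilities")
  expect_error(sim_config(missing_rate = -0.1), "probabilities")
  expect_error(sim_config(n_sites = 0), "counts")
  expect_error(sim_config(n_founder_haplotypes = 5, n_sites = 2),
               "infeasible")
  expect_error(sim_config(founder_props = c(0.5, 0.5),
                          n_founder_haplotypes = 3), "founder_props")
})

test_that("founder generation: segregation, distinctness, determinism", {
  # one site, two founders: the only segregating configuration
  cfg <- sim_config(n_founder_haplotypes = 2, n_sites = 1, n_accessions = 2,
                    seed = 5)
  f <- generate_founder_haplotypes(cfg)
  expect_setequal(f$alleles, c("R", "A"))

  cfg <- sim_config(seed = 7)   # 14 founders x 39 sites
  f1 <- generate_founder_haplotypes(cfg)
  f2 <- generate_founder_haplotypes(cfg)
  expect_identical(f1, f2)
  expect_length(f1, 14)
  expect_false(anyDuplicated(f1$alleles) > 0)
  mat <- do.call(rbind, strsplit(f1$alleles, ""))
  expect_true(all(apply(mat, 2, function(col) length(unique(col)) == 2)))

  # pigeonhole: 5 distinct strings cannot exist on 2 biallelic sites
  expect_error(
    generate_founder_haplotypes(
      structure(list(n_founder_haplotypes = 5L, n_sites = 2L,
                     maf_floor = 0, seed = 1L), class = "sim_config")),
    "infeasible")
})

test_that("planted per-site founder frequency respects maf_floor", {
  for (seed in 1:20) {
    cfg <- sim_config(n_founder_haplotypes = 10, n_sites = 25,
                      maf_floor = 0.2, n_accessions = 10, seed = seed)
    f <- generate_founder_haplotypes(cfg)
    mat <- do.call(rbind, strsplit(f$alleles, ""))
    freq <- colMeans(mat == "A")
    expect_true(all(pmin(freq, 1 - freq) >= 0.2 - 1e-12))
  }
})

test_that("panel generation: dimensions, noise-free recovery, degenerate rates", {
  cfg <- sim_config(seed = 11)
  f <- generate_founder_haplotypes(cfg)
  gm <- generate_panel(f, cfg)
  expect_equal(dim(gm), c(58L, 39L))
  truth <- attr(gm, "truth")
  expect_setequal(unique(truth$founder_of), f$name)  # every founder used

  cfg0 <- sim_config(n_founder_haplotypes = 5, n_sites = 12,
                     n_accessions = 20, het_rate = 0, missing_rate = 0,
                     seed = 3)
  f0 <- generate_founder_haplotypes(cfg0)
  gm0 <- generate_panel(f0, cfg0)
  rec <- reconstruct_haplotypes(gm0)
  truth0 <- attr(gm0, "truth")
  founder_string <- setNames(f0$alleles, f0$name)
  expect_identical(unname(rec$strings),
                   unname(founder_string[truth0$founder_of[names(rec$strings)]]))

  cfg1 <- sim_config(n_founder_haplotypes = 3, n_sites = 6, n_accessions = 6,
                     missing_rate = 1, clean_founder_copy = FALSE, seed = 2)
  f1 <- generate_founder_haplotypes(cfg1)
  gm1 <- generate_panel(f1, cfg1)
  expect_true(all(is.na(gm1$calls)))

  expect_error(generate_panel(f0, sim_config(n_founder_haplotypes = 5,
                                             n_sites = 12, n_accessions = 3,
                                             seed = 1)),
               "every founder")
})

test_that("founder proportions plant a major haplotype share", {
  props <- c(0.33, rep(0.67 / 13, 13))
  cfg <- sim_config(founder_props = props, het_rate = 0, missing_rate = 0,
                    seed = 9)
  f <- generate_founder_haplotypes(cfg)
  gm <- generate_panel(f, cfg)
  truth <- attr(gm, "truth")
  expect_equal(sum(truth$founder_of == "F1"), round(0.33 * 58), tolerance = 1)
})

test_that("pedigree generation is acyclic, deterministic and complete", {
  ped <- generate_pedigree(2, 1, seed = 4)
  expect_equal(sum(ped$parent1 == "" & ped$parent2 == ""), 2)
  child <- ped$name[ped$parent1 != ""]
  expect_length(child, 1)
  i <- match(child, ped$name)
  expect_setequal(c(ped$parent1[i], ped$parent2[i]), c("FND1", "FND2"))

  p1 <- generate_pedigree(4, 3, seed = 8, n_per_generation = 3)
  p2 <- generate_pedigree(4, 3, seed = 8, n_per_generation = 3)
  expect_identical(p1, p2)
  # topological order exists: depth resolved for every line (pedigree()
  # would have errored on a cycle)
  expect_false(anyNA(p1$depth))
  expect_error(generate_pedigree(0, 1, seed = 1), ">= 1")
})

test_that("amplicon pairs differ at exactly one position and break the motif", {
  amp <- generate_amplicon_pair(400, 170, "GTNNAC", 3, seed = 21)
  d <- which(strsplit(amp$allele1, "")[[1]] != strsplit(amp$allele2, "")[[1]])
  expect_equal(d, 170)
  expect_equal(nrow(scan_motif(amp$allele1, "GTNNAC")), 1)
  expect_equal(nrow(scan_motif(amp$allele2, "GTNNAC")), 0)
  enz <- list(name = "e", motif = "GTNNAC", cut_offset = 3)
  expect_equal(digest(amp$allele1, enz), amp$truth$fragments_allele1)
  expect_equal(digest(amp$allele2, enz), amp$truth$fragments_allele2)
  expect_equal(sum(amp$truth$fragments_allele1), 400)

  # an N motif base matches any base: a SNP there cannot break the site
  expect_error(generate_amplicon_pair(100, 50, "GTNNAC", 3, seed = 1,
                                      snp_motif_index = 3), "degenerate")
  expect_error(generate_amplicon_pair(100, 50, "NNNN", 2, seed = 1),
               "no non-degenerate base")
})

test_that("metadata assignment matches proportions and is deterministic", {
  acc <- sprintf("v%02d", 1:41)
  md <- generate_metadata(acc, c("bread", "other"), c(13 / 41, 28 / 41),
                          seed = 6)
  expect_equal(sum(md$group == "bread"), 13)
  expect_equal(sum(md$group == "other"), 28)
  expect_identical(md, generate_metadata(acc, c("bread", "other"),
                                         c(13 / 41, 28 / 41), seed = 6))
  one <- generate_metadata(acc, "all", 1, seed = 6)
  expect_true(all(one$group == "all"))
  expect_error(generate_metadata(acc, c("a", "b"), c(1), seed = 1),
               "same length")
})
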