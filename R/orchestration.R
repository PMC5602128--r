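## Stage orchestration: wires the modules into the survey workflow with
## reproducible seeds and provenance headers on every artifact. All artifacts
## are plain text (VCF/TSV/FASTA) so every intermediate is diffable.

provenance <- function(stage, params) {
  kv <- paste(names(params),
              vapply(params, function(p) paste(format(p), collapse = ","),
                     character(1)),
              sep = "=", collapse = " ")
  c(paste0("phshap ", as.character(packageVersion("phshap"))),
    paste0("stage=", stage, " ", kv))
}

#' Run one pipeline stage
#'
#' Single entry point wiring the modules into the survey workflow. Each stage
#' reads/writes plain-text artifacts under `out_dir`, stamped with a
#' provenance header (package version, stage, parameters, seed). Identical
#' parameters and seed give byte-identical outputs.
#'
#' Stages:
#' \describe{
#'   \item{`simulate`}{emit a synthetic panel: `panel.vcf`, `pedigree.tsv`,
#'     `metadata.tsv`, `amplicons.fasta`, `founders.tsv`. Params: the
#'     [sim_config()] arguments.}
#'   \item{`haplotype`}{filter, reconstruct, enumerate and subset: reads
#'     `vcf`, writes `haplotypes.tsv`, `filter_report.tsv`,
#'     `informative_sites.tsv`. Params: `vcf`, `maf_min` (0.05), `hom_min`
#'     (0.80), `informative_maf` (0.30), `k` (7).}
#'   \item{`network`}{median-joining network from a haplotype table: reads
#'     `haplotypes`, writes `network_edges.tsv`, `network_nodes.tsv`,
#'     `network.graphml`. Params: `haplotypes`, `epsilon` (0).}
#'   \item{`stats`}{group allele frequencies and the 2x2 chi-square: reads
#'     `metadata`, writes `frequencies.tsv`, `chisq.tsv`. Params: `metadata`,
#'     `focal_allele` ("C"), `class_a`, `class_b` (two group labels to
#'     contrast; default the first two).}
#'   \item{`cop`}{COP matrix and group means: reads `pedigree`, writes
#'     `cop_matrix.tsv`, `cop_summary.tsv`. Params: `pedigree`, optional
#'     `groups` (named list).}
#'   \item{`caps`}{CAPS candidates for an allele pair: reads `fasta` (two
#'     sequences), writes `caps_assays.tsv`. Params: `fasta`, `snp_position`,
#'     optional `enzymes` path.}
#'   \item{`kasp`}{KASP assay for a SNP: reads `fasta` (one template), writes
#'     `kasp_assay.tsv`. Params: `fasta`, `snp_position`, `ref_allele`,
#'     `alt_allele`, `primer_length` (20), `orientation` ("forward").}
#' }
#'
#' @param stage Stage name (see Details).
#' @param params Named list of stage parameters.
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed recorded in all outputs and used for any
#'   randomness.
#'
#' @return Invisibly, a list with `artifacts` (paths written) and `result`
#'   (the in-memory stage result).
#' @export
run_stage <- function(stage, params = list(), out_dir = ".", seed = 1L) {
  stages <- c("simulate", "haplotype", "network", "stats", "cop",
              "caps", "kasp")
  if (!stage %in% stages) {
    stop("unknown stage '", stage, "'; expected one of: ",
         paste(stages, collapse = ", "))
  }
  seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- provenance(stage, c(params[!vapply(params, is.list, logical(1))],
                              list(seed = seed)))
  p <- function(name) file.path(out_dir, name)
  switch(stage,
    simulate = {
      cfg_args <- params[names(params) %in% names(formals(sim_config))]
      cfg <- do.call(sim_config, c(cfg_args, list(seed = seed)))
      founders <- generate_founder_haplotypes(cfg)
      panel <- generate_panel(founders, cfg)
      ped <- generate_pedigree(n_founders = 4L, n_generations = 4L,
                               seed = seed, n_per_generation = 4L)
      meta <- generate_metadata(panel$accessions,
                                group_labels = c("bread", "other"),
                                proportions = c(0.3, 0.7), seed = seed)
      amp <- generate_amplicon_pair(length = 887L, snp_offset = 608L,
                                    motif = "GTNNAC", cut_offset = 3L,
                                    seed = seed)
      write_vcf(panel, p("panel.vcf"), meta = paste0("##", prov))
      write_pedigree(ped, p("pedigree.tsv"), comments = prov)
      write_table(meta, p("metadata.tsv"), comments = prov)
      write_table(as.data.frame(founders), p("founders.tsv"), comments = prov)
      write_fasta(c(allele1 = amp$allele1, allele2 = amp$allele2),
                  p("amplicons.fasta"))
      invisible(list(artifacts = p(c("panel.vcf", "pedigree.tsv",
                                     "metadata.tsv", "founders.tsv",
                                     "amplicons.fasta")),
                     result = list(config = cfg, panel = panel,
                                   founders = founders, pedigree = ped,
                                   metadata = meta, amplicons = amp)))
    },
    haplotype = {
      gm <- read_vcf(params$vcf)
      maf_min <- params$maf_min %||% 0.05
      hom_min <- params$hom_min %||% 0.80
      res <- haplotype_pipeline(gm, maf_min = maf_min, hom_min = hom_min)
      info <- tryCatch(
        select_informative_snps(res$haplotypes,
                                maf_min = params$informative_maf %||% 0.30,
                                k = params$k %||% 7L),
        error = function(e) NULL)
      write_table(as.data.frame(res$haplotypes), p("haplotypes.tsv"),
                  comments = c(prov,
                               paste0("site_ids=",
                                      paste(res$haplotypes$site_ids,
                                            collapse = ","))))
      rep <- res$report
      write_table(data.frame(measure = c("sites_in", "sites_kept",
                                         "accessions_in", "accessions_kept"),
                             value = c(rep$sites_in, rep$sites_kept,
                                       rep$accessions_in,
                                       rep$accessions_kept)),
                  p("filter_report.tsv"), comments = prov)
      if (!is.null(info)) {
        write_table(data.frame(site_id = info$site_ids %||%
                                 as.character(info$sites),
                               position = info$sites,
                               unresolved_pairs = info$unresolved),
                    p("informative_sites.tsv"), comments = prov)
      }
      invisible(list(artifacts = p(c("haplotypes.tsv", "filter_report.tsv",
                                     "informative_sites.tsv")),
                     result = c(res, list(informative = info))))
    },
    network = {
      tab <- read_table(params$haplotypes)
      members <- strsplit(tab$members, ",", fixed = TRUE)
      members[tab$members == "" | is.na(tab$members)] <- list(character(0))
      haps <- haplotype_set(tab$alleles, names = tab$name, members = members)
      net <- build_mj_network(haps, epsilon = params$epsilon %||% 0L)
      write_network(net, p("network_edges.tsv"), p("network_nodes.tsv"),
                    p("network.graphml"), comments = prov)
      invisible(list(artifacts = p(c("network_edges.tsv",
                                     "network_nodes.tsv",
                                     "network.graphml")),
                     result = net))
    },
    stats = {
      meta <- read_table(params$metadata)
      focal <- params$focal_allele %||% "C"
      freq <- group_allele_frequency(meta, focal)
      groups <- freq$group
      class_a <- params$class_a %||% groups[1]
      class_b <- params$class_b %||% groups[2]
      a <- freq[freq$group == class_a, ]
      b <- freq[freq$group == class_b, ]
      tab <- matrix(c(a$carriers, a$total - a$carriers,
                      b$carriers, b$total - b$carriers),
                    nrow = 2, byrow = TRUE,
                    dimnames = list(c(class_a, class_b),
                                    c(focal, "other")))
      test <- chi_square_2x2(tab)
      write_table(freq, p("frequencies.tsv"), comments = prov)
      write_table(data.frame(statistic = test$statistic, df = test$df,
                             p_value = test$p_value),
                  p("chisq.tsv"), comments = prov)
      invisible(list(artifacts = p(c("frequencies.tsv", "chisq.tsv")),
                     result = list(frequencies = freq, test = test,
                                   table = tab)))
    },
    cop = {
      ped <- read_pedigree(params$pedigree)
      m <- cop_matrix(ped$name, ped)
      write_table(data.frame(line = rownames(m), as.data.frame(m),
                             check.names = FALSE),
                  p("cop_matrix.tsv"),
                  comments = c(prov, "convention: inbred lines, self-COP = 1"))
      artifacts <- p("cop_matrix.tsv")
      summ <- NULL
      if (!is.null(params$groups)) {
        summ <- cop_summary(params$groups, ped)
        write_table(summ, p("cop_summary.tsv"), comments = prov)
        artifacts <- c(artifacts, p("cop_summary.tsv"))
      }
      invisible(list(artifacts = artifacts,
                     result = list(matrix = m, summary = summ)))
    },
    caps = {
      seqs <- read_fasta(params$fasta)
      if (length(seqs) < 2) stop("caps stage needs two allele sequences")
      enz <- if (is.null(params$enzymes)) read_enzyme_table()
             else read_enzyme_table(params$enzymes)
      assays <- find_caps_candidates(seqs[[1]], seqs[[2]],
                                     as.integer(params$snp_position), enz)
      write_table(assays, p("caps_assays.tsv"), comments = prov)
      invisible(list(artifacts = p("caps_assays.tsv"), result = assays))
    },
    kasp = {
      seqs <- read_fasta(params$fasta)
      assay <- design_kasp(seqs[[1]], as.integer(params$snp_position),
                           params$ref_allele, params$alt_allele,
                           primer_length = params$primer_length %||% 20L,
                           orientation = params$orientation %||% "forward")
      write_table(data.frame(field = c("dye_ref", "primer_ref",
                                       "dye_alt", "primer_alt",
                                       "common_primer", "orientation",
                                       "amplicon_length"),
                             value = c(assay$dye_ref, assay$primer_ref,
                                       assay$dye_alt, assay$primer_alt,
                                       assay$common_primer,
                                       assay$orientation,
                                       assay$amplicon_length)),
                  p("kasp_assay.tsv"), comments = prov)
      invisible(list(artifacts = p("kasp_assay.tsv"), result = assay))
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
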