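# phshap

Candidate-locus haplotype analysis for inbred crop diversity panels, built
around the workflow used to survey the wheat *Phs-A1* pre-harvest sprouting
(PHS) locus: define haplotypes from multi-sample VCF genotype calls over the
genes of a locus, cluster them with a median-joining network, summarise
allele frequencies across germplasm groups, quantify relatedness with
coefficients of parentage over breeding pedigrees, and design CAPS/KASP
diagnostic assays for a causal SNP. It is aimed at crop geneticists and
breeders working with locus-scale exome-capture or amplicon variant data in
highly inbred species, where accessions are (nearly) homozygous and a locus
haplotype is simply the vector of alleles an accession carries at the
retained SNPs.

## What it computes

* **Haplotype definition.** From an accessions × sites genotype matrix
  (classes hom-ref / het / hom-alt / missing), sites are kept when the
  minor-allele frequency over non-missing allele counts satisfies
  MAF > 5 %, and accessions when their homozygous fraction over the kept
  sites exceeds 80 % (both strict). Each fully homozygous accession yields
  an allele string h ∈ {R, A}^m; identical strings are grouped into
  haplotypes H1, H2, … ordered by descending carrier count.
* **Median-joining network.** Observed haplotypes are connected by an
  ε-relaxed minimum spanning network under Hamming distance d(h, h′);
  quasi-medians (for biallelic strings, the position-wise majority of a
  triple) are added greedily while they reduce the minimum spanning cost,
  then non-paying medians are pruned. At ε = 0 the network contains the
  union of all minimum spanning trees.
* **Informative SNP subsets.** Greedy set cover over haplotype pairs:
  among sites with carrier-weighted MAF > 30 %, repeatedly pick the site
  distinguishing the most still-unresolved haplotype pairs; an exhaustive
  search is available for small candidate sets. New panels are typed by
  exact projection matching, with collisions reported as compound labels
  (e.g. `H5/H7`) and unseen strings as panel-specific haplotypes.
* **Germplasm statistics.** Carrier percentages (nearest integer, ties away
  from zero) per group, and Pearson's χ² on a 2 × 2 trait-class × allele
  table without continuity correction: χ² = Σ (O − E)² / E, df = 1.
* **Coefficient of parentage.** For fully inbred lines, COP(x, x) = 1 and
  COP(x, y) = ½ [COP(x, p₁(y)) + COP(x, p₂(y))] expanding the younger line,
  unknown parents contributing 0; group summaries report mean COP with
  n(n−1)/2 within-group or |a|·|b| between-group pairs.
* **Assay design.** In-silico restriction digests over IUPAC motifs on both
  strands (CAPS: report enzymes whose fragment ladders separate the two
  alleles of a SNP) and KASP records: two allele-specific primers ending on
  the SNP alleles with FAM/HEX dye tails, plus a common primer from the
  opposite strand.

A synthetic-data module generates diversity panels (founder haplotypes
cloned into accessions with per-call heterozygous/missing corruption),
pedigrees, metadata tables and amplicon pairs with planted truth, so the
entire pipeline is testable end to end without external data.

## Worked example

```r
library(phshap)

cfg <- sim_config(n_founder_haplotypes = 14, n_sites = 39, n_accessions = 58,
                  het_rate = 0.02, missing_rate = 0.02, seed = 7)
panel <- generate_panel(generate_founder_haplotypes(cfg), cfg)
res <- haplotype_pipeline(panel, maf_min = 0.05, hom_min = 0.80)
res$report
#> filter_report:
#>   sites:      39 -> 39 (MAF > 0.05)
#>   accessions: 58 -> 58 (homozygosity > 0.8)
length(res$haplotypes)
#> [1] 14

build_mj_network(res$haplotypes)
#> haplo_network: 24 nodes (10 inferred medians), 23 edges, epsilon=0, spanning cost=126

sel <- select_informative_snps(res$haplotypes, maf_min = 0.30, k = 7)
sel$site_ids; sel$unresolved
#> [1] "S03" "S08" "S20" "S29" "S36"
#> [1] 0

chi_square_2x2(matrix(c(11, 2, 10, 18), 2, 2, byrow = TRUE))[c("statistic", "p_value")]
#> $statistic
#> [1] 8.497148
#> $p_value
#> [1] 0.003557539
```

The filter report shows that at these noise rates every planted site and
accession survives the 5 %/80 % filters; the 58 accessions collapse into
exactly the 14 planted haplotypes, and five of the 39 SNPs suffice to
distinguish all 91 haplotype pairs. The χ² value is the bread-making versus
feed/biscuit contrast of dormant-allele carriage (11/13 vs 10/28) in a
41-variety panel: association at p < 0.01.

The CAPS worked example plants a *Hpy*166II site (`GTNNAC`, blunt cut after
base 3) in an 887-bp amplicon so that the cut allele digests to 605 + 282 bp
while the allele that destroys the site stays intact at 887 bp:

```r
amp <- generate_amplicon_pair(887, 608, "GTNNAC", 3, seed = 14, snp_motif_index = 6)
hpy <- list(name = "Hpy166II", motif = "GTNNAC", cut_offset = 3)
digest(amp$allele1, hpy)   #> [1] 605 282
digest(amp$allele2, hpy)   #> [1] 887
```

A command-line wrapper over the same stages lives at
`inst/cli/phshap.R` (`Rscript phshap.R simulate --out dir --seed 7 ...`).

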