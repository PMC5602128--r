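---
title: "Methods: locus haplotype analysis, networks, parentage and assay design"
author: "phshap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locus haplotype analysis, networks, parentage and assay design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phshap)
```

# The model

phshap targets locus-scale haplotype surveys in highly inbred crops such as
bread wheat. Three assumptions shape everything downstream:

1. **Accessions are (nearly) homozygous.** Inbred lines carry one allele per
   site, so a locus haplotype is simply the allele string an accession shows
   at the retained SNPs. Heterozygous calls are treated as noise or residual
   heterozygosity, not as phase-ambiguous diplotypes; no statistical phasing
   or imputation is performed.
2. **The locus is a low-recombination block.** Haplotypes are treated as
   clonal units inherited whole. This is appropriate for a gene cluster of
   roughly a megabase in a selfing species surveyed across a diversity
   panel, and it is why a median-joining network — a genealogy under
   mutation only — is a sensible clustering device.
3. **Sites are biallelic SNPs.** Multi-allelic records and indels are
   excluded on input with a logged warning. All coordinates are 1-based and
   intervals are 1-based inclusive, following the VCF convention, so no
   conversion layer exists anywhere in the package.

## Filtering and haplotype definition

`filter_panel()` applies the two survey filters in a fixed order: sites with
minor-allele frequency above `maf_min` (default 0.05) are kept first, then
accessions whose homozygous fraction across the *kept* sites exceeds
`hom_min` (default 0.80). Both inequalities are strict: a site at exactly
5 % MAF and an accession at exactly 80 % homozygosity are dropped. MAF is
computed over allele counts of non-missing calls (a homozygote contributes
two copies, a heterozygote one of each); the homozygosity denominator is
the non-missing call count, a choice the filter report records. Reading
"allele frequency" as *minor*-allele frequency keeps the rule symmetric
under REF/ALT swaps; an alternate-allele reading would not be.

Two consequences are worth knowing. Raising `maf_min` never increases the
number of kept sites, and raising `hom_min` never increases the number of
kept accessions; but raising `maf_min` *can* increase the number of kept
accessions, because removing sites changes the homozygosity denominator of
borderline accessions. The test suite checks the two monotone components.

`reconstruct_haplotypes()` emits a complete string only for accessions
homozygous at every retained site; anything with a heterozygous or missing
call is reported as unassigned together with the offending sites. We prefer
losing an accession to imputing it: the >80 % homozygosity filter already
encodes the expectation that usable accessions are essentially homozygous.
`enumerate_haplotypes()` then groups identical strings and names them H1,
H2, … by descending carrier count, ties broken by first occurrence in the
input order so output is reproducible.

## Informative SNP subsets and panel typing

Published surveys genotype follow-up panels at a handful of "most
informative" SNPs rather than the full set. No construction algorithm is
standard, so `select_informative_snps()` uses greedy set cover over
haplotype pairs: among sites whose carrier-weighted MAF exceeds `maf_min`
(default 0.30), repeatedly pick the site that splits the most
still-identical haplotype pairs, breaking ties by larger MAF and then by
left-most position. Greedy set cover is not guaranteed minimal, so an
exhaustive search over subsets (feasible for ≤ 12 candidates) is provided
and used as the small-instance oracle in the tests.

`assign_to_haplotypes()` types new panels by exact matching against the
reference haplotypes projected onto the subset. Projection collisions are
reported as compound labels (`H5/H7`) rather than resolved arbitrarily —
the subset genuinely cannot tell those references apart. Novel strings get
panel-specific names (`N1`, …) and het/missing accessions stay unassigned,
mirroring the full-panel policy.

# The median-joining network

`build_msn()` constructs the ε-relaxed minimum spanning network: an edge
(u, v) of Hamming weight w is included iff w ≤ σ(u, v) + ε, where σ(u, v)
is the smallest distance level at which u and v become connected using all
edges of weight ≤ σ. At ε = 0 this is exactly the union of all minimum
spanning trees, so tied alternative connections are retained — the property
that makes the display a *network* rather than an arbitrary tree. The
default ε = 0 matches the default of the usual median-joining software.

`build_mj_network()` adds inferred intermediate haplotypes. For biallelic
strings the quasi-median of a triple reduces to the position-wise majority
string (three distinct states cannot occur at a site), which the
implementation exploits: candidate medians are the majority strings of node
triples, and the candidate that most reduces the minimum spanning cost of
the node set is added, repeating until no candidate pays. Each addition
strictly reduces an integer cost bounded below, so termination is
guaranteed. Inferred medians whose removal leaves the spanning cost
unchanged are then pruned (observed haplotypes never are); survivors are
genuinely internal and have degree ≥ 3 in the final network. Ties among
equally good medians are broken lexicographically for reproducibility.

On every random instance with ≤ 5 observed haplotypes over ≤ 4 sites the
final cost equals a brute-force Steiner search over all candidate internal
strings (see the test suite); on larger instances the construction is, like
all median-joining implementations, a heuristic. Because the exact ε and
star-contraction preprocessing of other programs are rarely reported,
median placement may legitimately differ from published figures even when
the observed-haplotype topology agrees.

# Germplasm statistics

`percent()` rounds to the nearest integer with ties away from zero — the
convention under which published survey percentages (2/41 → 5 %,
11/13 → 85 %) reproduce exactly from their counts. `chi_square_2x2()` is
Pearson's test *without* continuity correction: on the 41-variety
bread-vs-feed table (11/13 vs 10/28 dormant-allele carriers) it gives
8.497, reproducing the published statistic to three decimals; with Yates'
correction the value would differ materially, which is how the convention
was fixed. A warning is emitted when any expected count falls below 5
(one cell of the published table has expectation 6.3, so the test is
within, if near the edge of, the usual validity rule).

# Coefficient of parentage

`cop()` implements the fully-inbred-line convention: COP(x, x) = 1, and
COP(x, y) expands the line with larger generation depth as the mean of the
COPs of the other line with its two parents; unknown parents contribute 0,
so distinct founders have COP 0. For homozygous lines this is the
probability that alleles drawn from the two lines are identical by descent,
and it is the standard convention in wheat germplasm studies (no separate
kinship/2 factor). Memoization makes the all-pairs matrix affordable; the
tests verify it agrees exactly with an un-memoized recursion and, within
three standard errors, with a gene-dropping Monte-Carlo simulation in which
each offspring locus copies a uniformly chosen parent's allele.

`mean_cop()` excludes lines absent from the pedigree table before
averaging: an unrecorded pedigree (typical of landraces) cannot contribute
relatedness and would bias group means toward zero. Recorded founders —
lines present with unknown parents — do participate; excluding them would
make even a pair of founders unanalysable. Pair counts are n(n−1)/2 within
groups and |a|·|b| between disjoint groups. Published group means for
specific national germplasm sets depend on external pedigree databases and
are not reproduced here; the module is validated by oracle equivalence and
pair-count arithmetic instead.

# Assay design

`scan_motif()` matches IUPAC motifs on both strands (via Biostrings),
reporting reverse-strand hits in forward coordinates and deduplicating
palindromic motifs. `digest()` cuts after the `cut_offset`-th motif base
(reverse hits after base `length − cut_offset`), so fragments always sum to
the input length. Hpy166II is modelled as a blunt cutter at `GTN^NAC`
(`cut_offset = 3`); the enzyme table ships as an editable TSV so other
conventions can be swapped in.

`find_caps_candidates()` reports every enzyme whose ladders differ between
the two alleles — site-loss and site-gain assays symmetrically — ranked by
the smallest band separation a gel must resolve (largest first).
`design_kasp()` builds the allele-specific primer records positionally: the
window of `primer_length` bases ending at the SNP on the stated strand,
two variants differing only at the 3′ base, FAM tail on the first-listed
allele and HEX on the second (the dye tails default to the de-facto
standard sequences; only the dyes, not the tails, are usually published).
Primer thermodynamics (Tm, hairpins, genome specificity against homoeologs)
are deliberately out of scope — the surveyed assays were designed by
position, and a specificity screen needs the full polyploid genome.

# The synthetic-data generator

`generate_panel()` emulates the statistical structure of a locus-scale
exome-capture panel: a small set of distinct founder haplotypes (every site
segregating) cloned into accessions, then corrupted per call — missing
with probability `missing_rate` first, else heterozygous with probability
`het_rate`, mutually exclusive so the probability accounting is
unambiguous. Defaults are chosen as study conditions, not tuning knobs:

* `n_founder_haplotypes = 14`, `n_sites = 39`, `n_accessions = 58` — the
  scale of the survey the package emulates.
* `het_rate = missing_rate = 0.05` — the true call-quality rates of such
  panels are unpublished; these are configuration defaults, not claims.
  The acceptance recomputation uses 0.02/0.02 ("low noise").
* `maf_floor = 0.10` — each site's rarer allele is planted on at least two
  of 14 founders. With the default balanced founder assignment this puts
  every site's panel MAF near 14 % or higher, comfortably clear of the 5 %
  filter, so the filters measure call quality rather than destroying the
  planted structure.
* `clean_founder_copy = TRUE` — one accession per founder is exempt from
  corruption, guaranteeing every founder is recoverable by the
  no-imputation reconstruction rule. This encodes the survey condition
  that each haplotype is seen in at least one fully homozygous accession.
* `founder_props` lets a major-haplotype share (e.g. one third of
  accessions) be planted for frequency-structure tests.

What the generator does *not* emulate: recombination or coalescent
structure within the locus (haplotypes are clonal blocks), genotyping error
that flips a homozygote to the other homozygote, linkage to genome-wide
background variation, and ascertainment bias of exome capture. Passing
tests therefore demonstrate correctness of the pipeline's logic under the
stated model, not robustness to recombinant or error-flipped real data.

`generate_amplicon_pair()` plants exactly one motif occurrence spanning a
chosen SNP offset on a random backbone and substitutes the SNP base so the
motif is destroyed without creating a new occurrence on either strand; the
truth record carries the expected ladders for round-trip testing.
`generate_pedigree()` draws each non-founder's two parents from earlier
generations, so pedigrees are acyclic by construction.

# Problem sizes and runtime choices

The test suite exercises: 100-seed recovery and filter-monotonicity sweeps
on panels of up to ~25 accessions; 20-seed runs of the full 58 × 39 panel;
200 random network instances with ≤ 5 observed haplotypes over ≤ 4 sites
(where the brute-force Steiner search is exhaustive); 50 random pedigrees
of ≤ 30 lines with 10⁵ gene drops each. These sizes keep the whole suite
under a minute or two while the brute-force oracles remain exact; the
algorithms themselves handle the full survey scale (the 58 × 39 pipeline
plus its network run in well under a second).

# Known limitations

* Median-joining output beyond the small-instance regime is heuristic, and
  median placement may differ from other implementations with unreported
  preprocessing.
* The accession filter is not monotone in `maf_min` (see above) — an
  inherent property of the two-pass design, not an implementation bug.
* COP treats unknown parents as unrelated founders; ambiguous pedigrees
  therefore bias relatedness downward rather than propagating uncertainty.
* The KASP module emits positional records only; it does not check primer
  thermodynamics or homoeolog specificity.
* VCF support is deliberately narrow: diploid/haploid GT calls on biallelic
  SNPs, which is what locus-restricted inbred-panel files contain.
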