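Package: phshap
Title: Haplotype Analysis and Diagnostic Marker Design for a Wheat Dormancy Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for candidate-locus haplotype analysis in inbred crop panels:
    reading and filtering multi-sample VCF genotype calls over gene intervals,
    reconstructing and enumerating locus haplotypes, selecting informative SNP
    subsets and typing new panels against reference haplotypes, building
    median-joining haplotype networks, allele-frequency and 2x2 contingency
    statistics across germplasm groups, coefficient-of-parentage computation
    over breeding pedigrees, and in-silico design of CAPS (restriction digest)
    and KASP (allele-specific PCR) diagnostic assays. Includes a synthetic-data
    generator that emulates an exome-capture diversity panel with planted
    founder haplotypes so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    stats,
    utils,
    vcfR
Suggests:
    ape,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
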