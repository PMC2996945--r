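Package: aimpanel
Title: Ancestry-Informative Marker Panels for Admixture Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Construction and evaluation of ancestry-informative marker (AIM)
    panels for admixture mapping in two-way admixed populations, starting from
    dense SNP-array genotypes of two parental reference populations. Implements
    per-SNP differentiation statistics (allele-frequency differential delta,
    Wright's two-population F_ST, Shannon information content), a six-step
    iterative bin-based AIM selection algorithm with linkage-disequilibrium
    pruning, variance-inflation-factor pruning for random marker panels,
    genotype quality control (call rates, minor allele frequency, exact
    Hardy-Weinberg test), a two-ancestry hidden Markov model under the
    hybrid-isolation demographic model for local-ancestry posteriors,
    individual admixture and generations-since-admixture estimation,
    entropy-based map power, and the case-only locus-genome LOD and
    case-control z admixture-mapping statistics. Includes readers and writers
    for PLINK .ped/.map, VCF and EIGENSTRAT-style genotype files, genetic-map
    interpolation, and a seeded synthetic-data generator for parental panels
    and admixed case/control cohorts with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
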