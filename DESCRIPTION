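Package: palaeogen
Title: Population-Structure Analysis of Low-Coverage Ancient Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for population-genetic analysis of
    low-coverage ancient genomes: pseudo-haploid calling and imputed-call
    handling with posterior-probability, transversion, completeness and
    minor-allele-frequency filters; authentication estimators (genetic sex
    from Y-read fractions, mismatch-based contamination, post-mortem
    deamination profiles); D- and f-statistics with weighted block-jackknife
    standard errors and F4-ratio admixture proportions; Li-Stephens
    haplotype painting with coancestry matrices, donation-vector contrasts,
    total variation distance and greedy marginal-likelihood clustering;
    polygenic trait scores with odds-ratio conversion and temporal and
    ancestry analyses; and extended haplotype homozygosity decay and
    furcation structure. A synthetic-cohort generator reproduces the
    statistical structure of the data the pipeline assumes (differentiated
    source populations, admixed individuals with known ancestry tracts,
    Poisson low-coverage reads with sequencing error and C-to-T
    deamination, and imputed-like diploid calls) so every stage can be
    validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
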