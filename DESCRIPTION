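Package: genemeta
Title: Genetic Association Meta-Analysis from Genotype Counts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Meta-analysis of case-control genetic association studies starting
    from per-study genotype counts. Builds 2x2 contrast tables under the five
    classical genetic models (allele, dominant, recessive, homozygote,
    heterozygote), pools odds ratios with Mantel-Haenszel fixed effects
    (Robins-Breslow-Greenland variance) or DerSimonian-Laird random effects,
    quantifies heterogeneity with Cochran's Q and I-squared, screens control
    arms for Hardy-Weinberg equilibrium, and runs subgroup, leave-one-out
    sensitivity, and Egger/Begg publication-bias analyses. Includes a packaged
    dataset of Fas and FasL promoter polymorphisms in preeclampsia and a
    simulator of multi-study genotype data with known truth for estimator
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    withr
Config/testthat/edition: 3
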