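Package: snvppv
Title: Beta-Binomial Estimation of the True-Positive Proportion of SNV Call Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the positive predictive value (PPV, the proportion of
    true positives) of a human single-nucleotide-variant call list from
    call-set summary statistics alone. Fits Beta-binomial regression models
    in the (mu, sigma) parameterization with covariate-dependent mean (logit
    link) and dispersion (log or Box-Cox link), produces Normal-approximation
    95% prediction intervals for the observed PPV, evaluates leave-one-out
    coverage, performs AIC-gated backward elimination and dispersion-link
    scans, and supplies GLM-style diagnostics (randomized quantile residuals,
    Binomial hat values, Cook's distances). Includes a gold-standard
    validation engine (TP/FP/FN/PPV/sensitivity against a truth set), VCF/BED
    ingestion with SNV filtering, call-set quality statistics (Ti/Tv,
    Het/Hom, depth summaries), and a seeded synthetic-data generator for
    training tables and toy truth/call VCF pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
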