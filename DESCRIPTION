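Package: mrmediate
Title: Drug-Target Mendelian Randomization with Metabolite Mediation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-sample Mendelian randomization (MR) toolkit for drug-target
    analyses with mediation through circulating metabolites. Provides GWAS
    summary-statistic containers with cross-cohort allele harmonization,
    cis-window instrument construction with a colocalization gate and greedy
    LD clumping, the full univariable estimator suite (Wald ratio, inverse
    variance weighted, MR-Egger, weighted median, mode-based) with
    heterogeneity, pleiotropy and leave-one-out diagnostics, the MR-PRESSO
    global, outlier and distortion tests, Bayesian model averaging for
    multivariable MR (marginal inclusion probabilities and model-averaged
    causal effects with permutation p-values), metabolite-wide screening with
    Benjamini-Hochberg control, two-step MR mediation with proportion
    mediated, a seeded generator of three-cohort summary statistics under a
    known exposure-mediator-outcome structural model, and a config-driven
    pipeline runner producing reproducible delimited-text reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils-internal.R'
    'sumstats-io.R'
    'harmonize.R'
    'instruments.R'
    'coloc.R'
    'estimators.R'
    'presso.R'
    'mrbma.R'
    'mediation.R'
    'simulate.R'
    'pipeline.R'
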