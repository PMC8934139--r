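Package: bayesbmd
Title: Bayesian Benchmark Dose Modeling for Genomic Dose-Response Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Probe-level screening and Bayesian model-averaged benchmark
    dose (BMD) estimation for transcriptomic dose-response experiments.
    Screens probes by fold change, one-way ANOVA and Williams-type
    monotone trend tests with permutation or bootstrap null distributions,
    fits seven continuous dose-response models (linear, power, Hill and
    four exponential forms) by adaptive Metropolis MCMC under a normal
    likelihood, combines them by posterior model weights into a
    model-averaged BMD posterior with BMDL/BMDU credible bounds, and
    aggregates gene-level BMDs into pathway summaries with Fisher exact
    enrichment and a biological-effect point of departure (BEPOD). Includes
    a synthetic dose-response experiment generator with known true BMDs
    for validation, and an end-to-end pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
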