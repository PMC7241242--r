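Package: gemtailor
Title: Context-Specific Genome-Scale Metabolic Models from Expression Data
Version: 0.1.0
Authors@R:
    person("gemtailor", "developers", email = "gemtailor@example.org",
           role = c("aut", "cre"))
Description: Tailors condition- and time-specific genome-scale metabolic
    models (GEMs) from gene expression data with the GIMME algorithm,
    estimates flux distributions by norm-regularized flux balance analysis,
    screens reactions for their contribution to biomass production by
    single-reaction deletion and insertion experiments, and compares
    conditions through flux and flux-sum fold-change profiles clustered by
    correlation. Includes SBML input/output for a COBRA-style model subset,
    a bundled synthetic drought time-course scenario with planted ground
    truths for end-to-end testing, and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    quadprog,
    xml2,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
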