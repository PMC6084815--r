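Package: twinmeth
Title: Genetic and Environmental Decomposition of DNA Methylation in Twin Cohorts
Version: 0.1.0
Authors@R:
    person("E-Risk", "Methods", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide twin analyses of DNA methylation measured on
    beta-value scale arrays: per-site ACE (additive genetic / shared environment /
    unique environment) variance decomposition by full-information maximum
    likelihood on MZ/DZ twin pairs, summary-statistic and Falconer estimators,
    probe variability classification, double-entry twin correlations with exact
    log-space sign tests, feature/mQTL/cross-tissue enrichment analyses, a
    cluster-robust exposure EWAS, and a synthetic twin-cohort generator with
    known per-site variance structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
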