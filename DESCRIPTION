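Package: seltrend
Title: Two-Target Selectivity Profiling and Hansch SAR Analysis of
    Bioactivity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Curates ChEMBL-style bioactivity tables for a pair of protein
    targets (designed around the human serotonin and dopamine transporters),
    converts potencies to negative log molar activities, assigns binary
    activity labels against drug-anchored cutoffs with censoring-aware rules,
    builds compound-by-target overlap matrices with median label aggregation,
    clusters compounds by Bemis-Murcko scaffolds and classifies scaffold
    selectivity trends, flags hERG liabilities, extracts substructure-defined
    SAR series, and fits classical Hansch multiple linear regressions with
    backward descriptor elimination. Includes seeded synthetic-data
    generators emulating the statistical structure of public transporter
    bioactivity data so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
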