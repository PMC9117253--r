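Package: ubidyn
Title: Quantitative Ubiquitinome Dynamics from Label-Free diGly Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantitative analysis of ubiquitinome
    dynamics from label-free diGly-site and protein-group intensity tables.
    Reads MaxQuant-style site tables and Spectronaut-style wide DIA reports,
    applies identification filters, imputes left-censored missing values from
    a down-shifted normal distribution, and tests treatment-versus-control
    contrasts with an S0-moderated two-sample t statistic and SAM-style
    permutation-based FDR. Downstream modules classify substrate fold-change
    profiles over a time course, tabulate treatment-exclusive identifications,
    map diGly peptides onto ubiquitin and ubiquitin-like modifier (NEDD8,
    SUMO1/2/3) reference sequences for chain-linkage profiling, and build
    positional amino-acid frequency profiles around modified lysines. A
    synthetic-data generator with known ground truth (planted effects,
    intensity-dependent missingness) makes every stage testable without raw
    mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
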