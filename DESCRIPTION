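Package: lipidomix
Title: Lipidomics Shorthand Parsing, Differential Analysis, Enrichment and
    Reaction-Network Activity Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-group lipidomics studies: a parser for lipid
    shorthand nomenclature (sum-composition and molecular-species levels,
    with dialect normalization), structural characterization of lipid
    species (class, chain length, unsaturation, ether linkage),
    preprocessing and cross-sample profiling (PCA, t-SNE, UMAP-style
    embedding, sample correlation), species- and characteristic-level
    differential abundance testing with a dual chain-length by double-bond
    grid, lipid-set enrichment by over-representation (Fisher exact) and a
    ranked running-sum statistic with a permutation null, and
    direction-aware activity scoring of lipid-class reaction networks.
    Includes a seeded synthetic-experiment generator with planted group
    effects for power and calibration studies, plus a command-line
    pipeline producing tabular outputs and a reproducibility manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
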