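Package: depsinet
Title: Annotation, De Novo Sequencing and Environmental Statistics for
    Cyclic Depsipeptide Metabolomics
Version: 0.1.0
Authors@R:
    person("Schoenmakerskop", "Pipeline Maintainers", email = "depsinet@example.org",
           role = c("aut", "cre"))
Description: Exact-mass annotation and de novo residue sequencing of cyclic
    depsipeptides from MS2 spectra, together with the surrounding
    environmental-metabolomics workflow: feature-table cleaning (washout
    removal, blank subtraction, TIC normalization), feature-based molecular
    networking with modified-cosine scoring and ion-identity adduct grouping,
    Bray-Curtis ordination with PERMANOVA, and microbe-metabolite Spearman
    correlation with Benjamini-Hochberg FDR control. Ships a deterministic
    synthetic-data generator with queryable ground truth so every stage is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
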