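Package: tagstore
Title: Quantification of Lipid Droplet and Triacylglycerol Storage and
    Turnover in Trypanosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for fatty-acid storage experiments in procyclic
    trypanosomes: fold-change estimation of lipid-droplet induction from
    microscopy counts, flow cytometry and TLC densitometry; shotgun-lipidomics
    triacylglycerol (TAG) species parsing, internal-standard normalization and
    class aggregation; exponential growth-curve fitting; a division-dilution
    null model of stored-lipid decay with a kinetic extension (basal synthesis
    plus first-order catabolism) and a one-sided test for net catabolism;
    label-free two-genotype proteome ratio analysis; and marker-enzyme
    enrichment bookkeeping for subcellular fractions. Includes a seeded
    synthetic-data generator emulating every input table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
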