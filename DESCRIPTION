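Package: qmpcms
Title: Quantitative Microbiome Profiling and Community Modulation Scores
    for Ex Vivo Fermentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative (flow-cytometry-scaled) 16S rRNA gene
    profiling of ex vivo gut fermentation experiments. Converts OTU read
    counts to estimated absolute abundances (cells/mL) using total cell
    densities, models the per-sample limit of detection and imputes
    sub-detection values, computes traditional alpha-diversity indices and
    the community modulation score (CMS), performs paired
    treatment-versus-control testing across donors with Benjamini-Hochberg
    FDR control and a consistency classification, and summarises
    fermentation metabolites (SCFA, bCFA, gas, pH). Includes a synthetic
    generator for donor-by-condition fermentation experiments with planted
    effects and ground truth for recovery testing.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    vegan
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
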