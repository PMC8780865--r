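Package: hlctox
Title: Toxicogenomic Dose-Response Analysis for Hepatocyte-Like Cell Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for targeted-RNA-seq
    toxicogenomics studies on stem-cell-derived hepatocyte-like cells.
    Computes LDH-based cytotoxicity percentages and four-parameter logistic
    dose-response fits with ICx estimation and acute-toxicity classification;
    fits per-gene negative-binomial concentration-response models with Wald
    tests and Benjamini-Hochberg adjustment; scores stress-pathway
    overrepresentation with a hypergeometric z-score; builds signed
    co-expression networks with topological-overlap module detection, module
    eigengenes, kME and rank-based module-activity scores; selects candidate
    stress genes by cluster centrality, differential expression and curated
    evidence; and benchmarks fold-change concordance across hepatocyte
    models with per-gene similarity ratios and recovery curves. A seeded
    synthetic-data generator produces ground-truthed plates, count matrices
    with planted modules and pathway effects, and paired fold-change tables
    so every stage is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    minpack.lm,
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    knitr,
    mclust,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
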