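Package: gradexpr
Title: Pooled-Library RNA-Seq Differential Expression and Carcass Trait
    Analysis Across Beef Quality Grades
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for pooled muscle RNA-seq and carcass data
    from beef steers of differing USDA quality grades. Implements the
    per-gene pooled z-test on condition-summed read proportions (with a
    variance-stabilizing square-root transform), Bonferroni correction,
    fold-change and direction classification, gene-set over-representation
    of up- and downregulated gene lists (Fisher exact and EASE modes over
    GMT collections), and fixed-effects least-squares-means summaries of
    carcass and Warner-Bratzler shear-force traits with compact letter
    displays. A calibrated synthetic-data generator produces per-animal
    gene counts pooled into grade-level libraries and additive-model
    phenotypes, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    withr,
    emmeans,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
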