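Package: megaexpr
Title: Mega-Analysis of Multi-Study Case/Control Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gene-wise combination of case/control expression studies in
    which the log2 fold change of every gene is re-estimated from each
    study's original expression matrix ("mega-analysis") and combined
    across studies by inverse-variance weighting, with Cochran's Q and
    the I-squared statistic driving a per-gene choice between the
    fixed-effect and the DerSimonian-Laird random-effects model.
    Includes literature gene-list overlap testing (right-tail Fisher /
    hypergeometric), study-level moderator regression of effect sizes on
    sample size, country and study age, gene-set over-representation
    analysis with Benjamini-Hochberg false-discovery control, a
    seed-reproducible multi-study expression simulator with known truth,
    and a configuration-driven pipeline tying the stages together.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
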