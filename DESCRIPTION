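Package: dietfx
Title: Kinship-Aware Differential Expression, Differential Co-Expression,
    and Diet-Behavior Mediation for Primate Diet Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for diet-intervention studies in group-housed
    primates that profile purified immune-cell transcriptomes alongside
    behavior. Implements per-gene linear mixed models with a kinship
    (polygenic) random effect solved by eigendecomposition, permutation-based
    empirical false discovery rates, gene-set enrichment by label permutation,
    Fisher and hypergeometric tests, differential co-expression via
    correlation-by-individual-level-products (CILP) with a pair-resampling
    hub-gene null, ethogram summarisation with a principal-component composite
    of diet-altered behavior (DAB), and bidirectional bootstrap mediation
    between diet, behavior, and gene expression. A synthetic-study generator
    with recorded ground truth makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fgsea,
    generics,
    ggplot2,
    limma,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
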