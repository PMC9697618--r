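Package: nlivr
Title: Bioequivalence with Reference-Variability-Narrowed Limits for
    Narrow Therapeutic Index Drugs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate average-bioequivalence decision rules in
    which the acceptance range for narrow therapeutic index (NTI) drugs
    is narrowed in proportion to the within-subject variability of the
    reference product (limits exp(+/- k * s_WR), floored at 90.00-111.11
    per cent and capped at 80.00-125.00 per cent), optionally combined
    with a constraint on the geometric mean ratio point estimate.
    Provides the acceptance-limit geometry, a subject-level simulator and
    a fast summary-statistic simulator for the 2x3x3 partial replicate
    (TRR/RTR/RRT) crossover design, the TOST confidence-interval
    decision, Monte-Carlo power and type-I-error surfaces over (n, CV)
    grids, exact TOST power via Owen's Q for fixed limits, and
    simulation-based sample-size determination for the scaled rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
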