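Package: seamountEBSA
Title: Ecosystem Evaluation of Seamounts Against the EBSA Criteria
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores individual seamounts against the Convention on Biological
    Diversity criteria for Ecologically or Biologically Significant Areas
    (EBSA) using ten weighted presence/absence indicators, quantifies
    human-induced threats from the fishing and mining activities present via
    an activity-by-ecological-group impact matrix, attaches an evidence-based
    data-uncertainty index to both scores, and classifies seamounts into a
    four-cell conservation portfolio. Includes a backtracking constraint
    solver that reconstructs an impact matrix from published (activity set,
    threat score) pairs, a dummy-seamount simulator for robustness testing,
    eight fully transcribed case-study seamounts, and ggplot2 portfolio and
    radar displays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    tibble,
    tidyr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
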