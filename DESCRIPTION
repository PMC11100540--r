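Package: wmltm
Title: Hierarchical Models of Working Memory and Episodic Long-Term Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Generative simulators and Bayesian inferential models for
    paired-associate working-memory experiments that manipulate the
    availability of pre-learned episodic long-term memory (LTM) traces.
    Provides trial-schedule builders for four experimental designs
    (4-alternative forced-choice word-pair tasks under crossed WM/LTM
    load, and continuous colour-reproduction tasks with new, old-match
    and old-mismatch conjunctions), an aggregated binomial logistic
    hierarchical model with Savage-Dickey and directed Bayes factors,
    a hierarchical von Mises mixture model separating target retrieval,
    swap errors, LTM intrusions and guessing, participant screening
    rules, Cousineau-Morey within-subject confidence intervals, and an
    end-to-end parameter-recovery study runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    rjags,
    coda,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
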