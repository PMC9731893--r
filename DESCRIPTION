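Package: prlqlearn
Title: Q-Learning Analysis of Probabilistic Reversal Learning Behaviour
Version: 0.1.0
Authors@R: person("PRL", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Trial-by-trial reinforcement-learning analysis of two-choice
    probabilistic reversal learning (PRL) data. Implements three Q-learning
    model variants (delta-rule value update, softmax choice with an optional
    stickiness term, and separate learning rates for rewarded and
    non-rewarded trials), exhaustive grid-search maximum-likelihood fitting
    per subject and session, model comparison (log-likelihood ratio,
    pseudo-r2, BIC), conventional PRL measures (win-stay, lose-shift,
    trials to criterion, perseverative responses), Pearson correlation of
    model parameters with conventional measures under FDR control, and a
    task/agent simulator for cohort-level validation and parameter-recovery
    studies.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
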