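Package: survgame
Title: Two-Player Iterated Survival Games with Switch-Once Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact analysis of two-player iterated survival games in which
    payoffs are survival probabilities and each player switches once from
    cooperation (C) to defection (D). Provides closed-form n-step survival
    payoffs from absorbing Markov chain matrix powers together with an
    independent matrix-product oracle and a Monte-Carlo game simulator; the
    analytic loner-survival cutoffs governing incentives to defect or
    cooperate more; classification of the ten incentive structures into five
    qualitative types; local and global strict Nash (ESS) stability and
    stretches of equilibria or disequilibria; deterministic best-response
    walks and terminal-cycle detection on the payoff surface; and a random
    sampling survey of the Prisoner's Dilemma parameter space. Includes a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
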