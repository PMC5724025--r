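Package: mimicbayes
Title: Hierarchical Bayesian Analysis of Insect Visitation in Floral
    Self-Mimicry Systems
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing insect visitation trails to rewarding
    (male, "model") versus rewardless (female, "mimic") flowers in
    monoecious plants with a self-mimicry pollination system.  Per-insect
    duping probabilities are modelled with a hierarchical beta-binomial
    framework under three model structures (shared concentration,
    independent per-treatment concentrations, and an overarching
    gamma-distributed concentration) and two prior conditions; posterior
    inference uses a custom Metropolis-within-Gibbs sampler with
    Gelman-Rubin and effective-sample-size diagnostics, highest density
    interval summaries, posterior difference distributions, and deviance
    information criterion model comparison.  A synthetic trail generator
    supports parameter-recovery experiments, and companion frequentist
    routines (one-way ANOVA, Tukey HSD, two-sample t, chi-square goodness
    of fit) cover the reproductive side of such studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
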