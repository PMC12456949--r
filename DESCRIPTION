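Package: harmaversion
Title: Harm-Aversion Modelling of Money-Pain Trade-Off Choices
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.com",
    role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing money-pain trade-off
    experiments on moral decision-making. Builds factorial trial sets pairing
    monetary amounts with electric-shock counts, fits a softmax harm-aversion
    model (per-condition kappa, choice-consistency gamma) by multi-start
    maximum likelihood, estimates per-subject money/shock choice sensitivities
    by penalized logistic regression, runs trait-interaction regressions,
    moderated mediation with a subject-level cluster bootstrap, within-subject
    ANOVA with partial eta squared, Friedman tests, and noncentral-F post-hoc
    power. A synthetic-cohort generator reproduces the statistical structure of
    such studies (context-specific hyperaltruism, trait correlations, a
    framing-mediated pathway) so the full pipeline is testable without human
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
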