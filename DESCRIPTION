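Package: chronoval
Title: Modelling and Analysis of the Mental Association Between Time and Valence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the mental association between deictic time
    (past/future) and emotional valence (negative/positive) in speeded
    word-categorisation experiments. Provides an interactive-activation
    network model of the reaction-time "match effect" with two wiring
    variants (symmetric agonist links versus a future-positive-only link),
    seeded generators for trial-level reaction-time experiments, Likert
    valence-rating surveys and toy corpora with designed time-valence
    co-occurrence structure, an analysis pipeline with outlier filtering,
    condition summaries, subject-level permutation inference and a
    first-versus-second-half practice analysis, a mixed-design ANOVA with
    a standardised effect size for rating data, and toy distributional
    semantic models (LSA over word-by-document counts, HAL over windowed
    word-by-word counts) with cosine-similarity category contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4
Config/testthat/edition: 3
RoxygenNote: 7.3.3
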