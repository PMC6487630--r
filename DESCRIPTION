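Package: earlygrowth
Title: Fetal and Infant Growth Patterns and Childhood Adiposity
Version: 0.2.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how fetal and infant weight trajectories
    relate to general, visceral and organ fat in childhood. Implements
    Hadlock estimated fetal weight, internally constructed age- and
    sex-specific reference charts and standard deviation scores (SDS),
    centile-crossing growth-pattern classification (the 0.67-SDS rule)
    with the 24-to-11-to-6-month infant weight fallback, conditional
    growth regression via standardized residuals, Reed1 infant weight
    modelling with derived peak weight velocity, a cubic mixed model on
    log BMI with derived age and BMI at adiposity peak, allometric
    (log-log) height-power adiposity indices, covariate-adjusted linear
    association models with chained-equation multiple imputation and
    Rubin pooling, and a synthetic longitudinal cohort generator that
    emulates the data structure these analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
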