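Package: facepref
Title: Parental Speech Exposure and Infant Face Preference
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies preterm infants' exposure to their parents' speech
    during neonatal intensive care by fusing wearable-recorder adult word
    counts with caregiver presence diaries, scores infant eye-tracking
    disengagement trials into face-preference measures, and relates the two
    with rank-based statistics: paired Wilcoxon tests with z/sqrt(N) effect
    sizes, partial Spearman correlations with covariate adjustment, and an
    exhaustive twin-subset sensitivity analysis. A synthetic cohort
    simulator with known ground-truth parameters makes every stage testable
    without access to confidential study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
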