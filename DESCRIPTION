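Package: ftirap
Title: Scoring and Split-Plot Analysis of the Future Thinking IRAP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for latency-based implicit future-expectancy measures built
    on the Future Thinking Implicit Relational Assessment Procedure (FT-IRAP).
    Generates the alternating consistent/inconsistent block schedules, applies
    the standard D-score algorithm (trial filtering, participant exclusion,
    per-block trial-type cell means, pooled-SD normalised difference scores),
    scores CESD-R and visual analogue mood scales, and fits the split-plot
    (mixed) ANOVA/ANCOVA models used to analyse group-by-trial-type effects,
    with Bonferroni post-hoc tests, effect sizes and marginal means. Includes
    a calibrated synthetic cohort generator with known ground-truth D values
    per trial type so the whole pipeline can be validated by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, e1071, jsonlite
Suggests: testthat (>= 3.0.0), car, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
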