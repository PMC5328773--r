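Package: bkcolony
Title: Breeding-Colony Surveillance Analytics for BK-Channel Knockout Mice
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis toolkit for surveillance records of a heterozygote-by-
    heterozygote BK-channel (Kcnma1) knockout mouse breeding colony. Provides
    Mendelian segregation chi-square tests over six sex-by-genotype categories,
    an alternative cohort-size estimator (Mendelian2) that recovers losses
    occurring by non-Mendelian mechanisms via integer chi-square-component
    minimization, per-litter deviation-ratio screens, pup-mortality timecourse
    and litter-success summaries, post-weaning growth-gain and growth-pause
    analysis with average-shifted-histogram weight densities, quantitative
    magnetic resonance body-composition geometry including an origin-preserving
    two-angle rotation of lean-fat-water proportion space, and a seeded
    synthetic-colony generator so every stage runs end to end without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
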