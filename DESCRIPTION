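Package: smhat
Title: School Menu Healthiness Assessment and Affordability Auditing
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A configurable menu-auditing engine for assessing the
    healthiness of primary and secondary school food provision against
    food-based criteria. Scores rotational menu cycles with a data-driven
    codebook (absent/0/1 and incremental per-day ratings, week totals
    averaged across the cycle), validates coding through intercoder
    reliability statistics (per-item dispersion, pairwise agreement,
    Cohen's kappa with McHugh interpretation bands), analyses whether
    free-school-meal allowances cover the priced offering (meal-deal
    disparities, residual allowance, category price summaries), and
    generates synthetic menus, price lists and noisy coder ratings with
    controllable healthiness and agreement for testing and training.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
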