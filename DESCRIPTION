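Package: mealswap
Title: Diet-Substitution Modeling of Usual Nutrient Intake and Adequacy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling the effect of food substitutions on population
    nutrient intake from repeated 24-hour dietary recalls. Identifies the most
    commonly consumed dishes at each eating occasion, substitutes a replacement
    dish on a gram or calorie basis, estimates usual (long-run average) nutrient
    intake distributions with a Box-Cox mixed measurement-error model including
    a two-part option for episodically consumed nutrients, computes the
    prevalence of not meeting Estimated Average Requirement, Upper Limit and
    percent-of-energy recommendations, and summarizes change across all
    nutrients with a standard-error-weighted total nutrient index. Variances
    under complex survey designs are estimated by balanced repeated replication
    with optional Fay perturbation. A synthetic recall-data generator with
    known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
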