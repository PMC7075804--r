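Package: snacknrf
Title: Nutrient Density Scoring and Ingredient-List Classification for Snack Foods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes Nutrient Rich Food (NRFn.3) nutrient-density scores on a
    per-100 kcal basis, with the NRF8.3 configuration (eight qualifying
    nutrients, three nutrients to limit) as the shipped default. Parses
    back-of-pack ingredient lists in order of predominance and applies
    first-ingredient rules for dairy and fruit together with
    fruit-vegetable-nut (FVN) presence detection. Aggregates scored products
    into What We Eat in America (WWEIA) snack categories, compares
    ingredient-defined groups with one-way ANOVA, and ships a seedable
    synthetic snack-composition generator calibrated to published summary
    statistics for a four-country market survey of children's snacks, so the
    whole pipeline can be exercised without access to proprietary product
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
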