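#' Published calibration targets: per-category summary statistics
#'
#' Summary statistics of the four-country market survey of 261 children's
#' snacks that the synthetic-data generator is calibrated against: per WWEIA
#' category, the product count and the mean/SD of energy density
#' (kcal/100 g), of the LIM sub-score and of the NRF8.3 score, plus the
#' category's WWEIA codes. The raw product-level data are proprietary and
#' not redistributable; these aggregates are the published reference the
#' generator reproduces in expectation (energy density and counts exactly as
#' targets; LIM/NRF category means are descriptive only, since the
#' group-level nutrient calibration takes precedence — see the package
#' vignette).
#'
#' @return Tibble with columns `row_index`, `label`, `n`, `ed_mean`,
#'   `ed_sd`, `lim_mean`, `lim_sd`, `nrf_mean`, `nrf_sd`, `codes`
#'   (semicolon-separated WWEIA codes).
#' @examples
#' sum(snack_category_targets()$n) # 261
#' @export
snack_category_targets <- function() {
  tibble::tribble(
    ~row_index, ~label, ~n, ~ed_mean, ~ed_sd, ~lim_mean, ~lim_sd, ~nrf_mean, ~nrf_sd, ~codes,
    1L,  "Low fat milk, plain and flavored",   6L,  59, 22, 16.09,  6.16,  37.67, 24.48, "1004;1006;1204;1206",
    2L,  "Cheese",                            13L, 293, 114, 22.95, 10.31,  14.38, 15.99, "1602",
    3L,  "Yogurt, whole/reduced",             21L,  96,  26, 23.38,  8.10,  25.49, 29.30, "1802",
    4L,  "Yogurt, low fat/non-fat",           18L,  80,  18, 18.20,  8.26,  30.25, 18.59, "1804",
    5L,  "Nuts and seeds",                    16L, 504,  97, 14.28,  9.89,   2.72, 13.99, "2804",
    6L,  "Muffins, biscuits",                  2L, 428,  29, 13.82,  4.75,  13.57, 31.59, "4402",
    7L,  "Potato chips",                       6L, 534,  22,  8.60,  2.97,   1.98,  9.60, "5002",
    8L,  "Corn chips",                         4L, 508,  24,  7.08,  3.82,  -1.93,  3.94, "5004;5008",
    9L,  "Popcorn",                            2L, 541,  21, 11.41,  1.64,  -0.62,  7.24, "5006",
    10L, "Crackers",                          10L, 463,  36, 11.59,  3.84,   0.66,  8.11, "5202;5204",
    11L, "Cereal bars",                       15L, 390,  35, 11.49,  6.72,  22.06, 21.03, "5402",
    12L, "Nutrition bars",                     2L, 378,  40, 13.81, 13.88,  42.01,  2.61, "5404",
    13L, "Cakes, cookies, brownies",          27L, 438,  55, 22.42,  7.86,  -9.53, 11.46, "5502;5504;5506",
    14L, "Candy, chocolate",                  19L, 517,  34, 32.02,  8.16, -21.79,  7.63, "5702",
    15L, "Candy, fruit",                      27L, 331,  68, 12.67, 13.83,  22.38, 44.44, "5704",
    16L, "Ice cream",                          8L, 209,  80, 31.72,  5.19, -11.79, 11.39, "5802",
    17L, "Pudding/dairy dessert",             16L, 140,  47, 30.22,  8.69,  -2.62, 17.09, "5804",
    18L, "Ices",                               2L, 108,  35, 35.75,  2.62,  26.85, 58.33, "5806",
    19L, "Apples, bananas, berries",          18L,  79,  71,  2.69,  7.24,  48.88, 45.87, "6002;6004;6010",
    20L, "Fruit, dried",                       2L, 316,  23,  0.59,  0.29,  19.58,  2.76, "6016",
    21L, "Fruit salad",                        7L,  70,   8, 10.08, 15.86,  40.62, 36.78, "6018",
    22L, "Citrus, apple, and other juices",    7L,  48,   2,  0.33,  0.26,  67.55, 24.11, "7002;7004;7006",
    23L, "Sugar sweetened sodas",              5L,  59,  55, 44.61, 17.25, -43.98, 16.94, "7202",
    24L, "Fruit based soft drinks",            8L,  40,  10, 30.46, 18.51,  -1.90, 38.57, "7204"
  )
}

#' Published calibration targets: ingredient-defined group comparisons
#'
#' Group means and SEMs (per 100 kcal, as %DV or %MRV) from the same market
#' survey, for the two ingredient-defined contrasts: products with dairy or
#' fruit as the first listed ingredient (n = 115) versus neither (n = 146),
#' and products containing fruit/vegetables/nuts (n = 88) versus not
#' (n = 173). These rows calibrate the generator's class profiles and
#' provide exact internal-consistency checks (the NR sub-score is the sum of
#' the eight %DV rows; LIM is the sum of the saturated-fat, added-sugar and
#' sodium %MRV rows; NRF = NR - LIM).
#'
#' @return Long tibble with columns `contrast` (`"first_ingredient"` or
#'   `"fvn"`), `group` (`"fruit_or_dairy"`, `"neither"`, `"fvn"`,
#'   `"no_fvn"`), `n`, `variable`, `mean`, `sem`.
#' @examples
#' snack_group_targets() |> dplyr::filter(variable == "nrf_score")
#' @export
snack_group_targets <- function() {
  vars <- c("pct_dv_protein", "pct_dv_fiber", "pct_dv_vitamin_a",
            "pct_dv_vitamin_c", "pct_dv_vitamin_d", "pct_dv_calcium",
            "pct_dv_iron", "pct_dv_potassium",
            "pct_mrv_satfat", "total_sugar_pct_mrv", "pct_mrv_added_sugar",
            "pct_mrv_sodium",
            "energy_density", "nr_subscore", "lim_subscore", "nrf_score")
  g <- function(contrast, group, n, means, sems) {
    tibble::tibble(contrast = contrast, group = group, n = n,
                   variable = vars, mean = means, sem = sems)
  }
  dplyr::bind_rows(
    g("first_ingredient", "fruit_or_dairy", 115L,
      c(6.13, 3.63, 5.48, 12.14, 3.03, 10.40, 1.47, 3.35,
        5.29, 16.28, 9.25, 2.06,
        126, 45.65, 16.60, 29.05),
      c(0.46, 0.58, 0.80, 2.30, 0.48, 1.08, 0.33, 0.22,
        0.64, 0.76, 0.92, 0.21,
        9, 2.46, 1.20, 3.01)),
    g("first_ingredient", "neither", 146L,
      c(2.71, 2.39, 1.15, 6.16, 0.31, 2.44, 3.08, 0.99,
        6.00, 10.62, 11.66, 2.53,
        395, 19.12, 20.19, -1.07),
      c(0.18, 0.28, 0.43, 1.50, 0.11, 0.35, 0.32, 0.10,
        0.47, 0.65, 1.10, 0.18,
        12, 1.80, 1.11, 2.25)),
    g("fvn", "fvn", 88L,
      c(4.03, 5.04, 2.81, 15.98, 1.66, 5.30, 2.16, 2.96,
        3.42, 16.89, 8.34, 1.21,
        213, 40.00, 12.97, 26.99),
      c(0.43, 0.60, 0.74, 2.90, 0.42, 1.26, 0.44, 0.26,
        0.47, 0.94, 1.06, 0.13,
        20, 3.30, 1.35, 3.93)),
    g("fvn", "no_fvn", 173L,
      c(4.31, 1.86, 3.17, 5.13, 1.35, 6.27, 2.49, 1.55,
        6.84, 11.19, 11.67, 2.89,
        309, 26.16, 21.49, 4.68),
      c(0.31, 0.30, 0.56, 1.27, 0.26, 0.57, 0.28, 0.14,
        0.51, 0.58, 0.96, 0.19,
        13, 1.82, 0.97, 2.14))
  )
}
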