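#' Scatterplots of nutrient density against energy density
#'
#' Four standard views of a scored dataset: nutrient density (NRF score per
#' 100 kcal, x axis) against energy density (kcal/100 g, y axis), and the
#' NR sub-score against the LIM sub-score, each at category level (point
#' size proportional to the number of products) and at product level.
#'
#' @param category_summary Output of [summarize_categories()] (the overall
#'   `"Total"` row is dropped).
#' @param scores Output of [score_products()].
#' @return A ggplot object.
#' @examples
#' prods <- generate_dataset(default_config(), seed = 1)
#' plot_product_ed_nrf(score_products(prods))
#' @export
plot_category_ed_nrf <- function(category_summary) {
  dat <- category_summary[!is.na(category_summary$row_index), ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$nrf_mean, y = .data$ed_mean,
                                    size = .data$n)) +
    ggplot2::geom_point(alpha = 0.6, colour = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2.5,
                       vjust = -1, check_overlap = TRUE) +
    ggplot2::labs(x = "NRF nutrient density score (per 100 kcal)",
                  y = "Energy density (kcal/100 g)",
                  size = "Products",
                  title = "Energy density vs nutrient density by category") +
    ggplot2::theme_minimal()
}

#' @rdname plot_category_ed_nrf
#' @export
plot_category_lim_nr <- function(category_summary) {
  dat <- category_summary[!is.na(category_summary$row_index), ]
  dat$nr_mean <- dat$nrf_mean + dat$lim_mean
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$nr_mean, y = .data$lim_mean,
                                    size = .data$n)) +
    ggplot2::geom_point(alpha = 0.6, colour = "darkorange") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2.5,
                       vjust = -1, check_overlap = TRUE) +
    ggplot2::labs(x = "NR sub-score (sum of capped %DV per 100 kcal)",
                  y = "LIM sub-score (sum of %MRV per 100 kcal)",
                  size = "Products",
                  title = "Nutrients to limit vs nutrients to encourage by category") +
    ggplot2::theme_minimal()
}

#' @rdname plot_category_ed_nrf
#' @export
plot_product_ed_nrf <- function(scores) {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$nrf_score,
                                       y = .data$energy_density)) +
    ggplot2::geom_point(alpha = 0.4, colour = "steelblue") +
    ggplot2::labs(x = "NRF nutrient density score (per 100 kcal)",
                  y = "Energy density (kcal/100 g)",
                  title = "Energy density vs nutrient density, per product") +
    ggplot2::theme_minimal()
}

#' @rdname plot_category_ed_nrf
#' @export
plot_product_lim_nr <- function(scores) {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$nr_subscore,
                                       y = .data$lim_subscore)) +
    ggplot2::geom_point(alpha = 0.4, colour = "darkorange") +
    ggplot2::labs(x = "NR sub-score (sum of capped %DV per 100 kcal)",
                  y = "LIM sub-score (sum of %MRV per 100 kcal)",
                  title = "Nutrients to limit vs nutrients to encourage, per product") +
    ggplot2::theme_minimal()
}
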