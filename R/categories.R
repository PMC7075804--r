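#' WWEIA snack category map
#'
#' The 24 What We Eat in America (WWEIA) categories used to aggregate
#' snacks, with their 4-digit category codes. Ships as an editable CSV
#' (`row_index,label,codes`, codes semicolon-separated); code sets are
#' validated to be pairwise disjoint.
#'
#' @param path Path to a category-map CSV; defaults to the shipped map.
#' @return Tibble with columns `row_index`, `label`, `codes` (list-column
#'   of integer vectors).
#' @examples
#' wweia_categories()
#' @export
wweia_categories <- function(path = system.file("extdata",
                                                "wweia_categories.csv",
                                                package = "snacknrf")) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    row_index = readr::col_integer(),
    label = readr::col_character(),
    codes = readr::col_character()
  ))
  raw$codes <- lapply(strsplit(raw$codes, ";"), function(x) as.integer(trimws(x)))
  all_codes <- unlist(raw$codes)
  if (anyDuplicated(all_codes)) {
    stop("WWEIA category map is not a partition: code(s) ",
         paste(unique(all_codes[duplicated(all_codes)]), collapse = ", "),
         " appear in more than one category", call. = FALSE)
  }
  raw
}

#' Assign a WWEIA code to its category
#'
#' @param wweia_code Integer 4-digit WWEIA category code(s).
#' @param categories Category map from [wweia_categories()].
#' @return For a scalar code, a one-row tibble (`row_index`, `label`,
#'   `codes`); for a vector, one row per code. Unmapped codes raise an
#'   unknown-category error listing them.
#' @examples
#' assign_category(1802)$label # "Yogurt, whole/reduced"
#' @export
assign_category <- function(wweia_code, categories = wweia_categories()) {
  lookup <- tidyr::unnest(categories, "codes")
  i <- match(as.integer(wweia_code), lookup$codes)
  if (anyNA(i)) {
    stop("unknown WWEIA code(s): ",
         paste(unique(wweia_code[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  idx <- match(lookup$row_index[i], categories$row_index)
  categories[idx, ]
}

#' Per-category summary of scored products
#'
#' Aggregates scored products by WWEIA category: product count and
#' mean/sample SD (n - 1 denominator) of energy density, LIM sub-score and
#' NRF score, plus an overall row (`row_index` NA, label `"Total"`) whose
#' means are the n-weighted (i.e. pooled product-level) means. An SD of 0 is
#' reported for single-product categories.
#'
#' @param products Product tibble with `product_id` and `wweia_code`.
#' @param scores Score tibble from [score_products()]; computed from
#'   `products` if omitted.
#' @param categories Category map from [wweia_categories()].
#' @return Tibble: `row_index`, `label`, `n`, `ed_mean`, `ed_sd`,
#'   `lim_mean`, `lim_sd`, `nrf_mean`, `nrf_sd`.
#' @examples
#' prods <- generate_dataset(default_config(), seed = 1)
#' summarize_categories(prods)
#' @export
summarize_categories <- function(products, scores = score_products(products),
                                 categories = wweia_categories()) {
  products <- tibble::as_tibble(products)
  if (nrow(products) == 0) stop("no products to summarize", call. = FALSE)
  cat_rows <- assign_category(products$wweia_code, categories)
  dat <- dplyr::inner_join(
    tibble::tibble(product_id = products$product_id,
                   row_index = cat_rows$row_index,
                   label = cat_rows$label),
    scores[, c("product_id", "energy_density", "lim_subscore", "nrf_score")],
    by = "product_id"
  )
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  per_cat <- dat |>
    dplyr::group_by(.data$row_index, .data$label) |>
    dplyr::summarise(
      n = dplyr::n(),
      ed_mean = mean(.data$energy_density), ed_sd = sd0(.data$energy_density),
      lim_mean = mean(.data$lim_subscore), lim_sd = sd0(.data$lim_subscore),
      nrf_mean = mean(.data$nrf_score), nrf_sd = sd0(.data$nrf_score),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$row_index)
  total <- tibble::tibble(
    row_index = NA_integer_, label = "Total", n = nrow(dat),
    ed_mean = mean(dat$energy_density), ed_sd = sd0(dat$energy_density),
    lim_mean = mean(dat$lim_subscore), lim_sd = sd0(dat$lim_subscore),
    nrf_mean = mean(dat$nrf_score), nrf_sd = sd0(dat$nrf_score)
  )
  dplyr::bind_rows(per_cat, total)
}

#' Two-group comparison of score components with one-way ANOVA
#'
#' For each variable, reports the group means and standard errors
#' (SEM = SD / sqrt(n)) and the p-value of a classical one-way ANOVA across
#' the two groups (equal-variance F test; for two groups F equals the
#' squared pooled-variance t statistic). Raw p-values are stored; no
#' multiple-testing correction is applied across variables.
#'
#' @param scores Score tibble from [score_products()] (or any tibble with a
#'   `product_id` column and numeric variables).
#' @param group_flag Logical vector, one entry per row of `scores`: `TRUE`
#'   for group A.
#' @param group_labels Length-2 character vector naming the `TRUE` and
#'   `FALSE` groups.
#' @param grouping_name Name of the contrast (e.g. `"first_ingredient"`).
#' @param variables Variables to compare; defaults to the standard 16-row
#'   layout (eight %DVs, four %MRVs including total sugar, energy density,
#'   NR, LIM, NRF), restricted to columns present in `scores`.
#' @return A `group_comparison`: list with `grouping_name`, `group_a_label`,
#'   `group_b_label`, `n_a`, `n_b` and a `table` tibble (`variable`,
#'   `mean_a`, `sem_a`, `mean_b`, `sem_b`, `p_value`).
#' @examples
#' prods <- generate_dataset(default_config(), seed = 1)
#' scores <- score_products(prods)
#' flags <- classify_products(prods)
#' compare_groups(scores, flags$fruit_or_dairy_first,
#'                c("fruit_or_dairy", "neither"), "first_ingredient")
#' @export
compare_groups <- function(scores, group_flag,
                           group_labels = c("group_a", "group_b"),
                           grouping_name = "group",
                           variables = NULL) {
  scores <- tibble::as_tibble(scores)
  stopifnot(length(group_flag) == nrow(scores), is.logical(group_flag))
  if (anyNA(group_flag)) stop("`group_flag` must not contain NA", call. = FALSE)
  n_a <- sum(group_flag)
  n_b <- sum(!group_flag)
  if (n_a < 2 || n_b < 2) {
    stop("degenerate group: both groups need at least 2 products ",
         "(got ", n_a, " and ", n_b, "); SEM and ANOVA are undefined",
         call. = FALSE)
  }
  if (is.null(variables)) {
    variables <- intersect(comparison_variables(), names(scores))
  }
  missing_vars <- setdiff(variables, names(scores))
  if (length(missing_vars) > 0) {
    stop("variable(s) not in `scores`: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  rows <- purrr::map(variables, function(v) {
    y <- scores[[v]]
    fit <- stats::anova(stats::lm(y ~ factor(group_flag)))
    tibble::tibble(
      variable = v,
      mean_a = mean(y[group_flag]), sem_a = sem(y[group_flag]),
      mean_b = mean(y[!group_flag]), sem_b = sem(y[!group_flag]),
      p_value = fit[1, "Pr(>F)"]
    )
  })
  structure(
    list(
      grouping_name = grouping_name,
      group_a_label = group_labels[1], group_b_label = group_labels[2],
      n_a = n_a, n_b = n_b,
      table = dplyr::bind_rows(rows)
    ),
    class = "group_comparison"
  )
}

comparison_variables <- function() {
  c("pct_dv_protein", "pct_dv_fiber", "pct_dv_vitamin_a", "pct_dv_vitamin_c",
    "pct_dv_vitamin_d", "pct_dv_calcium", "pct_dv_iron", "pct_dv_potassium",
    "pct_mrv_satfat", "total_sugar_pct_mrv", "pct_mrv_added_sugar",
    "pct_mrv_sodium", "energy_density", "nr_subscore", "lim_subscore",
    "nrf_score")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %s (n = %d) vs %s (n = %d)\n",
              x$grouping_name, x$group_a_label, x$n_a,
              x$group_b_label, x$n_b))
  print(as.data.frame(format_group_comparison(x)), row.names = FALSE)
  invisible(x)
}

#' Render a comparison or category summary for presentation
#'
#' Rounds to 2 decimals at presentation time (internal arithmetic is full
#' precision) and, for comparisons, adds a significance label mirroring the
#' conventional thresholds (`"<0.05"`, `"<0.001"`); the raw p-value column
#' is retained.
#'
#' @param comparison A `group_comparison` from [compare_groups()].
#' @param summary_table A category summary from [summarize_categories()].
#' @return A tibble rounded for display.
#' @export
format_group_comparison <- function(comparison) {
  tab <- comparison$table
  tibble::tibble(
    variable = tab$variable,
    mean_a = round(tab$mean_a, 2), sem_a = round(tab$sem_a, 2),
    mean_b = round(tab$mean_b, 2), sem_b = round(tab$sem_b, 2),
    p_value = signif(tab$p_value, 3),
    significance = dplyr::case_when(
      is.na(tab$p_value) ~ "",
      tab$p_value < 0.001 ~ "<0.001",
      tab$p_value < 0.05 ~ "<0.05",
      TRUE ~ ""
    )
  )
}

#' @rdname format_group_comparison
#' @export
format_category_summary <- function(summary_table) {
  dplyr::mutate(summary_table,
                dplyr::across(dplyr::where(is.double), ~ round(.x, 2)))
}
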