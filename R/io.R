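#' Standard product CSV schema
#'
#' Column order of the product-table CSV: identifier and label metadata,
#' energy (kcal/100 g), per-100 g nutrient amounts in the unit encoded in
#' the column name, and the raw back-of-pack ingredient string (quoted,
#' since it contains commas). Files are UTF-8, comma-separated, decimal
#' point regardless of the product's market.
#'
#' @return Character vector of column names.
#' @export
product_schema_columns <- function() {
  c("product_id", "name", "country", "wweia_code", "energy_kcal_100g",
    "protein_g_100g", "fiber_g_100g", "vitamin_a_ug_100g",
    "vitamin_c_mg_100g", "vitamin_d_ug_100g", "calcium_mg_100g",
    "iron_mg_100g", "potassium_mg_100g", "satfat_g_100g",
    "total_sugar_g_100g", "added_sugar_g_100g", "sodium_mg_100g",
    "ingredient_text")
}

product_schema_version <- function() "1.0"

#' Read a product table from CSV
#'
#' Reads and validates product records. Mandatory columns are the standard
#' schema ([product_schema_columns()]); unknown extra columns are preserved
#' and survive a write/read round-trip. Row-level validation failures
#' (negative nutrient amounts, negative energy, added sugar exceeding total
#' sugar, duplicated product ids) are collected and reported together with
#' their row numbers.
#'
#' @param path CSV file path.
#' @return A validated product tibble with provenance attributes `source`
#'   and `schema_version`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_products(generate_dataset(default_config(), seed = 1), f)
#' nrow(read_products(f))
#' @export
read_products <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  products <- readr::read_csv(path, col_types = readr::cols(
    product_id = readr::col_character(),
    name = readr::col_character(),
    country = readr::col_character(),
    wweia_code = readr::col_integer(),
    ingredient_text = readr::col_character(),
    .default = readr::col_guess()
  ), show_col_types = FALSE)
  missing_cols <- setdiff(product_schema_columns(), names(products))
  if (length(missing_cols) > 0) {
    stop("schema error in ", path, ": missing mandatory column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  validate_products(products, context = path)
  attr(products, "source") <- path
  attr(products, "schema_version") <- product_schema_version()
  products
}

validate_products <- function(products, context = "products") {
  problems <- character(0)
  add <- function(rows, what) {
    if (length(rows) > 0) {
      problems <<- c(problems, paste0(
        "row(s) ", paste(utils::head(rows, 10), collapse = ", "),
        if (length(rows) > 10) ", ..." else "", ": ", what))
    }
  }
  nutrient_cols <- setdiff(
    grep("_100g$", product_schema_columns(), value = TRUE), "energy_kcal_100g")
  for (col in nutrient_cols) {
    add(which(products[[col]] < 0), paste0("negative ", col))
  }
  add(which(products$energy_kcal_100g < 0), "negative energy_kcal_100g")
  both <- !is.na(products$added_sugar_g_100g) &
    !is.na(products$total_sugar_g_100g)
  add(which(both & products$added_sugar_g_100g >
              products$total_sugar_g_100g + 1e-9),
      "added sugar exceeds total sugar")
  add(which(duplicated(products$product_id)), "duplicated product_id")
  add(which(is.na(products$ingredient_text) |
              !nzchar(trimws(products$ingredient_text))),
      "empty ingredient_text")
  if (length(problems) > 0) {
    stop("validation of ", context, " failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  invisible(products)
}

#' @rdname read_products
#' @param products Product tibble to write.
#' @export
write_products <- function(products, path) {
  readr::write_csv(products, path)
  invisible(path)
}

#' Run the full scoring and comparison pipeline
#'
#' Executes the analysis end-to-end: NRF scoring, ingredient
#' classification, per-category aggregation, and the two ingredient-defined
#' group contrasts (fruit-or-dairy-first vs neither; FVN vs no FVN), with
#' four scatterplot figures relating energy density to NRF score and the
#' LIM sub-score to the NR sub-score, at category and product level.
#' Unscorable products (energy density below [ED_MIN]) are skipped with a
#' warning naming them. Given the same inputs, configuration and seed the
#' outputs are identical.
#'
#' @param products Product tibble (from [read_products()] or
#'   [generate_dataset()]).
#' @param standards An [nrf_standards()] object.
#' @param lexicons Classification lexica from [default_lexicons()].
#' @param categories Category map from [wweia_categories()].
#' @param out_dir Optional directory; when given, tables are written as
#'   2-decimal CSVs and figures as PNG files.
#' @return List with elements `scores`, `classifications`,
#'   `category_summary`, `comparisons` (list `first_ingredient`, `fvn`),
#'   `figures` (list of 4 ggplot objects) and `run_summary` (product
#'   counts).
#' @examples
#' res <- run_pipeline(generate_dataset(default_config(), seed = 1))
#' res$run_summary
#' @export
run_pipeline <- function(products, standards = nrf_standards(),
                         lexicons = default_lexicons(),
                         categories = wweia_categories(),
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  products <- tibble::as_tibble(products)
  scorable <- products$energy_kcal_100g >= ED_MIN &
    !is.na(products$energy_kcal_100g)
  if (!all(scorable)) {
    warning("skipping ", sum(!scorable), " unscorable product(s): ",
            paste(products$product_id[!scorable], collapse = ", "),
            call. = FALSE)
  }
  kept <- products[scorable, , drop = FALSE]

  scores <- stage("score", score_products(kept, standards))
  flags <- stage("classify", classify_products(kept, lexicons))
  summary_tbl <- stage("summarize",
                       summarize_categories(kept, scores, categories))
  comparisons <- stage("compare", list(
    first_ingredient = compare_groups(
      scores, flags$fruit_or_dairy_first,
      group_labels = c("fruit_or_dairy_first", "neither"),
      grouping_name = "first_ingredient"),
    fvn = compare_groups(
      scores, flags$fvn_present,
      group_labels = c("fvn", "no_fvn"),
      grouping_name = "fvn")
  ))
  figures <- stage("plot", list(
    category_ed_nrf = plot_category_ed_nrf(summary_tbl),
    category_lim_nr = plot_category_lim_nr(summary_tbl),
    product_ed_nrf = plot_product_ed_nrf(scores),
    product_lim_nr = plot_product_lim_nr(scores)
  ))
  run_summary <- list(
    n_input = nrow(products),
    n_scored = nrow(scores),
    n_skipped = sum(!scorable),
    n_fruit_or_dairy_first = sum(flags$fruit_or_dairy_first),
    n_fvn = sum(flags$fvn_present)
  )
  res <- list(scores = scores, classifications = flags,
              category_summary = summary_tbl, comparisons = comparisons,
              figures = figures, run_summary = run_summary)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(format_category_summary(res$category_summary),
                   file.path(out_dir, "category_summary.csv"))
  for (nm in names(res$comparisons)) {
    readr::write_csv(format_group_comparison(res$comparisons[[nm]]),
                     file.path(out_dir, paste0("comparison_", nm, ".csv")))
  }
  readr::write_csv(res$scores, file.path(out_dir, "scores.csv"))
  readr::write_csv(res$classifications,
                   file.path(out_dir, "classifications.csv"))
  for (nm in names(res$figures)) {
    ggplot2::ggsave(file.path(out_dir, paste0(nm, ".png")),
                    res$figures[[nm]], width = 7, height = 5, dpi = 150)
  }
  invisible(out_dir)
}
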