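#' Minimum scoreable energy density
#'
#' The NRF calculation is defined per 100 kcal, so it is undefined for
#' (near-)zero-energy foods: amounts per 100 kcal diverge as energy density
#' approaches zero. Products with energy density below this floor
#' (1 kcal/100 g) raise an explicit unscorable-product error rather than
#' returning infinities. Every snack category in the calibration targets has
#' mean energy density of at least 40 kcal/100 g, so the floor is far below
#' any realistic snack.
#'
#' @format Numeric scalar, kcal/100 g.
#' @export
ED_MIN <- 1

#' Energy density of a food
#'
#' @param energy_kcal Energy (kcal) contained in `mass_g` grams of food.
#' @param mass_g Mass in grams; must be strictly positive.
#' @return Energy density in kcal/100 g.
#' @examples
#' energy_density(150, 50) # 300 kcal/100 g
#' @export
energy_density <- function(energy_kcal, mass_g) {
  if (!is.numeric(energy_kcal) || !is.numeric(mass_g)) {
    stop("`energy_kcal` and `mass_g` must be numeric", call. = FALSE)
  }
  if (any(mass_g <= 0)) {
    stop("`mass_g` must be strictly positive", call. = FALSE)
  }
  if (any(energy_kcal < 0)) {
    stop("`energy_kcal` must be non-negative", call. = FALSE)
  }
  energy_kcal * 100 / mass_g
}

#' Convert a per-100 g amount to a per-100 kcal amount
#'
#' The basis of all NRF calculations is 100 kcal of food, so per-100 g label
#' amounts are rescaled by the product's energy density.
#'
#' @param amount_per_100g Nutrient amount per 100 g.
#' @param ed Energy density, kcal/100 g; must be at least [ED_MIN].
#' @param product_id Optional identifier used in the unscorable-product
#'   error message.
#' @return Amount per 100 kcal, in the same unit as the input.
#' @examples
#' amount_per_100kcal(3, ed = 50) # 6 per 100 kcal
#' @export
amount_per_100kcal <- function(amount_per_100g, ed, product_id = NULL) {
  if (any(ed < ED_MIN)) {
    id <- if (is.null(product_id)) "product" else {
      paste0("product(s) ", paste(unique(product_id[ed < ED_MIN]), collapse = ", "))
    }
    stop("unscorable ", id, ": energy density below ", ED_MIN,
         " kcal/100 g, per-100 kcal amounts are undefined", call. = FALSE)
  }
  amount_per_100g * 100 / ed
}

#' Percent daily value per 100 kcal for a qualifying nutrient
#'
#' Qualifying %DVs are truncated at the configured cap (default 100) so that
#' an excessively high content of a single nutrient cannot produce an
#' excessive NRF score; the uncapped value is reported alongside.
#'
#' @param nutrient Name of a nutrient in `standards$qualifying`.
#' @param amount_per_100kcal Amount per 100 kcal, in the standard's unit.
#' @param standards An [nrf_standards()] object.
#' @return List with elements `capped` and `uncapped` (both %DV).
#' @examples
#' percent_dv("vitamin_c", 160, nrf_standards()) # capped 100, uncapped 200
#' @export
percent_dv <- function(nutrient, amount_per_100kcal, standards = nrf_standards()) {
  i <- match(nutrient, standards$qualifying$nutrient)
  if (is.na(i)) {
    stop("unknown qualifying nutrient '", nutrient, "'; configured: ",
         paste(standards$qualifying$nutrient, collapse = ", "), call. = FALSE)
  }
  uncapped <- amount_per_100kcal / standards$qualifying$dv[i] * 100
  list(capped = pmin(uncapped, standards$cap), uncapped = uncapped)
}

#' Percent maximum recommended value per 100 kcal for a nutrient to limit
#'
#' No cap is applied: truncation applies only to nutrients to encourage, so
#' essentially-all-sugar products can (and do) exceed 100 %MRV. The special
#' nutrient name `"total_sugar"` is referenced against
#' `standards$total_sugar_mrv`.
#'
#' @inheritParams percent_dv
#' @return %MRV (numeric).
#' @examples
#' percent_mrv("added_sugar", 25, nrf_standards()) # 50
#' @export
percent_mrv <- function(nutrient, amount_per_100kcal, standards = nrf_standards()) {
  if (identical(nutrient, "total_sugar")) {
    return(amount_per_100kcal / standards$total_sugar_mrv * 100)
  }
  i <- match(nutrient, standards$limiting$nutrient)
  if (is.na(i)) {
    stop("unknown limiting nutrient '", nutrient, "'; configured: ",
         paste(c(standards$limiting$nutrient, "total_sugar"), collapse = ", "),
         call. = FALSE)
  }
  amount_per_100kcal / standards$limiting$mrv[i] * 100
}

#' Score a table of products with the NRFn.3 model
#'
#' For each product the nutrient amounts per 100 g are converted to a
#' 100 kcal basis using the product's energy density, expressed as %DV
#' (qualifying, truncated at the cap) or %MRV (limiting, never truncated),
#' and combined into three scores:
#'
#' * `nr_subscore` — sum of capped %DVs over the qualifying nutrients
#'   (NR8 under the default standards);
#' * `lim_subscore` — sum of %MRVs over the three nutrients to limit;
#' * `nrf_score` — `nr_subscore - lim_subscore` (NRF8.3 under the defaults).
#'
#' Total sugar %MRV is computed and reported but never enters
#' `lim_subscore`: total sugars include those naturally present in fruit and
#' dairy, so only added sugar is penalized.
#'
#' Missing nutrient values (absent column or `NA`) contribute 0 to the
#' sub-scores and trigger a single warning listing the affected products.
#'
#' @param products Tibble of product records in the standard schema (see
#'   [read_products()]): `product_id`, `energy_kcal_100g`, one
#'   `<nutrient>_<unit>_100g` column per configured nutrient, and
#'   `total_sugar_g_100g`.
#' @param standards An [nrf_standards()] object.
#' @param on_unscorable `"error"` (default) to fail on products with energy
#'   density below [ED_MIN]; `"skip"` to drop them with a warning naming the
#'   product ids.
#' @return Tibble with one row per scored product: `product_id`,
#'   `energy_density`, capped `pct_dv_<nutrient>` and raw
#'   `pct_dv_uncapped_<nutrient>` columns, `pct_mrv_<nutrient>` columns,
#'   `total_sugar_pct_mrv`, `nr_subscore`, `lim_subscore`, `nrf_score`.
#' @examples
#' prods <- generate_dataset(default_config(), seed = 1)
#' scores <- score_products(prods)
#' head(scores[, c("product_id", "nr_subscore", "lim_subscore", "nrf_score")])
#' @export
score_products <- function(products, standards = nrf_standards(),
                           on_unscorable = c("error", "skip")) {
  on_unscorable <- match.arg(on_unscorable)
  products <- tibble::as_tibble(products)
  if (!"energy_kcal_100g" %in% names(products)) {
    stop("`products` must have an `energy_kcal_100g` column", call. = FALSE)
  }
  if (!"product_id" %in% names(products)) {
    products$product_id <- paste0("row", seq_len(nrow(products)))
  }

  ed <- products$energy_kcal_100g # per 100 g basis: ED is the energy column
  unscorable <- ed < ED_MIN | is.na(ed)
  if (any(unscorable)) {
    ids <- products$product_id[unscorable]
    if (on_unscorable == "error") {
      stop("unscorable product(s) ", paste(ids, collapse = ", "),
           ": energy density below ", ED_MIN, " kcal/100 g", call. = FALSE)
    }
    warning("skipping ", length(ids), " unscorable product(s): ",
            paste(ids, collapse = ", "), call. = FALSE)
    products <- products[!unscorable, , drop = FALSE]
    ed <- ed[!unscorable]
  }
  n <- nrow(products)

  # Pull a nutrient's per-100 g amounts; NA/absent contributes 0, logged once.
  missing_ids <- character(0)
  get_amounts <- function(nutrient, unit) {
    col <- nutrient_column(nutrient, unit)
    if (!col %in% names(products)) {
      missing_ids <<- union(missing_ids, products$product_id)
      return(rep(0, n))
    }
    x <- products[[col]]
    if (anyNA(x)) {
      missing_ids <<- union(missing_ids, products$product_id[is.na(x)])
      x[is.na(x)] <- 0
    }
    x
  }

  out <- tibble::tibble(product_id = products$product_id, energy_density = ed)

  nr <- rep(0, n)
  for (i in seq_len(nrow(standards$qualifying))) {
    nut <- standards$qualifying$nutrient[i]
    amt100kcal <- get_amounts(nut, standards$qualifying$unit[i]) * 100 / ed
    dv <- percent_dv(nut, amt100kcal, standards)
    out[[paste0("pct_dv_", nut)]] <- dv$capped
    out[[paste0("pct_dv_uncapped_", nut)]] <- dv$uncapped
    nr <- nr + dv$capped
  }

  lim <- rep(0, n)
  for (i in seq_len(nrow(standards$limiting))) {
    nut <- standards$limiting$nutrient[i]
    amt100kcal <- get_amounts(nut, standards$limiting$unit[i]) * 100 / ed
    mrv <- percent_mrv(nut, amt100kcal, standards)
    out[[paste0("pct_mrv_", nut)]] <- mrv
    lim <- lim + mrv
  }

  ts100kcal <- get_amounts("total_sugar", "g") * 100 / ed
  out$total_sugar_pct_mrv <- percent_mrv("total_sugar", ts100kcal, standards)

  out$nr_subscore <- nr
  out$lim_subscore <- lim
  out$nrf_score <- nr - lim

  if (length(missing_ids) > 0) {
    warning(length(missing_ids), " product(s) with missing nutrient values ",
            "contribute 0 for those nutrients: ",
            paste(utils::head(missing_ids, 5), collapse = ", "),
            if (length(missing_ids) > 5) ", ..." else "", call. = FALSE)
  }
  out
}

#' Score a single product
#'
#' Convenience wrapper around [score_products()] returning the score
#' components for one product as a list.
#'
#' @param product A one-row data frame / tibble, or a named list coercible to
#'   one, in the standard product schema.
#' @inheritParams score_products
#' @return A list of class `nrf_score` with elements `product_id`,
#'   `energy_density`, `pct_dv_per_100kcal` (named, capped), `pct_dv_uncapped`,
#'   `pct_mrv_per_100kcal`, `total_sugar_pct_mrv`, `nr_subscore`,
#'   `lim_subscore`, `nrf_score`.
#' @examples
#' p <- list(product_id = "x", energy_kcal_100g = 100,
#'           protein_g_100g = 5, total_sugar_g_100g = 10)
#' score_product(p)
#' @export
score_product <- function(product, standards = nrf_standards()) {
  if (!is.data.frame(product)) product <- tibble::as_tibble(product[!vapply(product, is.null, TRUE)])
  if (nrow(product) != 1) {
    stop("`product` must describe exactly one product", call. = FALSE)
  }
  row <- score_products(product, standards, on_unscorable = "error")
  qn <- standards$qualifying$nutrient
  ln <- standards$limiting$nutrient
  structure(
    list(
      product_id = row$product_id,
      energy_density = row$energy_density,
      pct_dv_per_100kcal = stats::setNames(
        as.numeric(row[paste0("pct_dv_", qn)]), qn),
      pct_dv_uncapped = stats::setNames(
        as.numeric(row[paste0("pct_dv_uncapped_", qn)]), qn),
      pct_mrv_per_100kcal = stats::setNames(
        as.numeric(row[paste0("pct_mrv_", ln)]), ln),
      total_sugar_pct_mrv = row$total_sugar_pct_mrv,
      nr_subscore = row$nr_subscore,
      lim_subscore = row$lim_subscore,
      nrf_score = row$nrf_score
    ),
    class = "nrf_score"
  )
}

#' @export
print.nrf_score <- function(x, ...) {
  cat(sprintf("<nrf_score> %s  ED %.1f kcal/100 g\n",
              x$product_id, x$energy_density))
  cat(sprintf("  NR  %.2f (sum of capped %%DV per 100 kcal)\n", x$nr_subscore))
  cat(sprintf("  LIM %.2f (sum of %%MRV per 100 kcal)\n", x$lim_subscore))
  cat(sprintf("  NRF %.2f\n", x$nrf_score))
  invisible(x)
}
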