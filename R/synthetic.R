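# Truncated-normal helpers ---------------------------------------------------

# Mean of a normal(mu, sd) left-truncated at `lower`, via the Mills ratio on
# the log scale so locations far below the bound stay finite.
tnorm_mean <- function(mu, sd, lower) {
  if (sd == 0) return(max(mu, lower))
  a <- (lower - mu) / sd
  hazard <- exp(stats::dnorm(a, log = TRUE) -
                  stats::pnorm(a, lower.tail = FALSE, log.p = TRUE))
  mu + sd * hazard
}

# Location parameter mu such that the truncated mean equals `target`.
# Truncating a normal at a lower bound raises its mean, so drawing directly
# at the target mean would bias small-mean/large-SD calibration targets
# upward; solving for the location removes that bias in expectation.
solve_tnorm_location <- function(target, sd, lower) {
  if (sd == 0) return(target)
  if (target <= lower) {
    stop("truncated-normal target mean (", target,
         ") must exceed the lower bound (", lower, ")", call. = FALSE)
  }
  f <- function(mu) tnorm_mean(mu, sd, lower) - target
  hi <- target # f(hi) >= 0 always
  lo <- target - 2 * sd
  while (f(lo) > 0) {
    lo <- lo - 4 * sd
    if (lo < target - 200 * sd) stop("truncated-normal solve failed to bracket")
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

# Draw from normal(mu, sd) left-truncated at `lower` by inverse CDF.
rtnorm <- function(n, mu, sd, lower) {
  if (sd == 0) return(rep(max(mu, lower), n))
  p0 <- min(stats::pnorm(lower, mu, sd), 1 - 1e-12)
  stats::qnorm(stats::runif(n, p0, 1), mu, sd)
}

# Draw n values whose *truncated* mean equals `mean` in expectation.
rtnorm_calibrated <- function(n, mean, sd, lower = 0) {
  rtnorm(n, solve_tnorm_location(mean, sd, lower), sd, lower)
}

# Generator configuration ----------------------------------------------------

#' Default synthetic-dataset configuration
#'
#' Builds the configuration that makes [generate_dataset()] emulate the
#' structure of the 261-product market survey the package is calibrated to:
#'
#' * 24 WWEIA categories with the published product counts and energy
#'   density mean/SD targets;
#' * a fixed per-category allocation of ingredient-template classes
#'   (fruit-first, dairy-first, dairy-first with fruit pieces, neither with
#'   FVN, neither) reproducing the published group sizes exactly: 115
#'   products with fruit or dairy first vs 146 with neither, and 88
#'   containing fruit/vegetables/nuts vs 173 without;
#' * two class-level nutrient profiles (per 100 kcal, in %DV / %MRV units)
#'   equal to the published first-ingredient group means, with SDs
#'   reconstructed as SEM * sqrt(n);
#' * an added-sugar/total-sugar fraction range per class, so the added <=
#'   total invariant holds for every product.
#'
#' @return A list of class `snack_sim_config` with elements `categories`
#'   (tibble of per-category specs), `class_profiles`, `added_sugar_frac`,
#'   `country_weights` and the shipped default `seed`.
#' @examples
#' cfg <- default_config()
#' sum(cfg$categories$n) # 261
#' @export
default_config <- function() {
  targets <- snack_category_targets()
  # Template-class allocation per category (fixed counts, not probabilities,
  # so group sizes match the published 115/146 and 88/173 partitions).
  alloc <- tibble::tribble(
    ~row_index, ~n_fruit_first, ~n_dairy_first, ~n_dairy_first_fvn, ~n_neither_fvn, ~n_neither,
    1L,  0L,  6L, 0L,  0L,  0L,
    2L,  0L, 13L, 0L,  0L,  0L,
    3L,  0L, 13L, 8L,  0L,  0L,
    4L,  0L, 11L, 7L,  0L,  0L,
    5L,  0L,  0L, 0L, 16L,  0L,
    6L,  0L,  0L, 0L,  0L,  2L,
    7L,  0L,  0L, 0L,  0L,  6L,
    8L,  0L,  0L, 0L,  0L,  4L,
    9L,  0L,  0L, 0L,  0L,  2L,
    10L, 0L,  0L, 0L,  0L, 10L,
    11L, 0L,  0L, 0L, 10L,  5L,
    12L, 0L,  0L, 0L,  2L,  0L,
    13L, 0L,  0L, 0L,  0L, 27L,
    14L, 0L,  0L, 0L,  4L, 15L,
    15L, 7L,  0L, 0L,  0L, 20L,
    16L, 0L,  0L, 0L,  0L,  8L,
    17L, 0L, 16L, 0L,  0L,  0L,
    18L, 0L,  0L, 0L,  0L,  2L,
    19L, 18L, 0L, 0L,  0L,  0L,
    20L, 2L,  0L, 0L,  0L,  0L,
    21L, 7L,  0L, 0L,  0L,  0L,
    22L, 7L,  0L, 0L,  0L,  0L,
    23L, 0L,  0L, 0L,  0L,  5L,
    24L, 0L,  0L, 0L,  0L,  8L
  )
  categories <- dplyr::inner_join(
    targets[, c("row_index", "label", "codes", "n", "ed_mean", "ed_sd")],
    alloc, by = "row_index")
  categories$codes <- lapply(strsplit(categories$codes, ";"), as.integer)

  grp <- snack_group_targets()
  profile_for <- function(group) {
    rows <- grp[grp$contrast == "first_ingredient" & grp$group == group, ]
    nutr <- rows[rows$variable %in% c(
      paste0("pct_dv_", default_qualifying_nutrients()$nutrient),
      "pct_mrv_satfat", "pct_mrv_added_sugar", "pct_mrv_sodium"), ]
    tibble::tibble(
      variable = nutr$variable,
      mean = nutr$mean,
      sd = nutr$sem * sqrt(nutr$n[1])
    )
  }

  structure(
    list(
      categories = categories,
      class_profiles = list(
        fruit_or_dairy = profile_for("fruit_or_dairy"),
        neither = profile_for("neither")
      ),
      # added sugar is this uniform fraction of total sugar; ranges chosen so
      # class total-sugar means land near the published 16.3 / ~11 %MRV rows
      added_sugar_frac = list(
        fruit_or_dairy = c(0.42, 0.72),
        neither = c(0.85, 1.00)
      ),
      country_weights = c(US = 0.25, CA = 0.25, FR = 0.25, UK = 0.25),
      seed = 2020L
    ),
    class = "snack_sim_config"
  )
}

validate_config <- function(config) {
  stopifnot(inherits(config, "snack_sim_config"))
  cat_tbl <- config$categories
  count_cols <- c("n_fruit_first", "n_dairy_first", "n_dairy_first_fvn",
                  "n_neither_fvn", "n_neither")
  stopifnot(
    all(c("row_index", "label", "codes", "n", "ed_mean", "ed_sd",
          count_cols) %in% names(cat_tbl)),
    all(cat_tbl$n >= 1),
    all(cat_tbl$ed_sd >= 0),
    all(cat_tbl$ed_mean > ED_MIN)
  )
  counts <- rowSums(as.matrix(cat_tbl[, count_cols]))
  if (!all(counts == cat_tbl$n)) {
    stop("template-class counts must sum to `n` in every category",
         call. = FALSE)
  }
  for (p in config$class_profiles) {
    stopifnot(all(p$mean > 0), all(p$sd >= 0))
  }
  for (fr in config$added_sugar_frac) {
    stopifnot(length(fr) == 2, fr[1] > 0, fr[2] <= 1, fr[1] <= fr[2])
  }
  w <- config$country_weights
  stopifnot(length(w) >= 1, all(w >= 0), sum(w) > 0)
  invisible(config)
}

#' @export
print.snack_sim_config <- function(x, ...) {
  cat(sprintf("<snack_sim_config> %d categories, %d products, seed %d\n",
              nrow(x$categories), sum(x$categories$n), x$seed))
  invisible(x)
}

# Dataset generation ----------------------------------------------------------

#' Generate a synthetic snack dataset
#'
#' Draws a complete, scoreable product table with the statistical structure
#' configured in a [default_config()]-style object. Per category, energy
#' density is drawn from a truncated normal (lower bound [ED_MIN]) whose
#' location is solved so the truncated mean equals the target; nutrient
#' amounts are drawn per 100 kcal from the class profile of the product's
#' ingredient-template class and converted to per-100 g amounts via the
#' drawn energy density. Added sugar is drawn calibrated, and total sugar is
#' derived as added sugar divided by a uniform fraction, so added <= total
#' holds for every record. Each product receives an ingredient label built
#' from its template class, guaranteed to classify under the
#' [classify_ingredients()] rules exactly as intended.
#'
#' The same seed and configuration always reproduce an identical dataset.
#'
#' @param config A `snack_sim_config`, by default [default_config()].
#' @param seed Integer seed; defaults to the seed shipped in the config.
#' @param standards Reference standards used to convert %DV / %MRV profile
#'   draws into nutrient amounts.
#' @return Product tibble in the standard schema (see [read_products()])
#'   with additional bookkeeping columns `category_row`, `template_class`,
#'   `intended_fruit_or_dairy_first` and `intended_fvn`.
#' @examples
#' prods <- generate_dataset(default_config(), seed = 42)
#' nrow(prods) # 261
#' @export
generate_dataset <- function(config = default_config(), seed = config$seed,
                             standards = nrf_standards()) {
  validate_config(config)
  withr::with_seed(as.integer(seed), generate_dataset_impl(config, standards))
}

generate_dataset_impl <- function(config, standards) {
  classes_of <- function(row) {
    rep(c("fruit_first", "dairy_first", "dairy_first_fvn", "neither_fvn",
          "neither"),
        times = c(row$n_fruit_first, row$n_dairy_first,
                  row$n_dairy_first_fvn, row$n_neither_fvn, row$n_neither))
  }

  # Unit scale per profile variable: %DV/%MRV -> amount per 100 kcal.
  qual <- standards$qualifying
  lim <- standards$limiting
  ref_amount <- c(
    stats::setNames(qual$dv, paste0("pct_dv_", qual$nutrient)),
    stats::setNames(lim$mrv, paste0("pct_mrv_", lim$nutrient))
  )
  units <- c(
    stats::setNames(qual$unit, paste0("pct_dv_", qual$nutrient)),
    stats::setNames(lim$unit, paste0("pct_mrv_", lim$nutrient))
  )

  out <- vector("list", nrow(config$categories))
  id0 <- 0L
  for (k in seq_len(nrow(config$categories))) {
    row <- config$categories[k, ]
    n <- row$n
    cls <- sample(classes_of(row)) # shuffle within category
    profile_class <- ifelse(
      cls %in% c("fruit_first", "dairy_first", "dairy_first_fvn"),
      "fruit_or_dairy", "neither")

    ed <- rtnorm_calibrated(n, row$ed_mean, row$ed_sd, lower = ED_MIN)

    prod <- tibble::tibble(
      product_id = sprintf("SNK%04d", id0 + seq_len(n)),
      name = paste0(row$label, " item ", seq_len(n)),
      country = sample(names(config$country_weights), n, replace = TRUE,
                       prob = config$country_weights),
      wweia_code = sample(rep(row$codes[[1]], length.out = n), n),
      energy_kcal_100g = ed
    )
    id0 <- id0 + n

    # Per-100 kcal draws from the class profiles, converted to per-100 g.
    pct <- matrix(0, nrow = n, ncol = length(ref_amount),
                  dimnames = list(NULL, names(ref_amount)))
    for (cl in unique(profile_class)) {
      idx <- which(profile_class == cl)
      prof <- config$class_profiles[[cl]]
      for (j in seq_len(nrow(prof))) {
        v <- prof$variable[j]
        pct[idx, v] <- rtnorm_calibrated(length(idx), prof$mean[j],
                                         prof$sd[j], lower = 0)
      }
    }
    for (v in names(ref_amount)) {
      amount_100kcal <- pct[, v] / 100 * ref_amount[[v]]
      nut <- sub("^pct_(dv|mrv)_", "", v)
      prod[[nutrient_column(nut, units[[v]])]] <- amount_100kcal * ed / 100
    }

    # Total sugar from added sugar and a uniform added/total fraction.
    frac_range <- vapply(profile_class, function(cl)
      config$added_sugar_frac[[cl]], numeric(2))
    frac <- stats::runif(n, frac_range[1, ], frac_range[2, ])
    prod$total_sugar_g_100g <- prod$added_sugar_g_100g / frac

    prod$ingredient_text <- vapply(cls, function(cl)
      generate_ingredient_label(cl, row$row_index), "")

    prod$category_row <- row$row_index
    prod$template_class <- cls
    prod$intended_fruit_or_dairy_first <-
      cls %in% c("fruit_first", "dairy_first", "dairy_first_fvn")
    prod$intended_fvn <-
      cls %in% c("fruit_first", "dairy_first_fvn", "neither_fvn")
    out[[k]] <- prod
  }
  res <- dplyr::bind_rows(out)
  res <- res[, c(product_schema_columns(),
                 "category_row", "template_class",
                 "intended_fruit_or_dairy_first", "intended_fvn")]
  attr(res, "schema_version") <- product_schema_version()
  attr(res, "source") <- "snacknrf synthetic generator"
  res
}

# Ingredient-label templates --------------------------------------------------

#' Generate one ingredient label for a template class
#'
#' Labels imitate real back-of-pack phrasing (including QUID percentages,
#' nested sub-ingredient lists and the water-leading juice pattern) while
#' guaranteeing, by construction, that the classification rules recover the
#' intended flags: `"fruit_first"` labels classify fruit-first (hence FVN),
#' `"dairy_first"` labels dairy-first without FVN, `"dairy_first_fvn"`
#' dairy-first with FVN, `"neither_fvn"` neither-first with FVN, and
#' `"neither"` with no flag set. Uses the current RNG state.
#'
#' @param template_class One of the five class names above.
#' @param row_index Optional category row (1-24) selecting category-typical
#'   phrasing (e.g. the water-leading pattern for juices, potato/corn labels
#'   for chips).
#' @return A single label string.
#' @examples
#' set.seed(1)
#' generate_ingredient_label("fruit_first", 22)
#' @export
generate_ingredient_label <- function(template_class, row_index = NA) {
  pick <- function(x) x[sample.int(length(x), 1)]
  fruits_first <- c("apple", "strawberries", "banana", "peaches",
                    "blueberries", "mango", "pear")
  fruit_piece <- c("strawberries", "raspberries", "blueberries", "peaches",
                   "cherries")
  juice_fruit <- c("oranges", "apples", "grapes", "pineapples")
  nuts <- c("almonds", "peanuts", "cashews", "hazelnuts", "sunflower seeds")

  switch(
    template_class,
    fruit_first = {
      if (identical(row_index, 22L)) {
        paste0("water, ", pick(juice_fruit))
      } else if (identical(row_index, 20L)) {
        paste0(pick(c("raisins", "dried apricots", "dried cranberries")),
               ", sunflower oil")
      } else if (identical(row_index, 15L)) {
        paste0(pick(fruits_first),
               ", apple puree concentrate, lemon juice concentrate")
      } else {
        paste0(pick(fruits_first), ", ",
               pick(c("banana", "grape juice", "water", "lemon juice")))
      }
    },
    dairy_first = {
      if (identical(row_index, 2L)) {
        paste0(pick(c("cheddar cheese", "mozzarella cheese", "swiss cheese")),
               " (pasteurized milk, salt, cheese cultures, enzymes)")
      } else if (identical(row_index, 17L)) {
        paste0(pick(c("skim milk", "whole milk")),
               ", sugar, modified corn starch, cocoa (processed with alkali),",
               " salt")
      } else if (identical(row_index, 1L)) {
        paste0(pick(c("low fat milk", "skim milk", "reduced fat milk")),
               ", vitamin a palmitate, vitamin d3")
      } else {
        paste0(pick(c("whole milk", "skim milk", "greek yogurt",
                      "cultured pasteurized milk")),
               ", cream, sugar (8.2%), live active cultures")
      }
    },
    dairy_first_fvn =
      paste0(pick(c("whole milk (59.5%)", "skim milk", "greek yogurt")),
             ", sugar (8.2%), ", pick(fruit_piece),
             " (5%), live active cultures"),
    neither_fvn = {
      if (identical(row_index, 5L)) {
        paste0(pick(nuts), ", ", pick(c("sea salt", "vegetable oil, sea salt")))
      } else if (identical(row_index, 12L)) {
        "soy protein isolate, peanuts, honey, chicory root fiber"
      } else if (identical(row_index, 14L)) {
        paste0("sugar, cocoa butter, chocolate, ", pick(nuts),
               ", soy lecithin")
      } else {
        paste0("oats, tapioca syrup, ",
               pick(c(nuts, "raisins", "dried cranberries")),
               ", honey, brown rice")
      }
    },
    neither = neither_label(row_index, pick),
    stop("unknown template class '", template_class, "'", call. = FALSE)
  )
}

neither_label <- function(row_index, pick) {
  if (is.na(row_index)) row_index <- -1L
  switch(
    as.character(row_index),
    "6" = "sugar, enriched wheat flour, eggs, soybean oil, baking powder, salt",
    "7" = "potatoes, vegetable oil, salt",
    "8" = "corn, vegetable oil, salt",
    "9" = "popcorn, palm oil, salt",
    "10" = paste0("enriched flour (wheat flour, niacin, reduced iron), ",
                  "vegetable oil, salt, yeast"),
    "11" = "oats, sugar, canola oil, honey, brown rice",
    "13" = paste0(
      "sugar, unbleached enriched flour (wheat flour, niacin, reduced iron, ",
      "thiamine mononitrate [vitamin b1], riboflavin [vitamin b2], ",
      "folic acid), palm oil, cocoa (processed with alkali), ",
      "high fructose corn syrup, salt, soy lecithin"),
    "14" = paste0("sugar, cocoa butter, chocolate, skim milk, soy lecithin, ",
                  "vanillin - an artificial flavor"),
    "15" = pick(c(
      "glucose syrup, sugar, gelatin, citric acid, fruit flavor",
      "sugar, corn syrup, modified corn starch, fruit pectin, citric acid")),
    "16" = "cream, skim milk, sugar, egg yolks, vanilla extract",
    "18" = "water, sugar, corn syrup, natural flavors",
    "23" = paste0("carbonated water, high fructose corn syrup, caramel color, ",
                  "phosphoric acid, natural flavors"),
    "24" = paste0("water, sugar, orange juice concentrate, citric acid, ",
                  "natural flavor"),
    pick(c("sugar, wheat flour, palm oil, salt",
           "wheat flour, sugar, vegetable oil, salt"))
  )
}

# Config serialization --------------------------------------------------------

#' Read or write a generator configuration as YAML
#'
#' Round-trips a `snack_sim_config`: `read_sim_config(write_sim_config(x))`
#' reproduces `x` exactly.
#'
#' @param config A `snack_sim_config`.
#' @param path File path.
#' @return `read_sim_config()` returns a `snack_sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
write_sim_config <- function(config, path) {
  validate_config(config)
  cats <- config$categories
  doc <- list(
    seed = config$seed,
    country_weights = as.list(config$country_weights),
    added_sugar_frac = lapply(config$added_sugar_frac, as.list),
    class_profiles = lapply(config$class_profiles, function(p)
      stats::setNames(
        purrr::map2(p$mean, p$sd, function(m, s) list(mean = m, sd = s)),
        p$variable)),
    categories = lapply(seq_len(nrow(cats)), function(i) {
      row <- cats[i, ]
      list(
        row_index = row$row_index, label = row$label,
        codes = as.list(row$codes[[1]]), n = row$n,
        ed_mean = row$ed_mean, ed_sd = row$ed_sd,
        n_fruit_first = row$n_fruit_first,
        n_dairy_first = row$n_dairy_first,
        n_dairy_first_fvn = row$n_dairy_first_fvn,
        n_neither_fvn = row$n_neither_fvn,
        n_neither = row$n_neither
      )
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  doc <- yaml::read_yaml(path)
  cats <- dplyr::bind_rows(lapply(doc$categories, function(row) {
    tibble::tibble(
      row_index = as.integer(row$row_index), label = row$label,
      codes = list(as.integer(unlist(row$codes))), n = as.integer(row$n),
      ed_mean = as.numeric(row$ed_mean), ed_sd = as.numeric(row$ed_sd),
      n_fruit_first = as.integer(row$n_fruit_first),
      n_dairy_first = as.integer(row$n_dairy_first),
      n_dairy_first_fvn = as.integer(row$n_dairy_first_fvn),
      n_neither_fvn = as.integer(row$n_neither_fvn),
      n_neither = as.integer(row$n_neither)
    )
  }))
  profiles <- lapply(doc$class_profiles, function(p)
    tibble::tibble(
      variable = names(p),
      mean = unname(vapply(p, function(e) as.numeric(e$mean), 0)),
      sd = unname(vapply(p, function(e) as.numeric(e$sd), 0))
    ))
  config <- structure(
    list(
      categories = cats,
      class_profiles = profiles,
      added_sugar_frac = lapply(doc$added_sugar_frac,
                                function(x) as.numeric(unlist(x))),
      country_weights = unlist(doc$country_weights),
      seed = as.integer(doc$seed)
    ),
    class = "snack_sim_config"
  )
  validate_config(config)
}

#' Rescale a configuration's product counts
#'
#' Multiplies every per-category (and per-template-class) count by `factor`,
#' e.g. for law-of-large-numbers checks of the generator's calibration.
#'
#' @param config A `snack_sim_config`.
#' @param factor Positive integer multiplier.
#' @return A rescaled `snack_sim_config`.
#' @examples
#' sum(scale_config(default_config(), 10)$categories$n) # 2610
#' @export
scale_config <- function(config, factor) {
  stopifnot(factor >= 1, factor == as.integer(factor))
  count_cols <- c("n", "n_fruit_first", "n_dairy_first", "n_dairy_first_fvn",
                  "n_neither_fvn", "n_neither")
  for (col in count_cols) {
    config$categories[[col]] <- as.integer(config$categories[[col]] * factor)
  }
  validate_config(config)
}
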