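# Shared fixtures: real-world back-of-pack ingredient strings covering the
# rule edge cases, and product builders for the scoring tests.

label_fruit_puree_pouch <- function() {
  "apple, apple puree concentrate, lemon juice concentrate"
}

label_ice_cream <- function() {
  "cream, skim milk, egg yolks, vanilla extract"
}

label_granola_bar <- function() {
  paste0(
    "oats, tapioca syrup, semi-sweet chocolate (unsweetened chocolate, ",
    "cane sugar, cocoa butter, vanilla extract), honey, canola oil, ",
    "brown rice, brown rice flour, cane sugar, sorghum, sea salt, quinoa, ",
    "vanilla extract, vitamin E")
}

label_sandwich_cookie <- function() {
  paste0(
    "sugar, unbleached enriched flour (wheat flour, niacin, reduced iron, ",
    "thiamine mononitrate [vitamin B1], riboflavin [vitamin B2], ",
    "folic acid), high oleic canola and/or palm and/or canola oil, ",
    "cocoa (processed with alkali), high fructose corn syrup, ",
    "leavening (baking soda and/or calcium phosphate), cornstarch, salt, ",
    "soy lecithin, vanillin—an artificial flavor, chocolate")
}

label_strawberry_yogurt <- function() {
  paste0(
    "whole milk (59.5%), skim milk powder, sugar (8.2%), ",
    "red fruit (blackberry, strawberry, raspberry 5%), raspberry (5%), ",
    "strawberry (5%)")
}

# A product record with every schema column; per-100 g amounts default to 0.
make_product <- function(product_id = "P1", ed = 100, ingredient = "sugar",
                         wweia_code = 5704L, ...) {
  base <- stats::setNames(
    as.list(rep(0, length(product_schema_columns()))),
    product_schema_columns())
  base$product_id <- product_id
  base$name <- product_id
  base$country <- "US"
  base$wweia_code <- wweia_code
  base$energy_kcal_100g <- ed
  base$ingredient_text <- ingredient
  dots <- list(...)
  for (nm in names(dots)) base[[nm]] <- dots[[nm]]
  tibble::as_tibble(base)
}

# Random fully-populated product for property tests.
random_product <- function(id) {
  make_product(
    product_id = paste0("R", id),
    ed = stats::runif(1, 40, 600),
    protein_g_100g = stats::runif(1, 0, 20),
    fiber_g_100g = stats::runif(1, 0, 10),
    vitamin_a_ug_100g = stats::runif(1, 0, 500),
    vitamin_c_mg_100g = stats::runif(1, 0, 60),
    vitamin_d_ug_100g = stats::runif(1, 0, 5),
    calcium_mg_100g = stats::runif(1, 0, 400),
    iron_mg_100g = stats::runif(1, 0, 8),
    potassium_mg_100g = stats::runif(1, 0, 500),
    satfat_g_100g = stats::runif(1, 0, 15),
    added_sugar_g_100g = stats::runif(1, 0, 30),
    sodium_mg_100g = stats::runif(1, 0, 800),
    total_sugar_g_100g = stats::runif(1, 30, 60)
  )
}

# Independent brute-force scorer written directly from the defining
# equations: NRn = sum_i min(cap, Content_i/DV_i * 100) with Content_i per
# 100 kcal, LIM = sum_i Content_i/MRV_i * 100, NRF = NR - LIM. Shares
# nothing with the package implementation beyond the column naming scheme.
oracle_score <- function(product, standards = nrf_standards()) {
  ed <- product$energy_kcal_100g
  nr <- 0
  for (i in seq_len(nrow(standards$qualifying))) {
    col <- paste0(standards$qualifying$nutrient[i], "_",
                  standards$qualifying$unit[i], "_100g")
    content_100kcal <- product[[col]] * 100 / ed
    nr <- nr + min(standards$cap,
                   content_100kcal / standards$qualifying$dv[i] * 100)
  }
  lim <- 0
  for (i in seq_len(nrow(standards$limiting))) {
    col <- paste0(standards$limiting$nutrient[i], "_",
                  standards$limiting$unit[i], "_100g")
    content_100kcal <- product[[col]] * 100 / ed
    lim <- lim + content_100kcal / standards$limiting$mrv[i] * 100
  }
  list(nr = nr, lim = lim, nrf = nr - lim)
}
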