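test_that("energy density is kcal per 100 g with input validation", {
  expect_equal(energy_density(59, 100), 59)
  expect_equal(energy_density(150, 50), 300)
  expect_equal(energy_density(0, 100), 0)
  expect_error(energy_density(100, 0), "strictly positive")
  expect_error(energy_density(-1, 100), "non-negative")
})

test_that("per-100 kcal conversion rescales by energy density", {
  expect_equal(amount_per_100kcal(2, 100), 2)
  expect_equal(amount_per_100kcal(3, 50), 6)
  expect_equal(amount_per_100kcal(10, 500), 2)
  expect_error(amount_per_100kcal(1, 0.5, product_id = "B9"),
               "unscorable.*B9")
})

test_that("%DV is referenced to the daily value and capped", {
  std <- nrf_standards()
  expect_equal(percent_dv("protein", 50, std), list(capped = 100, uncapped = 100))
  expect_equal(percent_dv("vitamin_c", 160, std),
               list(capped = 100, uncapped = 200))
  expect_equal(percent_dv("fiber", 1.4, std)$capped, 5)
  expect_error(percent_dv("selenium", 1, std), "unknown qualifying nutrient")
})

test_that("%MRV is referenced to the maximum recommended value, uncapped", {
  std <- nrf_standards()
  expect_equal(percent_mrv("added_sugar", 25, std), 50)
  expect_equal(percent_mrv("sodium", 0, std), 0)
  expect_equal(percent_mrv("satfat", 20, std), 100)
  expect_equal(percent_mrv("added_sugar", 75, std), 150) # no cap on LIM side
  expect_equal(percent_mrv("total_sugar", 25, std), 50)
  expect_error(percent_mrv("cholesterol", 1, std), "unknown limiting nutrient")
})

test_that("degenerate products score at the boundary values", {
  null_food <- make_product("null", ed = 100)
  s <- score_product(null_food)
  expect_equal(s$nr_subscore, 0)
  expect_equal(s$lim_subscore, 0)
  expect_equal(s$nrf_score, 0)

  # exactly one DV of each qualifying nutrient per 100 kcal, zero LIM
  std <- nrf_standards()
  args <- stats::setNames(
    as.list(std$qualifying$dv),
    paste0(std$qualifying$nutrient, "_", std$qualifying$unit, "_100g"))
  best <- do.call(make_product, c(list(product_id = "best", ed = 100), args))
  expect_equal(score_product(best)$nrf_score, 8 * 100)
})

test_that("unscorable and incomplete products are reported", {
  low_ed <- make_product("water1", ed = 0)
  expect_error(score_products(low_ed), "unscorable.*water1")
  expect_warning(score_products(low_ed, on_unscorable = "skip"), "skipping")

  partial <- make_product("p1", ed = 200)
  partial$protein_g_100g <- NA_real_
  expect_warning(s <- score_products(partial), "missing nutrient")
  expect_equal(s$nrf_score, 0) # NA contributed 0
})

test_that("scoring agrees with a brute-force oracle to 1e-9", {
  withr::with_seed(11, {
    prods <- dplyr::bind_rows(lapply(1:200, random_product))
  })
  scores <- score_products(prods)
  for (i in seq_len(nrow(prods))) {
    o <- oracle_score(prods[i, ])
    expect_equal(scores$nr_subscore[i], o$nr, tolerance = 1e-9)
    expect_equal(scores$lim_subscore[i], o$lim, tolerance = 1e-9)
    expect_equal(scores$nrf_score[i], o$nrf, tolerance = 1e-9)
  }
})

test_that("scores are invariant to rescaling mass and energy together", {
  withr::with_seed(21, prods <- dplyr::bind_rows(lapply(1:25, random_product)))
  base <- score_products(prods)
  for (lambda in c(0.25, 3.7)) {
    scaled <- prods
    cols <- grep("_100g$", names(scaled), value = TRUE)
    for (col in cols) scaled[[col]] <- scaled[[col]] * lambda
    s <- score_products(scaled)
    expect_equal(s$nr_subscore, base$nr_subscore, tolerance = 1e-12)
    expect_equal(s$lim_subscore, base$lim_subscore, tolerance = 1e-12)
    expect_equal(s$nrf_score, base$nrf_score, tolerance = 1e-12)
  }
})

test_that("qualifying nutrients never hurt and limiting nutrients never help", {
  withr::with_seed(31, prods <- dplyr::bind_rows(lapply(1:20, random_product)))
  base <- score_products(prods)
  std <- nrf_standards()
  for (i in seq_len(nrow(std$qualifying))) {
    col <- paste0(std$qualifying$nutrient[i], "_",
                  std$qualifying$unit[i], "_100g")
    up <- prods
    up[[col]] <- up[[col]] * 2 + 1
    expect_true(all(score_products(up)$nrf_score >= base$nrf_score - 1e-12))
  }
  for (i in seq_len(nrow(std$limiting))) {
    col <- paste0(std$limiting$nutrient[i], "_",
                  std$limiting$unit[i], "_100g")
    up <- prods
    up[[col]] <- up[[col]] * 2 + 1
    up$total_sugar_g_100g <- up$total_sugar_g_100g + up$added_sugar_g_100g
    expect_true(all(score_products(up)$nrf_score <= base$nrf_score + 1e-12))
  }
})

test_that("score identities and bounds hold for random products", {
  withr::with_seed(41, prods <- dplyr::bind_rows(lapply(1:100, random_product)))
  s <- score_products(prods)
  expect_equal(s$nrf_score, s$nr_subscore - s$lim_subscore) # exact identity
  expect_true(all(s$nr_subscore >= 0 & s$nr_subscore <= 8 * 100))
  expect_true(all(s$lim_subscore >= 0))
  dv_cols <- grep("^pct_dv_(?!uncapped)", names(s), value = TRUE, perl = TRUE)
  for (col in dv_cols) expect_true(all(s[[col]] >= 0 & s[[col]] <= 100))
})

test_that("the qualifying set is configurable between NRF6.3 and NRF15.3", {
  q6 <- default_qualifying_nutrients()[1:6, ]
  std6 <- nrf_standards(qualifying = q6)
  full <- make_product("x", ed = 100,
                       protein_g_100g = 50, fiber_g_100g = 28,
                       vitamin_a_ug_100g = 800, vitamin_c_mg_100g = 80,
                       vitamin_d_ug_100g = 15, calcium_mg_100g = 1000,
                       iron_mg_100g = 18, potassium_mg_100g = 4700)
  expect_equal(score_product(full, std6)$nr_subscore, 600)
  expect_equal(score_product(full)$nr_subscore, 800)

  q16 <- dplyr::bind_rows(
    default_qualifying_nutrients(),
    tibble::tibble(nutrient = paste0("x", 1:8), dv = 1, unit = "g"))
  expect_error(nrf_standards(qualifying = q16), "between 1 and 15")
  expect_error(nrf_standards(limiting = default_limiting_nutrients()[1:2, ]),
               "exactly 3")
})

test_that("reference standards round-trip through the YAML config format", {
  std <- nrf_standards(cap = 90, total_sugar_mrv = 45)
  f <- withr::local_tempfile(fileext = ".yml")
  write_standards(std, f)
  back <- read_standards(f)
  expect_equal(back$qualifying, std$qualifying)
  expect_equal(back$limiting, std$limiting)
  expect_equal(back$cap, 90)
  expect_equal(back$total_sugar_mrv, 45)
})
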