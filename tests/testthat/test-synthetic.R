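test_that("the default configuration reproduces the study structure", {
  cfg <- default_config()
  expect_equal(nrow(cfg$categories), 24)
  expect_equal(sum(cfg$categories$n), 261)
  choc <- cfg$categories[cfg$categories$label == "Candy, chocolate", ]
  expect_equal(choc$n, 19L)
  expect_equal(choc$ed_mean, 517)
  expect_true(all(cfg$categories$ed_mean > ED_MIN))
  # group sizes implied by the template allocation
  fd <- with(cfg$categories,
             sum(n_fruit_first + n_dairy_first + n_dairy_first_fvn))
  fvn <- with(cfg$categories,
              sum(n_fruit_first + n_dairy_first_fvn + n_neither_fvn))
  expect_equal(fd, 115)
  expect_equal(fvn, 88)
})

test_that("generation is deterministic given the seed", {
  a <- generate_dataset(default_config(), seed = 99)
  b <- generate_dataset(default_config(), seed = 99)
  expect_identical(a, b)
  c <- generate_dataset(default_config(), seed = 100)
  expect_false(identical(a, c))
  # structure is fixed even when draws vary
  expect_equal(table(a$category_row), table(c$category_row))
})

test_that("every generated record is valid and scoreable end-to-end", {
  prods <- generate_dataset(default_config(), seed = 12)
  expect_equal(nrow(prods), 261)
  expect_true(all(product_schema_columns() %in% names(prods)))
  expect_true(all(prods$energy_kcal_100g >= ED_MIN))
  nutrient_cols <- grep("_100g$", names(prods), value = TRUE)
  for (col in nutrient_cols) expect_true(all(prods[[col]] >= 0))
  expect_true(all(prods$added_sugar_g_100g <=
                    prods$total_sugar_g_100g + 1e-9))
  expect_silent(scores <- score_products(prods))
  expect_equal(nrow(scores), 261)
})

test_that("intended classification flags are recovered for every product", {
  prods <- generate_dataset(default_config(), seed = 12)
  flags <- classify_products(prods)
  expect_equal(flags$fruit_or_dairy_first, prods$intended_fruit_or_dairy_first)
  expect_equal(flags$fvn_present, prods$intended_fvn)
  expect_equal(sum(flags$fruit_or_dairy_first), 115)
  expect_equal(sum(!flags$fruit_or_dairy_first), 146)
  expect_equal(sum(flags$fvn_present), 88)
  expect_equal(sum(!flags$fvn_present), 173)
})

test_that("group nutrient means recover the calibration targets", {
  # At the shipped default size the first-ingredient NRF gap should sit
  # within +/-5 points of the 30-point target; at 20x it tightens.
  prods <- generate_dataset(default_config()) # shipped default seed
  scores <- score_products(prods)
  fd <- prods$intended_fruit_or_dairy_first
  gap <- mean(scores$nrf_score[fd]) - mean(scores$nrf_score[!fd])
  expect_lt(abs(gap - 30), 5)

  big <- generate_dataset(scale_config(default_config(), 20), seed = 8)
  s_big <- score_products(big)
  fd_big <- big$intended_fruit_or_dairy_first
  gap_big <- mean(s_big$nrf_score[fd_big]) - mean(s_big$nrf_score[!fd_big])
  expect_lt(abs(gap_big - 30), 1.5)

  # class means approach the published group rows (pick two load-bearing ones)
  expect_lt(abs(mean(s_big$nr_subscore[fd_big]) - 45.63), 1.5)
  expect_lt(abs(mean(s_big$lim_subscore[!fd_big]) - 20.19), 1.5)
})

test_that("generator configurations round-trip through YAML", {
  cfg <- default_config()
  f <- withr::local_tempfile(fileext = ".yml")
  write_sim_config(cfg, f)
  back <- read_sim_config(f)
  expect_equal(back$categories, cfg$categories)
  expect_equal(back$class_profiles, cfg$class_profiles)
  expect_equal(back$added_sugar_frac, cfg$added_sugar_frac)
  expect_equal(back$country_weights, cfg$country_weights)
  expect_equal(back$seed, cfg$seed)
  # and an edited config still generates
  back$categories$n[1] <- 8L
  back$categories$n_dairy_first[1] <- 8L
  prods <- generate_dataset(back, seed = 4)
  expect_equal(sum(prods$category_row == 1), 8)
})

test_that("calibrated truncated draws hit their target means", {
  withr::with_seed(6, {
    # a skewed case: target mean close to the bound, large SD
    x <- snacknrf:::rtnorm_calibrated(200000, mean = 0.31, sd = 1.33, lower = 0)
  })
  expect_true(all(x >= 0))
  expect_lt(abs(mean(x) - 0.31), 0.01)
  expect_error(snacknrf:::rtnorm_calibrated(10, mean = -1, sd = 1, lower = 0),
               "must exceed the lower bound")
})
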