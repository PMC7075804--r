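test_that("WWEIA codes map to their unique category", {
  expect_equal(assign_category(1802)$label, "Yogurt, whole/reduced")
  expect_equal(assign_category(5704)$label, "Candy, fruit")
  expect_equal(assign_category(c(1004, 1206))$row_index, c(1L, 1L))
  expect_error(assign_category(9999), "unknown WWEIA code.*9999")
})

test_that("a category map with overlapping code sets is rejected", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("row_index,label,codes", "1,A,1004;1006", "2,B,1006;1602"), f)
  expect_error(wweia_categories(f), "not a partition")
})

test_that("category summaries report n, mean and sample SD per category", {
  prods <- dplyr::bind_rows(
    make_product("a", ed = 100, wweia_code = 5704L),
    make_product("b", ed = 100, wweia_code = 5704L,
                 protein_g_100g = 5),
    make_product("c", ed = 300, wweia_code = 1602L)
  )
  s <- summarize_categories(prods)
  fruit_candy <- s[which(s$label == "Candy, fruit"), ]
  expect_equal(fruit_candy$n, 2)
  expect_equal(fruit_candy$nrf_mean, mean(c(0, 10))) # 5 g protein = 10 %DV
  cheese <- s[which(s$label == "Cheese"), ]
  expect_equal(cheese$n, 1)
  expect_equal(cheese$nrf_sd, 0) # degenerate SD reported as 0
  expect_error(summarize_categories(prods[0, ]), "no products")
})

test_that("category counts partition the dataset and weighted means pool", {
  prods <- generate_dataset(default_config(), seed = 3)
  scores <- score_products(prods)
  s <- summarize_categories(prods, scores)
  per_cat <- s[!is.na(s$row_index), ]
  total <- s[is.na(s$row_index), ]
  expect_equal(sum(per_cat$n), nrow(prods))
  expect_equal(total$n, nrow(prods))
  # n-weighted mean of category means equals the pooled mean, exactly
  expect_equal(sum(per_cat$n * per_cat$nrf_mean) / sum(per_cat$n),
               mean(scores$nrf_score))
  expect_equal(sum(per_cat$n * per_cat$ed_mean) / sum(per_cat$n),
               mean(scores$energy_density))
})

test_that("two-group ANOVA matches its classical identities", {
  # identical groups: no between-group variance, F = 0, p = 1
  sc <- tibble::tibble(product_id = paste0("p", 1:6),
                       nrf_score = c(1, 2, 3, 1, 2, 3))
  cmp <- compare_groups(sc, rep(c(TRUE, FALSE), each = 3),
                        variables = "nrf_score")
  expect_equal(cmp$table$p_value, 1)

  # SEM = SD / sqrt(n)
  sc2 <- tibble::tibble(product_id = paste0("q", 1:18),
                        v = c(rnorm(9) * 0 + c(1, 2, 3, 4, 5, 6, 7, 8, 9),
                              rnorm(9)))
  sc2$v[1:9] <- scale(sc2$v[1:9]) * 3 + 10 # SD exactly 3, n = 9
  cmp2 <- compare_groups(sc2, rep(c(TRUE, FALSE), each = 9), variables = "v")
  expect_equal(cmp2$table$sem_a, 1)

  # two-group one-way ANOVA p equals the pooled-variance t-test p (F = t^2)
  withr::with_seed(13, {
    for (rep in 1:10) {
      y <- rnorm(24)
      flag <- sample(rep(c(TRUE, FALSE), 12))
      sc3 <- tibble::tibble(product_id = paste0("r", 1:24), y = y)
      p_anova <- compare_groups(sc3, flag, variables = "y")$table$p_value
      p_t <- t.test(y[flag], y[!flag], var.equal = TRUE)$p.value
      expect_equal(p_anova, p_t, tolerance = 1e-12)
    }
  })
})

test_that("groups with fewer than two products are rejected", {
  sc <- tibble::tibble(product_id = paste0("p", 1:5), y = 1:5)
  expect_error(compare_groups(sc, c(TRUE, rep(FALSE, 4)), variables = "y"),
               "degenerate group")
})

test_that("rendered comparisons carry significance labels and raw p", {
  withr::with_seed(17, {
    sc <- tibble::tibble(product_id = paste0("p", 1:40),
                         y = c(rnorm(20), rnorm(20) + 3),
                         z = rep(rnorm(20), 2)) # same values in both groups
  })
  cmp <- compare_groups(sc, rep(c(TRUE, FALSE), each = 20),
                        variables = c("y", "z"))
  fmt <- format_group_comparison(cmp)
  expect_equal(fmt$significance[1], "<0.001")
  expect_equal(fmt$significance[2], "")
  expect_true(all(!is.na(cmp$table$p_value)))
  expect_true(all(cmp$table$p_value >= 0 & cmp$table$p_value <= 1))
})
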