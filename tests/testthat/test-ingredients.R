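test_that("labels split on top-level commas in order of predominance", {
  toks <- parse_ingredients(label_fruit_puree_pouch())
  expect_length(toks, 3)
  expect_equal(toks[[1]]$name, "apple")
  expect_equal(vapply(toks, `[[`, 0L, "position"), 1:3)

  cookie <- parse_ingredients(label_sandwich_cookie())
  expect_equal(cookie[[2]]$name, "unbleached enriched flour")
  expect_length(cookie[[2]]$sub_ingredients, 6)
  # square brackets behave like parentheses
  expect_equal(cookie[[2]]$sub_ingredients[[4]]$sub_ingredients[[1]]$name,
               "vitamin b1")
})

test_that("QUID percentages are extracted, parenthesized or bare", {
  yog <- parse_ingredients(label_strawberry_yogurt())
  expect_equal(yog[[1]]$name, "whole milk")
  expect_equal(yog[[1]]$quid_percent, 59.5)
  red_fruit <- yog[[4]]
  expect_equal(red_fruit$name, "red fruit")
  expect_equal(red_fruit$sub_ingredients[[3]]$name, "raspberry")
  expect_equal(red_fruit$sub_ingredients[[3]]$quid_percent, 5)
  expect_error(parse_ingredients("milk (150%)"), "QUID")
})

test_that("malformed labels are rejected with informative errors", {
  expect_error(parse_ingredients(""), "empty ingredient label")
  expect_error(parse_ingredients("   "), "empty ingredient label")
  expect_error(parse_ingredients("sugar, flour (wheat, salt"), "unbalanced")
  expect_error(parse_ingredients("sugar) , flour"), "offset")
})

test_that("canonical serialization round-trips the token tree", {
  labels <- c(label_fruit_puree_pouch(), label_ice_cream(),
              label_granola_bar(), label_sandwich_cookie(),
              label_strawberry_yogurt(), "water, oranges")
  for (lab in labels) {
    toks <- parse_ingredients(lab)
    again <- parse_ingredients(deparse_ingredients(toks))
    expect_equal(unclass(again), unclass(toks))
  }
})

test_that("the documented example labels classify as expected", {
  lex <- default_lexicons()
  cases <- list(
    # label, dairy_first, fruit_first, fvn
    list(label_fruit_puree_pouch(), FALSE, TRUE, TRUE),
    list(label_strawberry_yogurt(), TRUE, FALSE, TRUE),
    list(label_ice_cream(), FALSE, FALSE, FALSE), # cream is not milk/yogurt/cheese
    list(label_granola_bar(), FALSE, FALSE, FALSE),
    list(label_sandwich_cookie(), FALSE, FALSE, FALSE),
    list("water, oranges", FALSE, TRUE, TRUE),
    list("sugar, strawberries", FALSE, FALSE, TRUE) # fruit after sugar
  )
  for (case in cases) {
    cl <- classify_ingredients(case[[1]], lex)
    expect_equal(cl$dairy_first, case[[2]], label = case[[1]])
    expect_equal(cl$fruit_first, case[[3]], label = case[[1]])
    expect_equal(cl$fvn_present, case[[4]], label = case[[1]])
    expect_equal(cl$fruit_or_dairy_first, case[[2]] || case[[3]])
    if (cl$dairy_first || cl$fruit_first || cl$fvn_present) {
      expect_gt(nrow(cl$matched_terms), 0)
    }
  }
})

test_that("exclusion terms are checked before inclusion terms", {
  expect_false(classify_dairy_first("milk chocolate, sugar"))
  expect_false(classify_dairy_first("skim milk powder, water"))
  expect_false(classify_dairy_first("modified milk solids, sugar"))
  expect_true(classify_dairy_first("whole milk, sugar"))
  expect_true(classify_dairy_first("greek yogurt, honey"))
  expect_true(classify_dairy_first("cheddar cheese (milk, salt)"))

  expect_false(classify_fruit_first("apple juice concentrate, water"))
  expect_false(classify_fruit_first("strawberry jam, flour"))
  expect_false(classify_fruit_first("fruit flavor, sugar"))
  expect_true(classify_fruit_first("apple puree, water"))
})

test_that("classification ignores case and surrounding whitespace", {
  a <- classify_ingredients("  WHOLE MILK (59.5%),   Sugar ")
  b <- classify_ingredients("whole milk (59.5%), sugar")
  expect_equal(a$dairy_first, b$dairy_first)
  expect_equal(a$fvn_present, b$fvn_present)
  expect_true(a$dairy_first)
})

test_that("starchy vegetables in chip form never earn FVN credit", {
  expect_false(detect_fvn("potatoes, vegetable oil, salt", wweia_code = 5002))
  expect_false(detect_fvn("corn, vegetable oil, salt", wweia_code = 5004))
  # default lexicon excludes potato/corn even outside chip categories
  expect_false(detect_fvn("potatoes, vegetable oil, salt"))
  # a user lexicon adding potato is still overridden inside chip categories
  lex <- default_lexicons()
  lex$vegetables <- c(lex$vegetables, "potato")
  expect_true(detect_fvn("potatoes, vegetable oil, salt", lex))
  expect_false(detect_fvn("potatoes, vegetable oil, salt", lex,
                          wweia_code = 5002))
})

test_that("fruit-first labels are always FVN-positive (implication)", {
  withr::with_seed(5, {
    labels <- c(
      replicate(30, generate_ingredient_label(
        "fruit_first", sample(c(NA, 15L, 19L, 20L, 21L, 22L), 1))),
      replicate(20, generate_ingredient_label("dairy_first", NA)),
      replicate(20, generate_ingredient_label("neither", sample(6:24, 1)))
    )
  })
  lex <- default_lexicons()
  for (lab in labels) {
    cl <- classify_ingredients(lab, lex)
    if (cl$fruit_first) expect_true(cl$fvn_present, label = lab)
  }
})

test_that("matching folds plurals onto singular lexicon terms", {
  expect_true(classify_fruit_first("strawberries, water"))
  expect_true(classify_fruit_first("peaches, water"))
  expect_true(detect_fvn("sugar, dried cranberries"))
  expect_false(detect_fvn("sugar, grass")) # no false singular match
})
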