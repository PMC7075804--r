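#' Parse a back-of-pack ingredient list
#'
#' Ingredient labels list ingredients in order of predominance: the
#' ingredient used in the greatest amount first, followed in descending
#' order. This parser splits the label on top-level commas, treats
#' parenthesized (or square-bracketed) groups as nested sub-ingredient
#' lists, and extracts quantitative ingredient declarations (QUID, e.g.
#' `"whole milk (59.5%)"` or `"raspberry 5%"`) into a `quid_percent` field.
#' Names are lowercased and whitespace-normalized.
#'
#' @param label_text Raw ingredient string; must be non-empty after
#'   trimming.
#' @return An `ingredient_list`: an ordered list of tokens, each a list with
#'   `position` (1-based rank among its siblings), `name`, `quid_percent`
#'   (`NA` if undeclared) and `sub_ingredients` (possibly empty list of
#'   nested tokens).
#' @examples
#' toks <- parse_ingredients("water, oranges")
#' toks[[1]]$name
#' parse_ingredients("whole milk (59.5%), sugar (8.2%)")[[1]]$quid_percent
#' @export
parse_ingredients <- function(label_text) {
  if (length(label_text) != 1 || is.na(label_text) ||
      !nzchar(trimws(label_text))) {
    stop("empty ingredient label", call. = FALSE)
  }
  # Square brackets annotate the same way parentheses do.
  txt <- gsub("\\[", "(", label_text)
  txt <- gsub("\\]", ")", txt)
  check_balanced(txt)
  structure(parse_ingredient_level(txt), class = "ingredient_list")
}

check_balanced <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("unbalanced parentheses in ingredient label at offset ", i,
             call. = FALSE)
      }
    }
  }
  if (depth != 0L) {
    stop("unbalanced parentheses in ingredient label: ", depth,
         " unclosed '(' at end of string", call. = FALSE)
  }
  invisible(TRUE)
}

# Split one nesting level on top-level commas and parse each piece.
parse_ingredient_level <- function(txt) {
  pieces <- split_top_level(txt)
  pieces <- pieces[nzchar(trimws(pieces))]
  out <- vector("list", length(pieces))
  for (i in seq_along(pieces)) {
    out[[i]] <- parse_ingredient_token(pieces[i], position = i)
  }
  out
}

split_top_level <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  cut <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") depth <- depth - 1L
    else if (chars[i] == "," && depth == 0L) cut <- c(cut, i)
  }
  starts <- c(1L, cut + 1L)
  ends <- c(cut - 1L, length(chars))
  vapply(seq_along(starts), function(k) {
    if (starts[k] > ends[k]) "" else
      paste(chars[starts[k]:ends[k]], collapse = "")
  }, "")
}

parse_ingredient_token <- function(txt, position) {
  txt <- trimws(txt)
  quid <- NA_real_
  subs <- list()
  # Peel trailing parenthesized groups: a QUID annotation "(59.5%)" or a
  # sub-ingredient list "(wheat flour, niacin)"; both may be present.
  repeat {
    if (!grepl("\\)\\s*$", txt)) break
    open <- find_matching_open(txt)
    inner <- sub("\\)\\s*$", "", substr(txt, open + 1L, nchar(txt)))
    if (grepl("^\\s*[0-9]+(\\.[0-9]+)?\\s*%\\s*$", inner) && is.na(quid)) {
      quid <- as.numeric(sub("%", "", gsub("\\s", "", inner)))
    } else if (length(subs) == 0) {
      subs <- parse_ingredient_level(inner)
    } else {
      break
    }
    txt <- trimws(substr(txt, 1L, open - 1L))
  }
  # Bare trailing QUID without parentheses: "raspberry 5%".
  m <- regmatches(txt, regexec("\\s+([0-9]+(\\.[0-9]+)?)\\s*%$", txt))[[1]]
  if (length(m) > 0 && is.na(quid)) {
    quid <- as.numeric(m[2])
    txt <- sub("\\s+[0-9]+(\\.[0-9]+)?\\s*%$", "", txt)
  }
  name <- tolower(gsub("\\s+", " ", trimws(txt)))
  if (!nzchar(name)) {
    stop("ingredient token at position ", position, " has an empty name",
         call. = FALSE)
  }
  if (!is.na(quid) && (quid <= 0 || quid > 100)) {
    stop("QUID percentage out of (0, 100] for token '", name, "': ", quid,
         call. = FALSE)
  }
  list(position = position, name = name, quid_percent = quid,
       sub_ingredients = subs)
}

# Index of the '(' matching the final ')' of the string.
find_matching_open <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  i <- length(chars)
  while (chars[i] != ")") i <- i - 1L
  depth <- 0L
  while (i >= 1L) {
    if (chars[i] == ")") depth <- depth + 1L
    if (chars[i] == "(") {
      depth <- depth - 1L
      if (depth == 0L) return(i)
    }
    i <- i - 1L
  }
  stop("unbalanced parentheses", call. = FALSE) # unreachable after check
}

#' Serialize parsed ingredients back to a canonical label string
#'
#' The canonical form writes sub-ingredient lists in parentheses and QUID
#' percentages as a trailing `"(x%)"` group; re-parsing the canonical string
#' yields an identical token tree.
#'
#' @param tokens An `ingredient_list` from [parse_ingredients()].
#' @return A single string.
#' @examples
#' deparse_ingredients(parse_ingredients("Whole Milk (59.5%), sugar"))
#' @export
deparse_ingredients <- function(tokens) {
  paste(vapply(tokens, deparse_token, ""), collapse = ", ")
}

deparse_token <- function(tok) {
  out <- tok$name
  if (length(tok$sub_ingredients) > 0) {
    out <- paste0(out, " (", deparse_ingredients(tok$sub_ingredients), ")")
  }
  if (!is.na(tok$quid_percent)) {
    out <- paste0(out, " (", format(tok$quid_percent, trim = TRUE), "%)")
  }
  out
}

#' @export
print.ingredient_list <- function(x, ...) {
  show <- function(toks, indent) {
    for (tok in toks) {
      cat(strrep("  ", indent), tok$position, ". ", tok$name,
          if (!is.na(tok$quid_percent)) sprintf(" [%g%%]", tok$quid_percent),
          "\n", sep = "")
      show(tok$sub_ingredients, indent + 1)
    }
  }
  show(x, 0)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Lexicon handling

#' Load the term lexica used by the classification rules
#'
#' Classification is lexicon-driven: dairy, fruit, vegetable and nut/seed
#' term lists ship as editable plain-text files (UTF-8, one term per line,
#' `#` comments). Exclusion lists are applied before inclusion lists, so
#' e.g. "milk chocolate" never matches the dairy rule even though it
#' contains "milk".
#'
#' @param dir Directory holding the lexicon files; defaults to the lexica
#'   shipped with the package.
#' @return Named list of character vectors: `dairy`, `dairy_exclude`,
#'   `fruit`, `fruit_exclude`, `vegetables`, `nuts_seeds`.
#' @export
default_lexicons <- function(dir = system.file("extdata", "lexicons",
                                               package = "snacknrf")) {
  files <- c(
    dairy = "dairy_first.txt",
    dairy_exclude = "dairy_first_exclude.txt",
    fruit = "fruit.txt",
    fruit_exclude = "fruit_exclude.txt",
    vegetables = "vegetables.txt",
    nuts_seeds = "nuts_seeds.txt"
  )
  lapply(stats::setNames(file.path(dir, files), names(files)), read_lexicon)
}

#' @rdname default_lexicons
#' @param path Path to a single lexicon file.
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- tolower(trimws(lines))
  lines[nzchar(lines)]
}

# Light singularization so lexicon terms in the singular match plural label
# words ("strawberries" ~ "strawberry", "oranges" ~ "orange").
singularize <- function(w) {
  w <- ifelse(grepl("ies$", w) & nchar(w) > 4, sub("ies$", "y", w), w)
  w <- ifelse(grepl("(ses|xes|zes|ches|shes|oes)$", w), sub("es$", "", w), w)
  ifelse(grepl("[^su]s$", w), sub("s$", "", w), w)
}

token_word_list <- function(name) {
  singularize(strsplit(tolower(name), "[^a-z0-9]+")[[1]])
}

# Pre-split and singularize a lexicon once: single-word terms are matched by
# set membership, multi-word terms as consecutive word n-grams.
compile_lexicon <- function(terms) {
  word_lists <- lapply(terms, function(t) singularize(strsplit(t, "[^a-z0-9]+")[[1]]))
  k <- lengths(word_lists)
  list(
    single = stats::setNames(terms[k == 1], unlist(word_lists[k == 1])),
    multi_words = word_lists[k > 1],
    multi_terms = terms[k > 1]
  )
}

compile_lexicons <- function(lex) {
  if (isTRUE(attr(lex, "compiled"))) return(lex)
  structure(lapply(lex, compile_lexicon), compiled = TRUE)
}

# First lexicon term occurring (as consecutive whole words) in `words`, or NA.
first_matching_term <- function(words, clex) {
  hit <- match(names(clex$single), words)
  if (any(!is.na(hit))) return(clex$single[[which(!is.na(hit))[1]]])
  n <- length(words)
  for (j in seq_along(clex$multi_words)) {
    tw <- clex$multi_words[[j]]
    k <- length(tw)
    if (k > n) next
    for (s in seq_len(n - k + 1)) {
      if (all(words[s:(s + k - 1)] == tw)) return(clex$multi_terms[j])
    }
  }
  NA_character_
}

contains_term <- function(words, term) {
  !is.na(first_matching_term(words, compile_lexicon(term)))
}

# Rule predicates on a single token name. Exclusion terms are checked before
# inclusion terms. `lex` must be compiled (compile_lexicons()).
match_dairy <- function(name, lex) {
  words <- token_word_list(name)
  if (!is.na(first_matching_term(words, lex$dairy_exclude))) return(NA_character_)
  first_matching_term(words, lex$dairy)
}

match_fruit <- function(name, lex) {
  words <- token_word_list(name)
  if (!is.na(first_matching_term(words, lex$fruit_exclude))) return(NA_character_)
  first_matching_term(words, lex$fruit)
}

starchy_chip_lexicon <- local({
  compiled <- NULL
  function() {
    if (is.null(compiled)) compiled <<- compile_lexicon(c("potato", "corn"))
    compiled
  }
})

match_vegetable <- function(name, lex, chip_product = FALSE) {
  words <- token_word_list(name)
  if (chip_product &&
      !is.na(first_matching_term(words, starchy_chip_lexicon()))) {
    return(NA_character_)
  }
  first_matching_term(words, lex$vegetables)
}

match_nut_seed <- function(name, lex) {
  first_matching_term(token_word_list(name), lex$nuts_seeds)
}

# ---------------------------------------------------------------------------
# Classification rules

#' First-ingredient and FVN classification rules
#'
#' Three back-of-pack rules, all driven by the order of predominance:
#'
#' * **dairy-first** — true only when milk, yogurt or cheese (and qualified
#'   variants such as "whole milk" or "greek yogurt") is the *first* listed
#'   ingredient. Milk chocolate, milk powder, skim milk powder and modified
#'   milk solids never qualify, wherever they appear. Note that cream is
#'   deliberately not in the dairy lexicon: the rule enumerates only milk,
#'   yogurt and cheese, so cream-first ice creams classify as
#'   neither-first.
#' * **fruit-first** — true only when a fruit (whole fruit or fruit puree)
#'   is the first ingredient; second place following water is allowed (the
#'   "water, oranges" juice-from-concentrate pattern) but not after sugar or
#'   any other ingredient. Fruit concentrates (used as sweeteners), jams,
#'   pectins, fruit flavors, powders and leathers never qualify.
#' * **FVN presence** — true when any ingredient at any nesting depth is a
#'   fruit, vegetable, nut, peanut or seed, after the same fruit exclusions.
#'   Starchy vegetables (potatoes, corn) in the form of chips do not
#'   qualify: the default vegetable lexicon omits them entirely, and in chip
#'   categories (WWEIA 5002/5004/5008) they are excluded even if a user
#'   lexicon adds them.
#'
#' @param tokens An `ingredient_list` from [parse_ingredients()], or a raw
#'   label string (parsed on the fly).
#' @param lexicons Term lists from [default_lexicons()].
#' @param wweia_code Optional WWEIA category code of the product, used only
#'   for the starchy-vegetable-as-chips exclusion.
#' @return `classify_dairy_first()`, `classify_fruit_first()` and
#'   `detect_fvn()` return a logical scalar. `classify_ingredients()` returns
#'   a list of class `ingredient_classification` with logical flags
#'   `dairy_first`, `fruit_first`, `fruit_or_dairy_first`, `fvn_present` and
#'   a `matched_terms` tibble (`token`, `rule`, `term`) explaining every
#'   true flag.
#' @examples
#' classify_ingredients("whole milk (59.5%), sugar, strawberries (5%)")
#' classify_fruit_first(parse_ingredients("water, oranges"))
#' @export
classify_ingredients <- function(tokens, lexicons = default_lexicons(),
                                 wweia_code = NULL) {
  tokens <- as_ingredient_list(tokens)
  lexicons <- compile_lexicons(lexicons)
  matched <- list()
  note <- function(token, rule, term) {
    matched[[length(matched) + 1]] <<-
      tibble::tibble(token = token, rule = rule, term = term)
  }

  dairy <- FALSE
  fruit <- FALSE
  if (length(tokens) >= 1) {
    t1 <- tokens[[1]]$name
    dt <- match_dairy(t1, lexicons)
    if (!is.na(dt)) {
      dairy <- TRUE
      note(t1, "dairy_first", dt)
    }
    ft <- match_fruit(t1, lexicons)
    if (!is.na(ft)) {
      fruit <- TRUE
      note(t1, "fruit_first", ft)
    } else if (length(tokens) >= 2 &&
               contains_term(token_word_list(t1), "water")) {
      ft2 <- match_fruit(tokens[[2]]$name, lexicons)
      if (!is.na(ft2)) {
        fruit <- TRUE
        note(tokens[[2]]$name, "fruit_first_after_water", ft2)
      }
    }
  }

  chip <- !is.null(wweia_code) && !is.na(wweia_code) &&
    wweia_code %in% chip_wweia_codes()
  fvn <- FALSE
  walk <- function(toks) {
    for (tok in toks) {
      ft <- match_fruit(tok$name, lexicons)
      if (!is.na(ft)) { fvn <<- TRUE; note(tok$name, "fvn_fruit", ft) }
      vt <- match_vegetable(tok$name, lexicons, chip_product = chip)
      if (!is.na(vt)) { fvn <<- TRUE; note(tok$name, "fvn_vegetable", vt) }
      nt <- match_nut_seed(tok$name, lexicons)
      if (!is.na(nt)) { fvn <<- TRUE; note(tok$name, "fvn_nut_seed", nt) }
      walk(tok$sub_ingredients)
    }
  }
  walk(tokens)

  structure(
    list(
      dairy_first = dairy,
      fruit_first = fruit,
      fruit_or_dairy_first = dairy || fruit,
      fvn_present = fvn,
      matched_terms = if (length(matched) > 0) {
        dplyr::distinct(dplyr::bind_rows(matched))
      } else {
        tibble::tibble(token = character(0), rule = character(0),
                       term = character(0))
      }
    ),
    class = "ingredient_classification"
  )
}

#' @rdname classify_ingredients
#' @export
classify_dairy_first <- function(tokens, lexicons = default_lexicons()) {
  tokens <- as_ingredient_list(tokens)
  lexicons <- compile_lexicons(lexicons)
  if (length(tokens) == 0) return(FALSE)
  !is.na(match_dairy(tokens[[1]]$name, lexicons))
}

#' @rdname classify_ingredients
#' @export
classify_fruit_first <- function(tokens, lexicons = default_lexicons()) {
  tokens <- as_ingredient_list(tokens)
  lexicons <- compile_lexicons(lexicons)
  if (length(tokens) == 0) return(FALSE)
  if (!is.na(match_fruit(tokens[[1]]$name, lexicons))) return(TRUE)
  length(tokens) >= 2 &&
    contains_term(token_word_list(tokens[[1]]$name), "water") &&
    !is.na(match_fruit(tokens[[2]]$name, lexicons))
}

#' @rdname classify_ingredients
#' @export
detect_fvn <- function(tokens, lexicons = default_lexicons(),
                       wweia_code = NULL) {
  classify_ingredients(tokens, lexicons, wweia_code)$fvn_present
}

#' @export
print.ingredient_classification <- function(x, ...) {
  cat("<ingredient_classification>\n")
  cat("  dairy_first:          ", x$dairy_first, "\n")
  cat("  fruit_first:          ", x$fruit_first, "\n")
  cat("  fruit_or_dairy_first: ", x$fruit_or_dairy_first, "\n")
  cat("  fvn_present:          ", x$fvn_present, "\n")
  if (nrow(x$matched_terms) > 0) {
    cat("  matched terms:\n")
    print(as.data.frame(x$matched_terms), row.names = FALSE)
  }
  invisible(x)
}

as_ingredient_list <- function(x) {
  if (inherits(x, "ingredient_list")) return(x)
  if (is.character(x) && length(x) == 1) return(parse_ingredients(x))
  if (is.list(x)) return(structure(x, class = "ingredient_list"))
  stop("expected an ingredient_list or a label string", call. = FALSE)
}

chip_wweia_codes <- function() c(5002L, 5004L, 5008L)

#' Classify every product in a table
#'
#' Applies [classify_ingredients()] to the `ingredient_text` of each row,
#' passing the product's `wweia_code` for the chips exclusion.
#'
#' @param products Product tibble with `product_id`, `ingredient_text` and
#'   (optionally) `wweia_code` columns.
#' @param lexicons Term lists from [default_lexicons()] (loaded once for the
#'   whole table).
#' @return Tibble: `product_id`, `dairy_first`, `fruit_first`,
#'   `fruit_or_dairy_first`, `fvn_present`.
#' @examples
#' prods <- generate_dataset(default_config(), seed = 1)
#' table(classify_products(prods)$fruit_or_dairy_first)
#' @export
classify_products <- function(products, lexicons = default_lexicons()) {
  products <- tibble::as_tibble(products)
  stopifnot(all(c("product_id", "ingredient_text") %in% names(products)))
  codes <- if ("wweia_code" %in% names(products)) products$wweia_code else
    rep(NA_integer_, nrow(products))
  lexicons <- compile_lexicons(lexicons)
  flags <- matrix(FALSE, nrow = nrow(products), ncol = 3)
  for (i in seq_len(nrow(products))) {
    flags[i, ] <- classify_flags(parse_ingredients(products$ingredient_text[i]),
                                 lexicons, codes[i])
  }
  tibble::tibble(
    product_id = products$product_id,
    dairy_first = flags[, 1],
    fruit_first = flags[, 2],
    fruit_or_dairy_first = flags[, 1] | flags[, 2],
    fvn_present = flags[, 3]
  )
}

# Flag-only classification (dairy_first, fruit_first, fvn) on compiled
# lexica; used by the bulk path where matched-term bookkeeping is not needed.
classify_flags <- function(tokens, clex, wweia_code = NA) {
  dairy <- FALSE
  fruit <- FALSE
  if (length(tokens) >= 1) {
    t1 <- tokens[[1]]$name
    dairy <- !is.na(match_dairy(t1, clex))
    fruit <- !is.na(match_fruit(t1, clex))
    if (!fruit && length(tokens) >= 2 &&
        "water" %in% token_word_list(t1)) {
      fruit <- !is.na(match_fruit(tokens[[2]]$name, clex))
    }
  }
  chip <- !is.na(wweia_code) && wweia_code %in% chip_wweia_codes()
  fvn <- FALSE
  walk <- function(toks) {
    for (tok in toks) {
      if (fvn) return(invisible(NULL))
      if (!is.na(match_fruit(tok$name, clex)) ||
          !is.na(match_vegetable(tok$name, clex, chip_product = chip)) ||
          !is.na(match_nut_seed(tok$name, clex))) {
        fvn <<- TRUE
        return(invisible(NULL))
      }
      walk(tok$sub_ingredients)
    }
  }
  walk(tokens)
  c(dairy, fruit, fvn)
}
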