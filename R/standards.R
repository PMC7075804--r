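#' Reference standards for NRFn.3 scoring
#'
#' An `nrf_standards` object holds the reference amounts that define an
#' NRFn.3 variant: daily values (DV) for the qualifying nutrients to
#' encourage, maximum recommended values (MRV) for the three nutrients to
#' limit, a separate MRV used to report total sugar, and the truncation cap
#' applied to qualifying %DVs.
#'
#' The shipped default is the NRF8.3 configuration: eight qualifying
#' nutrients — protein (50 g), fiber (28 g), vitamin A (800 µg), vitamin C
#' (80 mg), vitamin D (15 µg), calcium (1000 mg), iron (18 mg), potassium
#' (4700 mg) — and three nutrients to limit — added sugar (50 g), saturated
#' fat (20 g), sodium (2400 mg). A single set of US-based reference amounts
#' is applied regardless of the product's market. Total sugar is reported
#' against a 50 g reference but never enters the LIM sub-score, because total
#' sugars include those naturally present in fruit and dairy.
#'
#' The qualifying set is configurable between 1 and 15 nutrients (published
#' NRF variants range from NRF6.3 to NRF15.3); the limiting set is always the
#' same three nutrients of public health concern.
#'
#' @param qualifying Tibble or data frame with columns `nutrient`, `dv`
#'   (reference daily value, strictly positive) and `unit`. Row order is the
#'   reporting order.
#' @param limiting Tibble with columns `nutrient`, `mrv` (strictly positive)
#'   and `unit`; exactly three rows.
#' @param total_sugar_mrv Reference amount (g) for the separately reported
#'   total-sugar %MRV.
#' @param cap Truncation ceiling for qualifying %DVs (default 100), so an
#'   excessively high content of a single nutrient cannot dominate the score.
#'
#' @return An object of class `nrf_standards`.
#' @examples
#' std <- nrf_standards()
#' std$qualifying
#' @export
nrf_standards <- function(qualifying = default_qualifying_nutrients(),
                          limiting = default_limiting_nutrients(),
                          total_sugar_mrv = 50,
                          cap = 100) {
  qualifying <- tibble::as_tibble(qualifying)
  limiting <- tibble::as_tibble(limiting)

  stopifnot(
    all(c("nutrient", "dv", "unit") %in% names(qualifying)),
    all(c("nutrient", "mrv", "unit") %in% names(limiting))
  )
  if (nrow(qualifying) < 1 || nrow(qualifying) > 15) {
    stop("`qualifying` must contain between 1 and 15 nutrients, got ",
         nrow(qualifying), call. = FALSE)
  }
  if (nrow(limiting) != 3) {
    stop("`limiting` must contain exactly 3 nutrients (the LIM sub-score is ",
         "always based on three nutrients to limit)", call. = FALSE)
  }
  if (anyDuplicated(qualifying$nutrient) || anyDuplicated(limiting$nutrient)) {
    stop("nutrient names must be unique within each set", call. = FALSE)
  }
  if (any(qualifying$dv <= 0) || any(limiting$mrv <= 0)) {
    stop("all DV and MRV reference amounts must be strictly positive",
         call. = FALSE)
  }
  if (!is.numeric(total_sugar_mrv) || total_sugar_mrv <= 0) {
    stop("`total_sugar_mrv` must be strictly positive", call. = FALSE)
  }
  if (!is.numeric(cap) || cap <= 0) {
    stop("`cap` must be strictly positive", call. = FALSE)
  }

  structure(
    list(
      qualifying = qualifying,
      limiting = limiting,
      total_sugar_mrv = as.numeric(total_sugar_mrv),
      cap = as.numeric(cap)
    ),
    class = "nrf_standards"
  )
}

#' @export
print.nrf_standards <- function(x, ...) {
  cat(sprintf("<nrf_standards> NRF%d.3 (cap = %g)\n",
              nrow(x$qualifying), x$cap))
  cat("Qualifying nutrients (DV):\n")
  print(as.data.frame(x$qualifying), row.names = FALSE)
  cat("Nutrients to limit (MRV):\n")
  print(as.data.frame(x$limiting), row.names = FALSE)
  cat(sprintf("Total sugar reference: %g g (reported, not in LIM)\n",
              x$total_sugar_mrv))
  invisible(x)
}

#' Default NRF8.3 qualifying-nutrient daily values
#'
#' @return Tibble with columns `nutrient`, `dv`, `unit`.
#' @export
default_qualifying_nutrients <- function() {
  tibble::tribble(
    ~nutrient,    ~dv,   ~unit,
    "protein",    50,    "g",
    "fiber",      28,    "g",
    "vitamin_a",  800,   "ug",
    "vitamin_c",  80,    "mg",
    "vitamin_d",  15,    "ug",
    "calcium",    1000,  "mg",
    "iron",       18,    "mg",
    "potassium",  4700,  "mg"
  )
}

#' Default maximum recommended values for the LIM nutrients
#'
#' @return Tibble with columns `nutrient`, `mrv`, `unit`.
#' @export
default_limiting_nutrients <- function() {
  tibble::tribble(
    ~nutrient,     ~mrv,  ~unit,
    "satfat",      20,    "g",
    "added_sugar", 50,    "g",
    "sodium",      2400,  "mg"
  )
}

#' Read or write reference standards as a YAML config file
#'
#' The on-disk format is a small key-value document: `cap`,
#' `total_sugar_mrv`, and per-nutrient entries carrying the reference amount
#' and unit. The shipped default round-trips exactly.
#'
#' @param path File path.
#' @param standards An [nrf_standards()] object.
#' @return `read_standards()` returns an `nrf_standards` object;
#'   `write_standards()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".yml")
#' write_standards(nrf_standards(), f)
#' read_standards(f)
#' @export
read_standards <- function(path) {
  doc <- yaml::read_yaml(path)
  parse_set <- function(entries, value_field) {
    tibble::tibble(
      nutrient = names(entries),
      value = unname(vapply(entries, function(e) as.numeric(e[[value_field]]), 0)),
      unit = unname(vapply(entries, function(e) as.character(e[["unit"]]), ""))
    )
  }
  q <- parse_set(doc$qualifying, "dv")
  names(q)[2] <- "dv"
  l <- parse_set(doc$limiting, "mrv")
  names(l)[2] <- "mrv"
  nrf_standards(
    qualifying = q,
    limiting = l,
    total_sugar_mrv = doc$total_sugar_mrv,
    cap = doc$cap
  )
}

#' @rdname read_standards
#' @export
write_standards <- function(standards, path) {
  stopifnot(inherits(standards, "nrf_standards"))
  doc <- list(
    cap = standards$cap,
    total_sugar_mrv = standards$total_sugar_mrv,
    qualifying = stats::setNames(
      purrr::map2(standards$qualifying$dv, standards$qualifying$unit,
                  function(dv, unit) list(dv = dv, unit = unit)),
      standards$qualifying$nutrient
    ),
    limiting = stats::setNames(
      purrr::map2(standards$limiting$mrv, standards$limiting$unit,
                  function(mrv, unit) list(mrv = mrv, unit = unit)),
      standards$limiting$nutrient
    )
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

# Column in the product table holding a nutrient's per-100 g amount,
# e.g. "vitamin_a" + "ug" -> "vitamin_a_ug_100g".
nutrient_column <- function(nutrient, unit) {
  paste0(nutrient, "_", unit, "_100g")
}
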