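#' @importFrom rlang .data
#' @importFrom stats rbinom rgeom runif
NULL

#' Age buckets used in JADER demographics
#'
#' The eleven decade labels under which JADER reports patient age, from
#' `"<10"` through `"100s"`.
#'
#' @return Character vector of the 11 bucket labels, youngest first.
#' @export
age_buckets <- function() {
  c("<10", "10s", "20s", "30s", "40s", "50s", "60s", "70s", "80s", "90s", "100s")
}

#' Outcome categories recorded on reaction rows
#'
#' @return Character vector of the six internal outcome codes.
#' @export
outcome_levels <- function() {
  c("recovery", "remission", "no_recovery", "after_effect", "death", "unknown")
}

# display labels for report output
outcome_labels <- function() {
  c(recovery = "Recovery", remission = "Remission", no_recovery = "No recovery",
    after_effect = "After-effect", death = "Death", unknown = "Unknown")
}

#' Round half away from zero
#'
#' Fixed-precision rounding in which a digit of exactly 5 rounds away from
#' zero (so 6.485 -> 6.49 and -0.745 -> -0.75), the convention used for the
#' reported 2-decimal estimates. Base `round()` rounds half to even, which
#' disagrees on exact halves.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Parse a JADER-style date token
#'
#' JADER dates are `YYYYMMDD` strings; partial dates (`YYYYMM`, `YYYY`) are
#' legal in the source but unusable for day-level arithmetic, so they parse
#' to `NA` here. Also accepts ISO `YYYY-MM-DD`.
#'
#' @param x Character vector of date tokens.
#' @return `Date` vector; `NA` where the token is empty, partial or invalid.
#' @export
parse_jader_date <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(as.Date(NA), length(x))
  full <- !is.na(x) & grepl("^[0-9]{8}$", x)
  out[full] <- as.Date(x[full], format = "%Y%m%d")
  iso <- !is.na(x) & grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", x)
  out[iso] <- as.Date(x[iso])
  out
}

format_jader_date <- function(d) {
  ifelse(is.na(d), NA_character_, format(d, "%Y%m%d"))
}

# trimmed, case-folded drug-name comparison key
normalize_drug_name <- function(x) {
  tolower(trimws(as.character(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
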