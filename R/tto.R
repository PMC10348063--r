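# Time-to-onset (TTO): days from the vaccination (target-drug
# administration) date to the first onset of the target event, binned as
# reported for vaccine adverse events, with outcome tallies.

#' Time-to-onset bin labels
#' @return Character vector of the six bins, in display order.
#' @export
tto_bins <- function() {
  c("0 day", "1 day", "2 days", "3-28 days", "28< days", "Unknown")
}

#' Bin a time-to-onset value
#'
#' Day 0 (same day), day 1 and day 2 are individual bins; "3-28 days" is
#' inclusive at both ends; "28< days" starts at day 29; `NA` (missing or
#' unusable dates, or a negative delay) maps to "Unknown". Every
#' non-negative integer and `NA` maps to exactly one bin.
#'
#' @param tto_days Integer vector of day delays (`NA` = unknown).
#' @return Character vector of bin labels.
#' @export
#' @examples
#' bin_tto(c(0, 1, 2, 3, 28, 29, NA))
bin_tto <- function(tto_days) {
  dplyr::case_when(
    is.na(tto_days) ~ "Unknown",
    tto_days == 0 ~ "0 day",
    tto_days == 1 ~ "1 day",
    tto_days == 2 ~ "2 days",
    tto_days <= 28 ~ "3-28 days",
    TRUE ~ "28< days"
  )
}

#' Per-case time to onset for the joint (drug-and-event) cases
#'
#' For every case carrying both the target drug (suspected) and a
#' reaction in the PT set, computes the delay in whole days from the
#' anchor administration date to the earliest onset date among the PT-set
#' reactions. The anchor is the earliest (`"first_dose"`) or latest
#' (`"most_recent_dose"`) parseable administration date of the target
#' drug within the case. The delay is unknown (`NA`) when either date is
#' missing or partial, or when the onset precedes the anchor (counted and
#' surfaced as a negative-TTO warning). The case outcome is taken from
#' the earliest PT-set reaction row, ties broken by row order.
#'
#' @param cases A `jader_cases` object.
#' @param target_drug Drug name.
#' @param pt_set A [pt_set].
#' @param anchor `"first_dose"` (default) or `"most_recent_dose"`.
#' @return Tibble with one row per joint case: `case_id`, `tto_days`
#'   (integer or `NA`), `bin`, `outcome`. The number of negative delays
#'   is attached as `attr(, "n_negative_tto")`.
#' @export
compute_tto <- function(cases, target_drug, pt_set,
                        anchor = c("first_dose", "most_recent_dose")) {
  stopifnot(inherits(cases, "jader_cases"), inherits(pt_set, "pt_set"))
  anchor <- match.arg(anchor)
  joint <- case_has_drug(cases, target_drug) & case_has_event(cases, pt_set)
  ids <- cases$demo$case_id[joint]

  key <- normalize_drug_name(target_drug)
  drows <- cases$drug[cases$drug$case_id %in% ids &
                        cases$drug$role %in% "suspected" &
                        normalize_drug_name(cases$drug$drug_name) == key,
                      , drop = FALSE]
  drows$admin <- parse_jader_date(drows$admin_date)
  anchors <- drows |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(anchor_date = {
      a <- .data$admin[!is.na(.data$admin)]
      if (length(a) == 0L) {
        as.Date(NA)
      } else if (anchor == "first_dose") {
        min(a)
      } else {
        max(a)
      }
    }, .groups = "drop")

  rrows <- cases$reac[cases$reac$case_id %in% ids &
                        cases$reac$pt_code %in% pt_set$codes, , drop = FALSE]
  rrows$onset <- parse_jader_date(rrows$onset_date)
  rrows$.row <- seq_len(nrow(rrows))
  firsts <- rrows |>
    dplyr::arrange(.data$case_id, .data$onset, .data$.row) |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(
      onset_date = if (all(is.na(.data$onset))) as.Date(NA) else
        min(.data$onset, na.rm = TRUE),
      outcome = dplyr::first(.data$outcome),
      .groups = "drop"
    )

  out <- tibble::tibble(case_id = ids) |>
    dplyr::left_join(anchors, by = "case_id") |>
    dplyr::left_join(firsts, by = "case_id") |>
    dplyr::mutate(tto_days = as.integer(.data$onset_date - .data$anchor_date))
  n_neg <- sum(!is.na(out$tto_days) & out$tto_days < 0)
  if (n_neg > 0) {
    warning(n_neg, " case(s) with onset before the anchor administration ",
            "date: classified as unknown", call. = FALSE)
    out$tto_days[!is.na(out$tto_days) & out$tto_days < 0] <- NA_integer_
  }
  out <- dplyr::mutate(out, bin = bin_tto(.data$tto_days))
  out <- out[, c("case_id", "tto_days", "bin", "outcome")]
  attr(out, "n_negative_tto") <- n_neg
  out
}

#' Time-to-onset and outcome table for the joint cases
#'
#' Tallies the joint (target drug and target event) cases per TTO bin and
#' per outcome category; both tallies sum to the joint case count `n11`.
#'
#' @inheritParams compute_tto
#' @return A `tto_table`: list with `bins` (named integer vector over
#'   [tto_bins()]), `outcomes` (named integer vector over the display
#'   outcome labels), `n11`, and `n_known_tto` (= `n11` minus the Unknown
#'   bin).
#' @export
build_tto_table <- function(cases, target_drug, pt_set,
                            anchor = c("first_dose", "most_recent_dose")) {
  per_case <- compute_tto(cases, target_drug, pt_set, anchor = anchor)
  bins <- table(factor(per_case$bin, levels = tto_bins()))
  lab <- outcome_labels()
  outc <- table(factor(unname(lab[per_case$outcome]), levels = unname(lab)))
  structure(
    list(bins = stats::setNames(as.integer(bins), names(bins)),
         outcomes = stats::setNames(as.integer(outc), names(outc)),
         n11 = nrow(per_case),
         n_known_tto = nrow(per_case) - as.integer(bins[["Unknown"]])),
    class = "tto_table"
  )
}

#' @export
print.tto_table <- function(x, ...) {
  cat("<tto_table> ", x$n11, " joint cases (", x$n_known_tto,
      " with known time to onset)\n", sep = "")
  print(data.frame(`Time-to-onset` = names(x$bins), N = unname(x$bins),
                   Outcomes = names(x$outcomes), N. = unname(x$outcomes),
                   check.names = FALSE), row.names = FALSE)
  invisible(x)
}
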