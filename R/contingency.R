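# Case-level 2x2 contingency tables: target drug vs all other drugs
# crossed with a target PT event set vs all other adverse events. The
# counting unit is the case, so a case with several qualifying reaction
# rows or several target-drug rows still contributes exactly once.

#' Construct a 2x2 contingency table
#'
#' Cells follow the drug-by-event layout: `n11` target drug and target
#' event, `n10` target drug only, `n01` target event only, `n00` neither.
#' Margins are derived: `n1plus = n11 + n10`, `nplus1 = n11 + n01`, and so
#' on; `nplusplus` is the case total.
#'
#' @param n11,n10,n01,n00 Non-negative cell counts.
#' @param target_drug,event_set Optional labels carried for reporting.
#' @return A `contingency_table` object.
#' @export
#' @examples
#' contingency_table(30, 21425, 146, 676284)
contingency_table <- function(n11, n10, n01, n00,
                              target_drug = NA_character_,
                              event_set = NA_character_) {
  cells <- c(n11 = n11, n10 = n10, n01 = n01, n00 = n00)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop("contingency cells must be non-negative numbers", call. = FALSE)
  }
  structure(
    list(n11 = n11, n10 = n10, n01 = n01, n00 = n00,
         n1plus = n11 + n10, n0plus = n01 + n00,
         nplus1 = n11 + n01, nplus0 = n10 + n00,
         nplusplus = n11 + n10 + n01 + n00,
         target_drug = target_drug, event_set = event_set,
         corrected = FALSE),
    class = "contingency_table"
  )
}

#' Construct a 2x2 table from its margins
#'
#' Builds the table from the joint cell and the marginal totals as they
#' are typically reported: `n10 = n1plus - n11`, `n01 = nplus1 - n11`,
#' `n00 = ntotal - n1plus - n01`.
#'
#' @param n11 Joint cell (target drug and target event).
#' @param n1plus Target-drug row total.
#' @param nplus1 Target-event column total.
#' @param ntotal Grand total of cases.
#' @inheritParams contingency_table
#' @return A `contingency_table` object.
#' @export
#' @examples
#' contingency_from_margins(30, 21455, 176, 697885)
contingency_from_margins <- function(n11, n1plus, nplus1, ntotal,
                                     target_drug = NA_character_,
                                     event_set = NA_character_) {
  if (n11 > min(n1plus, nplus1) || n1plus + nplus1 - n11 > ntotal) {
    stop("infeasible margins for a 2x2 table", call. = FALSE)
  }
  contingency_table(n11, n1plus - n11, nplus1 - n11,
                    ntotal - n1plus - (nplus1 - n11),
                    target_drug = target_drug, event_set = event_set)
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$n11, x$n10, x$n1plus, x$n01, x$n00, x$n0plus,
                x$nplus1, x$nplus0, x$nplusplus),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("target drug", "other drugs", "total"),
                              c("target AE", "other AEs", "total")))
  cat("<contingency_table>",
      if (!is.na(x$target_drug)) paste0(" drug=", x$target_drug),
      if (!is.na(x$event_set)) paste0(" event=", x$event_set),
      if (isTRUE(x$corrected)) " (continuity-corrected)", "\n", sep = "")
  print(m)
  invisible(x)
}

#' Build the 2x2 table for one drug and one event set
#'
#' Each case is counted exactly once: in `n11` if the target drug is among
#' its suspected drugs and any reaction belongs to the PT set, in `n10`
#' or `n01` if only one of the two holds, and in `n00` otherwise. "Other
#' drugs" therefore includes cases with no suspected drug at all. Drug
#' matching is exact on the normalized (trimmed, case-folded) name.
#'
#' @param cases A `jader_cases` object from [link_cases()].
#' @param target_drug Drug name.
#' @param pt_set A [pt_set] defining the target event.
#' @return A `contingency_table`; cells sum to `n_cases(cases)`.
#' @export
build_contingency <- function(cases, target_drug, pt_set) {
  stopifnot(inherits(cases, "jader_cases"))
  if (nrow(cases$demo) == 0L) {
    stop("contingency table undefined for an empty case list", call. = FALSE)
  }
  drug <- case_has_drug(cases, target_drug)
  event <- case_has_event(cases, pt_set)
  contingency_table(
    n11 = sum(drug & event), n10 = sum(drug & !event),
    n01 = sum(!drug & event), n00 = sum(!drug & !event),
    target_drug = target_drug, event_set = pt_set$name
  )
}

strata_counts <- function(demo_subset, label, denom) {
  sex_tab <- table(factor(demo_subset$sex, levels = c("male", "female")))
  age_tab <- table(factor(demo_subset$age_bucket, levels = age_buckets()))
  tibble::tibble(
    population = label,
    stratum_type = c(rep("sex", 2L), rep("age", length(age_buckets()))),
    stratum = c(names(sex_tab), names(age_tab)),
    n = as.integer(c(sex_tab, age_tab)),
    pct = round_half_up(100 * as.integer(c(sex_tab, age_tab)) / max(denom, 1L), 2),
    population_total = denom
  )
}

#' Sex- and age-stratified case counts
#'
#' Tallies cases per sex and per decade age bucket for the four
#' populations of interest: all drugs x all AEs, all drugs x the event
#' set, target drug x all AEs, and target drug x the event set.
#' Percentages are of the population total, rounded half-up to 2
#' decimals, so within each population the sex (and age) percentages sum
#' to 100 up to rounding.
#'
#' @inheritParams build_contingency
#' @return Tidy tibble with columns `population`, `stratum_type`,
#'   `stratum`, `n`, `pct`, `population_total`.
#' @export
build_sex_age_table <- function(cases, target_drug, pt_set) {
  stopifnot(inherits(cases, "jader_cases"))
  drug <- case_has_drug(cases, target_drug)
  event <- case_has_event(cases, pt_set)
  demo <- cases$demo
  dplyr::bind_rows(
    strata_counts(demo, "all drugs / all AEs", nrow(demo)),
    strata_counts(demo[event, , drop = FALSE],
                  paste0("all drugs / ", pt_set$name), sum(event)),
    strata_counts(demo[drug, , drop = FALSE],
                  paste0(target_drug, " / all AEs"), sum(drug)),
    strata_counts(demo[drug & event, , drop = FALSE],
                  paste0(target_drug, " / ", pt_set$name), sum(drug & event))
  )
}
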