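# Synthetic JADER-schema report generator. Two entry points:
#   simulate_reports()     - stochastic generator with known ground truth
#   fixture_from_margins() - deterministic dataset with exact 2x2 margins

# Sex and age frequencies of the full reporting database (case counts per
# stratum over all drugs and all adverse events), used as sampling defaults.
.default_sex_counts <- c(male = 356723, female = 341162)
.default_age_counts <- c(25152, 20318, 25503, 40245, 56683, 88673, 154485,
                         180378, 92752, 13419, 277)

.default_outcome_probs <- c(recovery = 0.10, remission = 0.20, no_recovery = 0.35,
                            after_effect = 0.02, death = 0.03, unknown = 0.30)

default_background_pt_pool <- function(n_pts = 20) {
  tibble::tibble(
    pt_code = sprintf("%08d", 90000000 + seq_len(n_pts)),
    pt_name = sprintf("Background PT %02d", seq_len(n_pts)),
    weight = 1 / seq_len(n_pts)
  )
}

#' Configuration for the synthetic report generator
#'
#' Defines the generative model for a JADER-style dataset with one target
#' drug and one target event. Per case: sex and age are drawn from
#' `sex_probs` / `age_probs`; target-drug exposure is Bernoulli
#' (`p_target_drug`); the target event occurs with odds
#' `baseline_event_odds` for unexposed cases and
#' `baseline_event_odds * true_odds_ratio` for exposed cases, so
#' `true_odds_ratio` is the exact population odds ratio of the implied 2x2
#' table. Every case receives at least one reaction row (a background PT
#' when the target event is absent). Exposed cases carry a vaccination
#' date; target-event rows in exposed cases get an onset date equal to the
#' vaccination date plus a lag drawn from `onset_lag_distribution`.
#'
#' Defaults mirror the observed renal-event analysis of the reporting
#' database: exposure prevalence about 3.1%, baseline event odds 2e-4,
#' odds ratio 6.5, and the database's sex/age frequencies.
#'
#' @param n_cases Number of cases (>= 1).
#' @param p_target_drug Probability a case lists the target drug as a
#'   suspected drug.
#' @param baseline_event_odds Odds of the target event among unexposed
#'   cases.
#' @param true_odds_ratio Multiplicative odds factor for exposed cases
#'   (> 0).
#' @param background_pt_pool Data frame with columns `pt_code`, `pt_name`,
#'   `weight`: the PT codes used for non-target reactions.
#' @param sex_probs Named probabilities over `c("male", "female")`, summing
#'   to 1.
#' @param age_probs Probabilities over the 11 decade buckets of
#'   [age_buckets()], summing to 1.
#' @param onset_lag_distribution Mixture over integer day lags: a list with
#'   `point_days` / `point_probs` (point masses; probs sum to <= 1) and a
#'   geometric tail starting at `tail_start` with success probability
#'   `tail_geom_prob` carrying the remaining mass. The default puts most
#'   mass on lags 0-2 days with a thin tail extending past 28 days.
#' @param p_missing_sex,p_missing_age Probability that sex / age is blanked
#'   in the demo table.
#' @param p_missing_dates Probability that a vaccination or onset date is
#'   blanked.
#' @param p_duplicate_row Probability that a drug or reac row is emitted
#'   twice (exact copy).
#' @param seed Integer RNG seed; the same configuration always yields the
#'   same dataset.
#' @param target_drug,target_pt,target_pt_name Names of the simulated
#'   target drug and target event PT.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_cases,
                       p_target_drug = 0.031,
                       baseline_event_odds = 2e-4,
                       true_odds_ratio = 6.5,
                       background_pt_pool = default_background_pt_pool(),
                       sex_probs = .default_sex_counts / sum(.default_sex_counts),
                       age_probs = .default_age_counts / sum(.default_age_counts),
                       onset_lag_distribution = list(
                         point_days = c(0, 1, 2),
                         point_probs = c(0.125, 0.3125, 0.25),
                         tail_start = 3,
                         tail_geom_prob = 0.08
                       ),
                       p_missing_sex = 0.02,
                       p_missing_age = 0.02,
                       p_missing_dates = 0.10,
                       p_duplicate_row = 0.01,
                       seed = 1L,
                       target_drug = "COVID-19 mRNA vaccine",
                       target_pt = "10021263",
                       target_pt_name = "IgA nephropathy") {
  cfg <- list(
    n_cases = n_cases, p_target_drug = p_target_drug,
    baseline_event_odds = baseline_event_odds,
    true_odds_ratio = true_odds_ratio,
    background_pt_pool = tibble::as_tibble(background_pt_pool),
    sex_probs = sex_probs, age_probs = age_probs,
    onset_lag_distribution = onset_lag_distribution,
    p_missing_sex = p_missing_sex, p_missing_age = p_missing_age,
    p_missing_dates = p_missing_dates, p_duplicate_row = p_duplicate_row,
    seed = as.integer(seed), target_drug = target_drug,
    target_pt = target_pt, target_pt_name = target_pt_name
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk_prob <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("invalid sim_config: `", field, "` must be a probability in [0, 1]",
           call. = FALSE)
    }
  }
  if (!is.numeric(cfg$n_cases) || length(cfg$n_cases) != 1L ||
      is.na(cfg$n_cases) || cfg$n_cases < 1 || cfg$n_cases != floor(cfg$n_cases)) {
    stop("invalid sim_config: `n_cases` must be a positive integer", call. = FALSE)
  }
  for (f in c("p_target_drug", "p_missing_sex", "p_missing_age",
              "p_missing_dates", "p_duplicate_row")) chk_prob(f)
  if (!is.numeric(cfg$true_odds_ratio) || cfg$true_odds_ratio <= 0) {
    stop("invalid sim_config: `true_odds_ratio` must be > 0", call. = FALSE)
  }
  if (!is.numeric(cfg$baseline_event_odds) || cfg$baseline_event_odds <= 0) {
    stop("invalid sim_config: `baseline_event_odds` must be > 0", call. = FALSE)
  }
  if (any(cfg$sex_probs < 0) || abs(sum(cfg$sex_probs) - 1) > 1e-9) {
    stop("invalid sim_config: `sex_probs` must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (length(cfg$age_probs) != length(age_buckets()) ||
      any(cfg$age_probs < 0) || abs(sum(cfg$age_probs) - 1) > 1e-9) {
    stop("invalid sim_config: `age_probs` must give one non-negative weight per ",
         "age bucket and sum to 1", call. = FALSE)
  }
  d <- cfg$onset_lag_distribution
  if (!is.list(d) || is.null(d$point_days) || is.null(d$point_probs) ||
      length(d$point_days) != length(d$point_probs) ||
      any(d$point_probs < 0) || sum(d$point_probs) > 1 + 1e-9 ||
      !is.numeric(d$tail_geom_prob) || d$tail_geom_prob <= 0 || d$tail_geom_prob > 1) {
    stop("invalid sim_config: `onset_lag_distribution` must have matching ",
         "point_days/point_probs (probs summing to <= 1) and tail_geom_prob in (0, 1]",
         call. = FALSE)
  }
  pool <- cfg$background_pt_pool
  if (!all(c("pt_code", "pt_name", "weight") %in% names(pool)) || nrow(pool) == 0) {
    stop("invalid sim_config: `background_pt_pool` needs columns ",
         "pt_code, pt_name, weight and at least one row", call. = FALSE)
  }
  invisible(cfg)
}

# draw n integer onset lags from the point-mass + geometric-tail mixture
r_onset_lag <- function(n, dist) {
  p_point <- sum(dist$point_probs)
  u <- runif(n)
  lag <- integer(n)
  from_tail <- u >= p_point
  if (any(!from_tail)) {
    lag[!from_tail] <- sample(dist$point_days, sum(!from_tail), replace = TRUE,
                              prob = dist$point_probs)
  }
  if (any(from_tail)) {
    lag[from_tail] <- dist$tail_start + rgeom(sum(from_tail), dist$tail_geom_prob)
  }
  lag
}

#' Simulate a JADER-style dataset with known ground truth
#'
#' Draws a dataset under the generative model described in [sim_config()]
#' and records the realized 2x2 counts (before any missingness blanking or
#' duplicate injection) in `$truth`, together with the number of injected
#' duplicate rows, so downstream exclusion and counting logic can be
#' checked against exact bookkeeping.
#'
#' @param config A [sim_config()].
#' @return A `jader_sim` object: list with tibbles `demo`, `drug`, `reac`
#'   in the ingest schema, `truth` (config, realized counts, injected
#'   duplicate counts) and `target` (target drug name and [pt_set]).
#' @export
#' @examples
#' ds <- simulate_reports(sim_config(n_cases = 500, seed = 42))
#' ds$truth$counts
simulate_reports <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_cases

  case_id <- sprintf("C%08d", seq_len(n))
  sex <- sample(names(config$sex_probs), n, replace = TRUE, prob = config$sex_probs)
  age <- sample(age_buckets(), n, replace = TRUE, prob = config$age_probs)

  exposed <- runif(n) < config$p_target_drug
  odds <- config$baseline_event_odds * ifelse(exposed, config$true_odds_ratio, 1)
  event <- runif(n) < odds / (1 + odds)

  counts <- c(
    n11 = sum(exposed & event), n10 = sum(exposed & !event),
    n01 = sum(!exposed & event), n00 = sum(!exposed & !event)
  )

  # demo table (sex/age blanked per missingness probabilities)
  demo <- tibble::tibble(
    case_id = case_id,
    sex = ifelse(runif(n) < config$p_missing_sex, NA_character_, sex),
    age_bucket = ifelse(runif(n) < config$p_missing_age, NA_character_, age)
  )

  # drug table: exposed cases get the target drug (suspected, dated);
  # unexposed cases get one background drug with a mixed role
  vax_base <- as.Date("2021-02-17")
  admin_target <- vax_base + sample.int(400L, n, replace = TRUE) - 1L
  other_base <- as.Date("2004-04-01")
  admin_other <- other_base + sample.int(6000L, n, replace = TRUE) - 1L
  drug <- tibble::tibble(
    case_id = case_id,
    drug_name = ifelse(exposed, config$target_drug,
                       sprintf("Background drug %02d",
                               sample.int(20L, n, replace = TRUE))),
    role = ifelse(exposed, "suspected",
                  sample(c("suspected", "concomitant", "interaction"), n,
                         replace = TRUE, prob = c(0.70, 0.25, 0.05))),
    admin_date = format_jader_date(dplyr::if_else(exposed, admin_target, admin_other))
  )
  drug$admin_date[runif(n) < config$p_missing_dates] <- NA_character_

  # reac table: one row per case; target PT where the event occurred
  pool <- config$background_pt_pool
  bg_idx <- sample.int(nrow(pool), n, replace = TRUE, prob = pool$weight)
  lag <- r_onset_lag(n, config$onset_lag_distribution)
  onset <- dplyr::if_else(
    exposed & event,
    admin_target + lag,               # anchored to the vaccination date
    other_base + sample.int(6000L, n, replace = TRUE) - 1L
  )
  reac <- tibble::tibble(
    case_id = case_id,
    pt_code = ifelse(event, config$target_pt, pool$pt_code[bg_idx]),
    pt_name = ifelse(event, config$target_pt_name, pool$pt_name[bg_idx]),
    onset_date = format_jader_date(onset),
    outcome = sample(names(.default_outcome_probs), n, replace = TRUE,
                     prob = .default_outcome_probs)
  )
  reac$onset_date[runif(n) < config$p_missing_dates] <- NA_character_

  # inject exact duplicate rows
  dup_drug <- which(runif(nrow(drug)) < config$p_duplicate_row)
  dup_reac <- which(runif(nrow(reac)) < config$p_duplicate_row)
  if (length(dup_drug)) drug <- dplyr::bind_rows(drug, drug[dup_drug, ])
  if (length(dup_reac)) reac <- dplyr::bind_rows(reac, reac[dup_reac, ])

  structure(
    list(
      demo = demo, drug = drug, reac = reac,
      truth = list(config = config, counts = counts,
                   n_duplicates_drug = length(dup_drug),
                   n_duplicates_reac = length(dup_reac)),
      target = list(drug = config$target_drug,
                    pt_set = pt_set(config$target_pt_name, config$target_pt))
    ),
    class = "jader_sim"
  )
}

#' @export
print.jader_sim <- function(x, ...) {
  cat("<jader_sim> ", nrow(x$demo), " cases; realized 2x2: ",
      paste(names(x$truth$counts), x$truth$counts, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Deterministic fixture with exact contingency margins
#'
#' Constructs a clean dataset (no missingness, no duplicates) of exactly
#' `ntotal` cases whose case-level recount for the target drug and target
#' event gives exactly the requested 2x2 margins: `n11` joint cases,
#' `n1plus` target-drug cases, `nplus1` target-event cases. Every case has
#' one suspected drug row and one reaction row; joint (n11) cases carry a
#' vaccination date and an onset date offset by a lag, so time-to-onset is
#' computable for all of them (an `NA` lag blanks the onset date, putting
#' that case in the "Unknown" bin).
#'
#' @param n11 Cases with both the target drug and the target event.
#' @param n1plus Total target-drug cases (>= n11).
#' @param nplus1 Total target-event cases (>= n11).
#' @param ntotal Total cases; must be >= `n1plus + nplus1 - n11`.
#' @param seed Accepted for interface symmetry with [simulate_reports()];
#'   the construction is deterministic.
#' @param target_drug,target_pt,target_pt_name Target drug and PT labels.
#' @param n11_lags Optional integer vector (length `n11`, `NA` allowed) of
#'   onset lags in days for the joint cases; default cycles 0, 1, 2, 5, 30.
#' @param n11_outcomes Optional character vector (length `n11`) of outcome
#'   codes for the joint cases; default cycles [outcome_levels()].
#' @param extra_events Optional list of additional event blocks, each a
#'   list with `pt_code`, `pt_name`, `n11`, `nplus1`, placed in disjoint
#'   case blocks so one fixture can reproduce margins for several PT sets
#'   simultaneously.
#' @return A `jader_sim` object (see [simulate_reports()]).
#' @export
#' @examples
#' fx <- fixture_from_margins(5, 20, 8, 100)
#' fx$truth$counts
fixture_from_margins <- function(n11, n1plus, nplus1, ntotal, seed = 1L,
                                 target_drug = "COVID-19 mRNA vaccine",
                                 target_pt = "10021263",
                                 target_pt_name = "IgA nephropathy",
                                 n11_lags = NULL, n11_outcomes = NULL,
                                 extra_events = NULL) {
  if (ntotal < 1) stop("infeasible margins: ntotal >= 1 violated", call. = FALSE)
  if (n11 > min(n1plus, nplus1)) {
    stop("infeasible margins: n11 <= min(n1plus, nplus1) violated", call. = FALSE)
  }
  if (n1plus + nplus1 - n11 > ntotal) {
    stop("infeasible margins: n1plus + nplus1 - n11 <= ntotal violated",
         call. = FALSE)
  }
  extra_n11 <- sum(vapply(extra_events, function(e) e$n11, numeric(1)))
  extra_n01 <- sum(vapply(extra_events, function(e) e$nplus1 - e$n11, numeric(1)))
  if (n11 + extra_n11 > n1plus) {
    stop("infeasible margins: event blocks exceed n1plus target-drug cases",
         call. = FALSE)
  }
  if ((nplus1 - n11) + extra_n01 > ntotal - n1plus) {
    stop("infeasible margins: event blocks exceed the non-target-drug cases",
         call. = FALSE)
  }

  case_id <- sprintf("C%08d", seq_len(ntotal))
  demo <- tibble::tibble(
    case_id = case_id,
    sex = rep_len(c("male", "female"), ntotal),
    age_bucket = rep_len(age_buckets(), ntotal)
  )

  vax_date <- "20210601"
  drug <- tibble::tibble(
    case_id = case_id,
    drug_name = c(rep(target_drug, n1plus), rep("Background drug", ntotal - n1plus)),
    role = "suspected",
    admin_date = c(rep(vax_date, n1plus), rep("20150101", ntotal - n1plus))
  )

  # reaction PT assignment in disjoint blocks:
  #   drug block  [1 .. n1plus]      : n11 target-event, extra-event blocks, rest background
  #   other block [n1plus+1..ntotal] : (nplus1-n11) target-event, extra blocks, rest background
  pt_code <- rep("90000001", ntotal)
  pt_name <- rep("Background PT 01", ntotal)
  onset <- rep("20150102", ntotal)
  outcome <- rep_len(outcome_levels(), ntotal)

  pos <- 0L
  if (n11 > 0) {
    idx <- seq_len(n11)
    pt_code[idx] <- target_pt
    pt_name[idx] <- target_pt_name
    lags <- n11_lags %||% rep_len(c(0L, 1L, 2L, 5L, 30L), n11)
    stopifnot(length(lags) == n11)
    onset[idx] <- ifelse(is.na(lags), NA_character_,
                         format_jader_date(as.Date(vax_date, "%Y%m%d") +
                                             as.integer(lags)))
    if (!is.null(n11_outcomes)) {
      stopifnot(length(n11_outcomes) == n11,
                all(n11_outcomes %in% outcome_levels()))
      outcome[idx] <- n11_outcomes
    }
    pos <- n11
  }
  for (e in extra_events %||% list()) {
    if (e$n11 > 0) {
      idx <- pos + seq_len(e$n11)
      pt_code[idx] <- e$pt_code
      pt_name[idx] <- e$pt_name
      onset[idx] <- format_jader_date(as.Date(vax_date, "%Y%m%d") + 7L)
      pos <- pos + e$n11
    }
  }
  pos <- n1plus
  if (nplus1 - n11 > 0) {
    idx <- pos + seq_len(nplus1 - n11)
    pt_code[idx] <- target_pt
    pt_name[idx] <- target_pt_name
    onset[idx] <- "20180101"
    pos <- pos + (nplus1 - n11)
  }
  for (e in extra_events %||% list()) {
    k <- e$nplus1 - e$n11
    if (k > 0) {
      idx <- pos + seq_len(k)
      pt_code[idx] <- e$pt_code
      pt_name[idx] <- e$pt_name
      onset[idx] <- "20180101"
      pos <- pos + k
    }
  }

  reac <- tibble::tibble(case_id = case_id, pt_code = pt_code, pt_name = pt_name,
                         onset_date = onset, outcome = outcome)
  counts <- c(n11 = n11, n10 = n1plus - n11, n01 = nplus1 - n11,
              n00 = ntotal - n1plus - (nplus1 - n11))
  structure(
    list(
      demo = demo, drug = drug, reac = reac,
      truth = list(config = list(margins = c(n11 = n11, n1plus = n1plus,
                                             nplus1 = nplus1, ntotal = ntotal),
                                 seed = as.integer(seed)),
                   counts = counts, n_duplicates_drug = 0L, n_duplicates_reac = 0L),
      target = list(drug = target_drug, pt_set = pt_set(target_pt_name, target_pt))
    ),
    class = "jader_sim"
  )
}

#' Write a synthetic dataset as delimited tables
#'
#' Writes `demo.csv`, `drug.csv` and `reac.csv` (UTF-8, header row, missing
#' values as empty fields) in the schema consumed by [read_demo()],
#' [read_drug()] and [read_reac()], so a written dataset round-trips
#' losslessly through the readers.
#'
#' @param dataset A `jader_sim` object.
#' @param directory Output directory (created if absent).
#' @param delim Field delimiter (default comma).
#' @return Named character vector of the three file paths.
#' @export
write_tables <- function(dataset, directory, delim = ",") {
  stopifnot(inherits(dataset, "jader_sim"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", directory, call. = FALSE)
  }
  paths <- c(demo = file.path(directory, "demo.csv"),
             drug = file.path(directory, "drug.csv"),
             reac = file.path(directory, "reac.csv"))
  readr::write_delim(dataset$demo, paths[["demo"]], delim = delim, na = "")
  readr::write_delim(dataset$drug, paths[["drug"]], delim = delim, na = "")
  readr::write_delim(dataset$reac, paths[["reac"]], delim = delim, na = "")
  paths
}
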