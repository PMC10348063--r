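# Disproportionality statistics on the case-level 2x2 table:
#   - reporting odds ratio (ROR) with the Woolf log-normal 95% CI
#   - BCPNN information component (IC) with a moment-based 95% interval
# and the dual signal criterion (lower ROR bound > 1 AND lower IC bound > 0).

#' Reporting odds ratio with Woolf 95% confidence interval
#'
#' The ROR is the cross-product ratio `(n11 * n00) / (n10 * n01)`. Its
#' log-scale standard error is `sqrt(1/n11 + 1/n10 + 1/n01 + 1/n00)` and
#' the 95% interval is `exp(log(ror) +/- 1.96 * se)` (Woolf). With a zero
#' cell the estimate is undefined; enable `correction` to apply the
#' Haldane-Anscombe +0.5 first.
#'
#' @param table A `contingency_table`.
#' @param correction Apply [apply_continuity_correction()] when a cell is
#'   zero (default `FALSE`: a zero cell is an error).
#' @param conf_z Normal quantile for the interval (default 1.96).
#' @return A `ror_result`: list with `ror`, `ci_low`, `ci_high`, `log_se`,
#'   `corrected`.
#' @export
#' @examples
#' compute_ror(contingency_from_margins(30, 21455, 176, 697885))
compute_ror <- function(table, correction = FALSE, conf_z = 1.96) {
  stopifnot(inherits(table, "contingency_table"))
  cells <- c(n11 = table$n11, n10 = table$n10, n01 = table$n01, n00 = table$n00)
  if (any(cells == 0)) {
    if (!correction) {
      stop("reporting odds ratio undefined: zero cell(s) ",
           paste(names(cells)[cells == 0], collapse = ", "),
           " (enable `correction` for the Haldane-Anscombe +0.5)",
           call. = FALSE)
    }
    table <- apply_continuity_correction(table)
    cells <- c(n11 = table$n11, n10 = table$n10, n01 = table$n01, n00 = table$n00)
  }
  ror <- (cells[["n11"]] * cells[["n00"]]) / (cells[["n10"]] * cells[["n01"]])
  log_se <- sqrt(sum(1 / cells))
  structure(
    list(ror = ror,
         ci_low = exp(log(ror) - conf_z * log_se),
         ci_high = exp(log(ror) + conf_z * log_se),
         log_se = log_se,
         corrected = isTRUE(table$corrected)),
    class = "ror_result"
  )
}

#' @export
print.ror_result <- function(x, ...) {
  cat(sprintf("ROR %.2f [95%% CI %.2f-%.2f]%s\n",
              round_half_up(x$ror), round_half_up(x$ci_low),
              round_half_up(x$ci_high),
              if (x$corrected) " (continuity-corrected)" else ""))
  invisible(x)
}

#' BCPNN priors for the information component
#'
#' Pseudo-count priors of the Bayesian confidence propagation neural
#' network estimator: `alpha1`/`beta1` on the drug and event margins with
#' totals `alpha`/`beta`, and `gamma11` on the joint cell. The joint prior
#' total `gamma` is data-dependent, chosen so the prior expectation of the
#' IC is zero:
#' `gamma = gamma11 * (N + alpha) * (N + beta) / ((n1plus + alpha1) * (nplus1 + beta1))`.
#' It is filled in by [compute_ic()].
#'
#' @param alpha1,beta1 Marginal pseudo-counts (default 1).
#' @param alpha,beta Marginal prior totals (default 2).
#' @param gamma11 Joint-cell pseudo-count (default 1).
#' @return An `ic_priors` list.
#' @export
ic_priors <- function(alpha1 = 1, beta1 = 1, alpha = 2, beta = 2, gamma11 = 1) {
  p <- list(alpha1 = alpha1, beta1 = beta1, alpha = alpha, beta = beta,
            gamma11 = gamma11, gamma = NA_real_)
  if (any(unlist(p[1:5]) <= 0)) {
    stop("IC priors must be strictly positive", call. = FALSE)
  }
  structure(p, class = "ic_priors")
}

#' Information component with 95% interval
#'
#' Posterior-moment BCPNN estimator of the information component, the
#' base-2 log of the ratio between the observed joint reporting
#' probability and the product of the margins, shrunk by the pseudo-count
#' priors of [ic_priors()]. With `N` the case total,
#'
#' `IC = log2( (n11+g11)(N+a)(N+b) / ((N+g)(n1plus+a1)(nplus1+b1)) )`
#'
#' and the posterior variance is the three-term expression
#'
#' `V = [ (N-n11+g-g11)/((n11+g11)(1+N+g))
#'      + (N-n1plus+a-a1)/((n1plus+a1)(1+N+a))
#'      + (N-nplus1+b-b1)/((nplus1+b1)(1+N+b)) ] / ln(2)^2`.
#'
#' The default interval is `IC +/- 2 * sd` (the classical BCPNN choice);
#' `interval = "z"` uses 1.96 instead. The priors keep every term finite,
#' so the IC is defined even when `n11 = 0`.
#'
#' @param table A `contingency_table`.
#' @param priors An [ic_priors()] object.
#' @param interval `"2sd"` (default) or `"z"` (1.96 sd).
#' @return An `ic_result`: list with `ic`, `ci_low`, `ci_high`, `ic_sd`,
#'   `priors` (with the data-dependent `gamma` filled in).
#' @export
#' @examples
#' compute_ic(contingency_from_margins(30, 21455, 176, 697885))
compute_ic <- function(table, priors = ic_priors(), interval = c("2sd", "z")) {
  stopifnot(inherits(table, "contingency_table"), inherits(priors, "ic_priors"))
  interval <- match.arg(interval)
  n <- table$nplusplus
  if (n <= 0) stop("IC undefined: empty table", call. = FALSE)
  n11 <- table$n11; n1p <- table$n1plus; np1 <- table$nplus1
  a1 <- priors$alpha1; b1 <- priors$beta1
  a <- priors$alpha; b <- priors$beta; g11 <- priors$gamma11

  g <- g11 * (n + a) * (n + b) / ((n1p + a1) * (np1 + b1))
  ic <- log2((n11 + g11) * (n + a) * (n + b) /
               ((n + g) * (n1p + a1) * (np1 + b1)))
  v <- ((n - n11 + g - g11) / ((n11 + g11) * (1 + n + g)) +
          (n - n1p + a - a1) / ((n1p + a1) * (1 + n + a)) +
          (n - np1 + b - b1) / ((np1 + b1) * (1 + n + b))) / log(2)^2
  ic_sd <- sqrt(v)
  k <- if (interval == "2sd") 2 else 1.96
  priors$gamma <- g
  structure(
    list(ic = ic, ci_low = ic - k * ic_sd, ci_high = ic + k * ic_sd,
         ic_sd = ic_sd, priors = priors, interval = interval),
    class = "ic_result"
  )
}

#' @export
print.ic_result <- function(x, ...) {
  cat(sprintf("IC %.2f [95%% CI %.2f to %.2f]\n",
              round_half_up(x$ic), round_half_up(x$ci_low),
              round_half_up(x$ci_high)))
  invisible(x)
}

#' Haldane-Anscombe continuity correction
#'
#' Adds 0.5 to all four cells so the odds ratio is defined when a cell is
#' zero; the result is flagged `corrected`. Calling it on a zero-free
#' table is a no-op with a warning.
#'
#' @param table A `contingency_table`.
#' @return The corrected `contingency_table`.
#' @export
apply_continuity_correction <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  if (all(c(table$n11, table$n10, table$n01, table$n00) > 0)) {
    warning("no zero cell: continuity correction not applied", call. = FALSE)
    return(table)
  }
  out <- contingency_table(table$n11 + 0.5, table$n10 + 0.5,
                           table$n01 + 0.5, table$n00 + 0.5,
                           target_drug = table$target_drug,
                           event_set = table$event_set)
  out$corrected <- TRUE
  out
}

#' Dual signal criterion
#'
#' A safety signal is positive only when the lower 95% bound of the ROR
#' exceeds 1 AND the lower 95% bound of the IC exceeds 0. An undefined ROR
#' (`NULL`) cannot satisfy the criterion.
#'
#' @param ror A `ror_result`, or `NULL` if undefined.
#' @param ic An `ic_result`.
#' @return List with `signal` (logical) and `rationale` (string recording
#'   both bounds).
#' @export
detect_signal <- function(ror, ic) {
  stopifnot(inherits(ic, "ic_result"))
  if (is.null(ror)) {
    return(list(signal = FALSE,
                rationale = sprintf(
                  "ROR undefined (zero cell); IC lower bound %.4f: no signal",
                  ic$ci_low)))
  }
  stopifnot(inherits(ror, "ror_result"))
  ok_ror <- ror$ci_low > 1
  ok_ic <- ic$ci_low > 0
  list(
    signal = ok_ror && ok_ic,
    rationale = sprintf(
      "ROR lower bound %.4f %s 1; IC lower bound %.4f %s 0: %s",
      ror$ci_low, if (ok_ror) ">" else "<=",
      ic$ci_low, if (ok_ic) ">" else "<=",
      if (ok_ror && ok_ic) "signal" else "no signal")
  )
}

#' Run the signal analysis for one drug over several event sets
#'
#' Composes [build_contingency()], [compute_ror()], [compute_ic()] and
#' [detect_signal()] for each PT set. Event sets with a zero cell are
#' reported with the IC only and the ROR columns `NA` unless `correction`
#' is enabled; such sets cannot be flagged as signals without a defined
#' ROR.
#'
#' @param cases A `jader_cases` object.
#' @param target_drug Drug name.
#' @param pt_sets A list of [pt_set] objects (e.g. [default_pt_sets()]).
#' @param correction Apply the Haldane-Anscombe correction to zero-cell
#'   tables.
#' @param ic_interval Passed to [compute_ic()].
#' @return Tibble with one row per event set: `drug`, `event_set`,
#'   `n11`, `n10`, `n01`, `n00`, `ror`, `ror_low`, `ror_high`, `ic`,
#'   `ic_low`, `ic_high`, `signal`, `rationale`.
#' @export
run_signal_analysis <- function(cases, target_drug, pt_sets = default_pt_sets(),
                                correction = FALSE, ic_interval = "2sd") {
  if (inherits(pt_sets, "pt_set")) pt_sets <- list(pt_sets)
  rows <- lapply(pt_sets, function(ps) {
    tab <- build_contingency(cases, target_drug, ps)
    ror_res <- tryCatch(compute_ror(tab, correction = correction),
                        error = function(e) NULL)
    ic_res <- compute_ic(tab, interval = ic_interval)
    sig <- detect_signal(ror_res, ic_res)
    tibble::tibble(
      drug = target_drug, event_set = ps$name,
      n11 = tab$n11, n10 = tab$n10, n01 = tab$n01, n00 = tab$n00,
      ror = if (is.null(ror_res)) NA_real_ else ror_res$ror,
      ror_low = if (is.null(ror_res)) NA_real_ else ror_res$ci_low,
      ror_high = if (is.null(ror_res)) NA_real_ else ror_res$ci_high,
      ic = ic_res$ic, ic_low = ic_res$ci_low, ic_high = ic_res$ci_high,
      signal = sig$signal, rationale = sig$rationale
    )
  })
  dplyr::bind_rows(rows)
}
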