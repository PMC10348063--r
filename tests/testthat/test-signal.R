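test_that("ROR and Woolf CI reproduce the reported renal-event estimates", {
  igan <- contingency_from_margins(30, 21455, 176, 697885)
  r1 <- compute_ror(igan)
  expect_equal(round_half_up(c(r1$ror, r1$ci_low, r1$ci_high)),
               c(6.49, 4.38, 9.61))
  neph <- contingency_from_margins(98, 21455, 5360, 697885)
  r2 <- compute_ror(neph)
  expect_equal(round_half_up(c(r2$ror, r2$ci_low, r2$ci_high)),
               c(0.59, 0.48, 0.72))
})

test_that("BCPNN IC reproduces the reported estimates with default priors", {
  i1 <- compute_ic(contingency_from_margins(30, 21455, 176, 697885))
  expect_equal(round_half_up(c(i1$ic, i1$ci_low, i1$ci_high)),
               c(2.27, 1.70, 2.83))
  i2 <- compute_ic(contingency_from_margins(98, 21455, 5360, 697885))
  expect_equal(round_half_up(c(i2$ic, i2$ci_low, i2$ci_high)),
               c(-0.74, -1.04, -0.45))
  # interval is symmetric about the point estimate
  expect_equal(i1$ci_high - i1$ic, i1$ic - i1$ci_low, tolerance = 1e-12)
})

test_that("Woolf CI matches a logistic-regression log-OR interval", {
  set.seed(31)
  for (rep in 1:10) {
    cells <- rpois(4, lambda = c(20, 400, 80, 2000)) + 1
    tab <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    r <- compute_ror(tab)
    df <- data.frame(drug = c(1, 1, 0, 0), event = c(1, 0, 1, 0), w = cells)
    fit <- stats::glm(event ~ drug, family = stats::binomial(), data = df,
                      weights = w,
                      control = stats::glm.control(epsilon = 1e-14, maxit = 100))
    expect_equal(log(r$ror), unname(stats::coef(fit)["drug"]), tolerance = 1e-8)
    expect_equal(r$log_se,
                 unname(sqrt(diag(stats::vcov(fit))["drug"])),
                 tolerance = 1e-8)
  }
})

test_that("scaling all cells preserves the ROR and strictly shrinks its CI", {
  set.seed(7)
  for (rep in 1:10) {
    cells <- rpois(4, c(15, 200, 60, 900)) + 1
    t1 <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    t2 <- contingency_table(cells[1] * 5, cells[2] * 5, cells[3] * 5, cells[4] * 5)
    r1 <- compute_ror(t1); r2 <- compute_ror(t2)
    expect_equal(r1$ror, r2$ror, tolerance = 1e-12)
    expect_lt(r2$log_se, r1$log_se)
  }
})

test_that("exact-independence tables give ROR 1 and IC near 0", {
  tab <- contingency_table(100, 900, 900, 8100)
  expect_equal(compute_ror(tab)$ror, 1)
  expect_lt(abs(compute_ic(tab)$ic), 0.01)
})

test_that("for large N the IC approaches the crude log2 reporting ratio", {
  k <- 1000
  tab <- contingency_table(20 * k, 80 * k, 80 * k, 820 * k)
  crude <- log2(tab$n11 * tab$nplusplus / (tab$n1plus * tab$nplus1))
  expect_lt(abs(compute_ic(tab)$ic - crude), 0.01)
})

test_that("ROR and IC are strictly increasing in n11 with margins fixed", {
  n1p <- 500; np1 <- 300; n <- 10000
  sweep <- 10:60
  rors <- vapply(sweep, function(n11) {
    compute_ror(contingency_from_margins(n11, n1p, np1, n))$ror
  }, numeric(1))
  ics <- vapply(sweep, function(n11) {
    compute_ic(contingency_from_margins(n11, n1p, np1, n))$ic
  }, numeric(1))
  expect_true(all(diff(rors) > 0))
  expect_true(all(diff(ics) > 0))
})

test_that("zero cells error without correction and apply Haldane +0.5 with it", {
  tab0 <- contingency_table(0, 10, 10, 80)
  expect_error(compute_ror(tab0), "n11")
  corr <- apply_continuity_correction(tab0)
  expect_equal(c(corr$n11, corr$n10, corr$n01, corr$n00),
               c(0.5, 10.5, 10.5, 80.5))
  expect_true(corr$corrected)
  r <- compute_ror(tab0, correction = TRUE)
  expect_equal(r$ror, (0.5 * 80.5) / (10.5 * 10.5), tolerance = 1e-12)
  expect_true(r$corrected)
  # no-op with warning on a zero-free table
  clean <- contingency_table(1, 1, 1, 1)
  expect_warning(same <- apply_continuity_correction(clean), "no zero cell")
  expect_equal(same$n11, 1)
  # IC stays defined at n11 = 0 through the priors
  expect_true(is.finite(compute_ic(tab0)$ic))
})

test_that("the dual criterion requires both lower bounds", {
  igan_ror <- compute_ror(contingency_from_margins(30, 21455, 176, 697885))
  igan_ic <- compute_ic(contingency_from_margins(30, 21455, 176, 697885))
  expect_true(detect_signal(igan_ror, igan_ic)$signal)

  neph_ror <- compute_ror(contingency_from_margins(98, 21455, 5360, 697885))
  neph_ic <- compute_ic(contingency_from_margins(98, 21455, 5360, 697885))
  expect_false(detect_signal(neph_ror, neph_ic)$signal)

  # one criterion alone is not enough: ROR bound above 1, IC bound below 0
  mixed_ror <- igan_ror; mixed_ic <- neph_ic
  res <- detect_signal(mixed_ror, mixed_ic)
  expect_false(res$signal)
  expect_match(res$rationale, "no signal")
  expect_false(detect_signal(NULL, igan_ic)$signal)
})

test_that("run_signal_analysis composes the stage functions and ignores case order", {
  fx <- fixture_from_margins(12, 60, 25, 600)
  cases <- link_cases(fx$demo, filter_suspected(fx$drug), fx$reac)
  res <- run_signal_analysis(cases, fx$target$drug, list(fx$target$pt_set))
  tab <- build_contingency(cases, fx$target$drug, fx$target$pt_set)
  ror <- compute_ror(tab); ic <- compute_ic(tab)
  expect_equal(res$ror, ror$ror)
  expect_equal(res$ror_low, ror$ci_low)
  expect_equal(res$ic, ic$ic)
  expect_equal(res$signal, detect_signal(ror, ic)$signal)

  perm <- link_cases(fx$demo[sample(nrow(fx$demo)), ],
                     filter_suspected(fx$drug)[sample(nrow(fx$drug)), ],
                     fx$reac[sample(nrow(fx$reac)), ])
  res2 <- run_signal_analysis(perm, fx$target$drug, list(fx$target$pt_set))
  expect_equal(res2[, setdiff(names(res2), "rationale")],
               res[, setdiff(names(res), "rationale")])
})

test_that("zero-count event sets report IC only with the ROR undefined", {
  fx <- fixture_from_margins(5, 30, 10, 300,
                             extra_events = list(list(pt_code = "10025140",
                                                      pt_name = "Lupus nephritis",
                                                      n11 = 0, nplus1 = 4)))
  cases <- link_cases(fx$demo, filter_suspected(fx$drug), fx$reac)
  sets <- list(fx$target$pt_set, pt_set("Lupus nephritis", "10025140"))
  res <- run_signal_analysis(cases, fx$target$drug, sets)
  lup <- res[res$event_set == "Lupus nephritis", ]
  expect_true(is.na(lup$ror))
  expect_true(is.finite(lup$ic))
  expect_false(lup$signal)
  # with the continuity correction the ROR becomes available
  res_c <- run_signal_analysis(cases, fx$target$drug, sets, correction = TRUE)
  expect_false(is.na(res_c$ror[res_c$event_set == "Lupus nephritis"]))
})
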