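# Small in-code builders for linked-case fixtures.

demo_tbl <- function(ids, sex = "male", age = "20s") {
  tibble::tibble(case_id = ids,
                 sex = rep_len(sex, length(ids)),
                 age_bucket = rep_len(age, length(ids)))
}

drug_tbl <- function(ids, name = "VaxX", role = "suspected", date = NA_character_) {
  tibble::tibble(case_id = ids,
                 drug_name = rep_len(name, length(ids)),
                 role = rep_len(role, length(ids)),
                 admin_date = rep_len(date, length(ids)))
}

reac_tbl <- function(ids, code = "10021263", name = "IgA nephropathy",
                     onset = NA_character_, outcome = "unknown") {
  tibble::tibble(case_id = ids,
                 pt_code = rep_len(code, length(ids)),
                 pt_name = rep_len(name, length(ids)),
                 onset_date = rep_len(onset, length(ids)),
                 outcome = rep_len(outcome, length(ids)))
}

# joint-case onset lags and outcomes mirroring the reported renal
# time-to-onset distribution: 30 joint cases, 16 with a known delay
tto_report_lags <- function() {
  c(rep(0L, 2), rep(1L, 5), rep(2L, 4), 5L, 10L, 20L, 30L, 60L, rep(NA_integer_, 14))
}

tto_report_outcomes <- function() {
  c(rep("recovery", 2), rep("remission", 6), rep("no_recovery", 11),
    rep("unknown", 11))
}

# the three extra event blocks that make one fixture reproduce the
# nephritis and lupus-nephritis margins alongside the target event
renal_extra_events <- function(scale = 1) {
  list(
    list(pt_code = "10018364", pt_name = "Glomerulonephritis",
         n11 = round(98 / scale), nplus1 = round(5360 / scale)),
    list(pt_code = "10025140", pt_name = "Lupus nephritis",
         n11 = 0, nplus1 = round(62 / scale))
  )
}

# multiset comparison of data frames, ignoring row order
expect_same_rows <- function(a, b) {
  ord <- function(d) d[do.call(order, as.list(d)), , drop = FALSE]
  expect_equal(as.data.frame(ord(a)), as.data.frame(ord(b)),
               ignore_attr = TRUE)
}
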