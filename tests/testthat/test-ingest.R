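write_csv_tmp <- function(df, dir, name) {
  p <- file.path(dir, name)
  readr::write_csv(df, p, na = "")
  p
}

test_that("readers pass rows through and coerce unparseable enums", {
  dir <- withr::local_tempdir()
  p <- write_csv_tmp(tibble::tibble(
    case_id = c("A", "B", "C"),
    sex = c("male", "", "FEMALE"),
    age_bucket = c("20s", "30s", "")), dir, "demo.csv")
  demo <- read_demo(p)
  expect_equal(nrow(demo), 3)
  expect_equal(demo$sex, c("male", NA, "female"))
  expect_equal(demo$age_bucket, c("20s", "30s", NA))

  pd <- write_csv_tmp(tibble::tibble(
    case_id = c("A", "B", "C"),
    drug_name = "X", role = c("suspected", "maybe", "bogus"),
    admin_date = "20210101"), dir, "drug.csv")
  expect_warning(drug <- read_drug(pd), "unrecognized")
  expect_equal(nrow(drug), 3)  # rows kept, role flagged unknown
  expect_equal(drug$role, c("suspected", NA, NA))
  expect_equal(attr(drug, "warning_counts")[["bad_role"]], 2)
})

test_that("missing mapped columns raise a schema error naming the column", {
  dir <- withr::local_tempdir()
  p <- write_csv_tmp(tibble::tibble(case_id = "A", sex = "male"), dir, "demo.csv")
  expect_error(read_demo(p), "age_bucket")
})

test_that("column mapping allows arbitrary source headers", {
  dir <- withr::local_tempdir()
  p <- write_csv_tmp(tibble::tibble(
    ID = c("A", "B"), SEI = c("male", "female"), NENREI = c("20s", "50s")),
    dir, "demo_jp.csv")
  demo <- read_demo(p, column_map = c(case_id = "ID", sex = "SEI",
                                      age_bucket = "NENREI"))
  expect_equal(demo$case_id, c("A", "B"))
  expect_equal(demo$age_bucket, c("20s", "50s"))
})

test_that("exclude_incomplete removes and counts cases missing sex or age", {
  demo <- tibble::tibble(
    case_id = c("A", "B", "C", "D", "E"),
    sex = c("male", NA, "female", "male", NA),
    age_bucket = c("20s", "30s", NA, "40s", NA))
  res <- exclude_incomplete(demo)
  expect_equal(nrow(res$kept), 2)   # B and C each miss one field, E misses both
  expect_equal(res$n_excluded, 3)   # counted once even when both are missing
  # all-complete input is the identity
  res2 <- exclude_incomplete(res$kept)
  expect_equal(res2$n_excluded, 0)
  expect_equal(res2$kept, res$kept)
})

test_that("dedupe removes only full-field duplicates, keeping first occurrence", {
  reac <- reac_tbl(c("A", "A"), onset = "20210101")
  res <- dedupe_rows(reac)
  expect_equal(nrow(res$kept), 1)
  expect_equal(res$n_removed, 1)
  # rows differing only in onset_date are both kept
  reac2 <- reac_tbl(c("A", "A"), onset = c("20210101", "20210102"))
  expect_equal(dedupe_rows(reac2)$n_removed, 0)
})

test_that("dedupe removal count equals the generator's injected duplicates", {
  ds <- simulate_reports(sim_config(n_cases = 2000, p_duplicate_row = 0.1,
                                    seed = 17))
  expect_equal(dedupe_rows(ds$drug)$n_removed, ds$truth$n_duplicates_drug)
  expect_equal(dedupe_rows(ds$reac)$n_removed, ds$truth$n_duplicates_reac)
  expect_gt(ds$truth$n_duplicates_drug, 0)
})

test_that("filter_suspected keeps exactly the suspected-role rows", {
  drug <- drug_tbl(c("A", "B", "C", "D"),
                   role = c("suspected", "concomitant", "interaction", "suspected"))
  out <- filter_suspected(drug)
  expect_equal(out$case_id, c("A", "D"))
  expect_equal(filter_suspected(out), out)       # idempotent
  expect_equal(nrow(filter_suspected(drug_tbl("E", role = "concomitant"))), 0)
})

test_that("link_cases keeps one case per demo row and counts orphans", {
  demo <- demo_tbl(c("A", "B"))
  reac <- reac_tbl(c("A", "C"))
  cases <- link_cases(demo, drug_tbl(character(0)), reac)
  expect_equal(n_cases(cases), 2)
  expect_equal(cases$reac$case_id, "A")
  expect_equal(cases$n_orphan_reac, 1)
  # cases may have zero drug and zero reaction rows
  empty <- link_cases(demo, drug_tbl(character(0)), reac_tbl(character(0)))
  expect_equal(n_cases(empty), 2)
  expect_equal(nrow(empty$reac), 0)
})

test_that("ingest flow bookkeeping satisfies in = kept + removed and is idempotent", {
  ds <- simulate_reports(sim_config(n_cases = 1500, p_missing_sex = 0.1,
                                    p_missing_age = 0.1, p_duplicate_row = 0.05,
                                    seed = 8))
  dir <- withr::local_tempdir()
  paths <- write_tables(ds, dir)
  ing <- ingest_jader(paths[["demo"]], paths[["drug"]], paths[["reac"]])
  expect_true(all(ing$flow$rows_in == ing$flow$rows_kept + ing$flow$rows_removed))

  # applying the cleaning stages to already-clean tables changes nothing
  cases <- ing$cases
  expect_equal(exclude_incomplete(cases$demo)$n_excluded, 0)
  expect_equal(dedupe_rows(cases$drug)$n_removed, 0)
  expect_equal(dedupe_rows(cases$reac)$n_removed, 0)
  relinked <- link_cases(cases$demo, cases$drug, cases$reac)
  expect_equal(relinked$demo, cases$demo)
  expect_equal(relinked$drug, cases$drug)
  expect_equal(relinked$reac, cases$reac)
})

test_that("link_cases matches a naive quadratic re-linker", {
  ds <- simulate_reports(sim_config(n_cases = 300, p_missing_sex = 0.05,
                                    p_missing_age = 0.05, seed = 21))
  demo <- exclude_incomplete(ds$demo)$kept
  drug <- filter_suspected(dedupe_rows(ds$drug)$kept)
  reac <- dedupe_rows(ds$reac)$kept
  cases <- link_cases(demo, drug, reac)

  slow_drug <- do.call(rbind, lapply(demo$case_id, function(id) {
    drug[drug$case_id == id, , drop = FALSE]
  }))
  slow_reac <- do.call(rbind, lapply(demo$case_id, function(id) {
    reac[reac$case_id == id, , drop = FALSE]
  }))
  expect_same_rows(cases$drug, slow_drug)
  expect_same_rows(cases$reac, slow_reac)
})
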