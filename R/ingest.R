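# Readers and cleaning steps for the three-table JADER schema, applied in
# the study-flow order: demographic exclusions, duplicate removal,
# suspected-role filtering, then linkage on the case identifier.

#' Default column mapping for the three tables
#'
#' Maps the schema field names used internally to the column headers of
#' the input files. Override entries to ingest files with other headers
#' (e.g. the original Japanese JADER column names) without code changes.
#'
#' @return A list with elements `demo`, `drug`, `reac`; each a named
#'   character vector `c(field = header)`.
#' @export
default_column_map <- function() {
  list(
    demo = c(case_id = "case_id", sex = "sex", age_bucket = "age_bucket"),
    drug = c(case_id = "case_id", drug_name = "drug_name", role = "role",
             admin_date = "admin_date"),
    reac = c(case_id = "case_id", pt_code = "pt_code", pt_name = "pt_name",
             onset_date = "onset_date", outcome = "outcome")
  )
}

read_mapped <- function(path, map, delim) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           na = c("", "NA"), progress = FALSE,
                           show_col_types = FALSE)
  missing_cols <- map[!map %in% names(raw)]
  if (length(missing_cols) > 0) {
    stop("schema error in ", path, ": mapped column(s) not found: ",
         paste(sprintf("'%s' (field %s)", missing_cols, names(missing_cols)),
               collapse = ", "),
         call. = FALSE)
  }
  out <- raw[, unname(map), drop = FALSE]
  names(out) <- names(map)
  out
}

# normalize an enum column: recognized tokens pass (case-insensitive),
# blanks become `missing_value`, anything else becomes `missing_value`
# and is counted as a warning
normalize_enum <- function(x, levels, missing_value = NA_character_) {
  tok <- tolower(trimws(x))
  ok <- tok %in% levels
  blank <- is.na(x) | tok == ""
  bad <- !ok & !blank
  out <- ifelse(ok, tok, missing_value)
  list(values = out, n_bad = sum(bad))
}

finish_read <- function(df, warnings, what) {
  warnings <- warnings[warnings > 0]
  if (length(warnings) > 0) {
    warning(what, ": unrecognized values coerced to missing/unknown (",
            paste(names(warnings), warnings, sep = "=", collapse = ", "), ")",
            call. = FALSE)
  }
  attr(df, "warning_counts") <- warnings
  df
}

#' Read the demographics table
#'
#' Every file row becomes exactly one typed row. Unrecognized sex or age
#' tokens are coerced to missing with a counted warning (retrievable via
#' `attr(x, "warning_counts")`).
#'
#' @param path Path to the delimited file.
#' @param column_map Named character vector mapping fields `case_id`,
#'   `sex`, `age_bucket` to file headers.
#' @param delim Field delimiter.
#' @return Tibble with columns `case_id`, `sex` (male/female/`NA`),
#'   `age_bucket` (one of [age_buckets()] or `NA`).
#' @export
read_demo <- function(path, column_map = default_column_map()$demo, delim = ",") {
  df <- read_mapped(path, column_map, delim)
  s <- normalize_enum(df$sex, c("male", "female"))
  a <- normalize_enum(df$age_bucket, tolower(age_buckets()))
  # restore canonical bucket case ("10s" etc. are already lower-case; "<10" unchanged)
  df$sex <- s$values
  df$age_bucket <- a$values
  finish_read(df, c(bad_sex = s$n_bad, bad_age = a$n_bad), "demo")
}

#' Read the drug table
#'
#' Involvement roles outside suspected/concomitant/interaction are kept
#' but flagged as `NA` with a counted warning; administration dates are
#' kept as raw tokens (see [parse_jader_date()]).
#'
#' @inheritParams read_demo
#' @return Tibble with columns `case_id`, `drug_name`, `role`,
#'   `admin_date`.
#' @export
read_drug <- function(path, column_map = default_column_map()$drug, delim = ",") {
  df <- read_mapped(path, column_map, delim)
  r <- normalize_enum(df$role, c("suspected", "concomitant", "interaction"))
  df$role <- r$values
  finish_read(df, c(bad_role = r$n_bad), "drug")
}

#' Read the reaction table
#'
#' Outcomes outside the six categories of [outcome_levels()] become
#' `"unknown"` with a counted warning; PT codes not matching the 8-digit
#' pattern are kept verbatim but counted.
#'
#' @inheritParams read_demo
#' @return Tibble with columns `case_id`, `pt_code`, `pt_name`,
#'   `onset_date`, `outcome`.
#' @export
read_reac <- function(path, column_map = default_column_map()$reac, delim = ",") {
  df <- read_mapped(path, column_map, delim)
  o <- normalize_enum(df$outcome, outcome_levels(), missing_value = "unknown")
  df$outcome <- o$values
  n_bad_pt <- sum(!is.na(df$pt_code) & !grepl("^[0-9]{8}$", df$pt_code))
  finish_read(df, c(bad_outcome = o$n_bad, bad_pt_code = n_bad_pt), "reac")
}

#' Exclude cases with missing sex or age
#'
#' Cases lacking either demographic field are removed before any linking;
#' a case missing both is excluded (and counted) once.
#'
#' @param demo_rows Tibble from [read_demo()].
#' @return List with `kept` (tibble of complete rows) and `n_excluded`.
#' @export
exclude_incomplete <- function(demo_rows) {
  keep <- !is.na(demo_rows$sex) & !is.na(demo_rows$age_bucket)
  list(kept = demo_rows[keep, , drop = FALSE], n_excluded = sum(!keep))
}

#' Remove exact duplicate rows
#'
#' Rows are duplicates only when every field is identical; the first
#' occurrence is retained. Rows differing in any field (e.g. only the
#' onset date) are both kept.
#'
#' @param rows A tibble (drug or reac rows).
#' @return List with `kept` and `n_removed`.
#' @export
dedupe_rows <- function(rows) {
  kept <- dplyr::distinct(rows)
  list(kept = kept, n_removed = nrow(rows) - nrow(kept))
}

#' Keep only suspected-drug rows
#'
#' Only drugs in the "suspected" involvement category contribute to drug
#' exposure; concomitant, interaction and unrecognized roles are dropped.
#'
#' @param drug_rows Tibble from [read_drug()].
#' @return Tibble of suspected rows.
#' @export
filter_suspected <- function(drug_rows) {
  drug_rows[drug_rows$role %in% "suspected", , drop = FALSE]
}

#' Link the three tables into cases
#'
#' One case per kept demo row; drug and reaction rows whose case id does
#' not appear in the demo table are dropped and counted as orphans. A case
#' may legitimately have zero drug rows or zero reaction rows.
#'
#' @param demo Demo rows that already passed [exclude_incomplete()].
#' @param drug Drug rows, deduplicated and filtered to suspected.
#' @param reac Reaction rows, deduplicated.
#' @return A `jader_cases` object: list of tibbles `demo`, `drug`, `reac`
#'   plus orphan counts `n_orphan_drug`, `n_orphan_reac`.
#' @export
link_cases <- function(demo, drug, reac) {
  ids <- demo$case_id
  if (anyDuplicated(ids)) {
    stop("demo table has duplicated case ids after cleaning", call. = FALSE)
  }
  drug_in <- drug$case_id %in% ids
  reac_in <- reac$case_id %in% ids
  structure(
    list(
      demo = tibble::as_tibble(demo),
      drug = tibble::as_tibble(drug[drug_in, , drop = FALSE]),
      reac = tibble::as_tibble(reac[reac_in, , drop = FALSE]),
      n_orphan_drug = sum(!drug_in),
      n_orphan_reac = sum(!reac_in)
    ),
    class = "jader_cases"
  )
}

#' @export
print.jader_cases <- function(x, ...) {
  cat("<jader_cases> ", nrow(x$demo), " cases; ", nrow(x$drug),
      " suspected drug rows; ", nrow(x$reac), " reaction rows\n", sep = "")
  invisible(x)
}

#' Number of cases in a linked dataset
#' @param cases A `jader_cases` object.
#' @return Integer case count.
#' @export
n_cases <- function(cases) {
  stopifnot(inherits(cases, "jader_cases"))
  nrow(cases$demo)
}

#' Run the full ingest flow on three files
#'
#' Applies the study flow in order: read, exclude cases with missing sex
#' or age, remove exact duplicate drug/reac rows, keep suspected drug
#' rows, link on the case id. Every exclusion is counted so the flow can
#' be audited (`$flow` satisfies rows_in = rows_kept + rows_removed at
#' each stage).
#'
#' @param demo_path,drug_path,reac_path Paths to the three tables.
#' @param column_map List as [default_column_map()].
#' @param delim Field delimiter.
#' @return List with `cases` (a `jader_cases`) and `flow` (a tibble of
#'   stage/rows_in/rows_kept/rows_removed).
#' @export
ingest_jader <- function(demo_path, drug_path, reac_path,
                         column_map = default_column_map(), delim = ",") {
  demo <- read_demo(demo_path, column_map$demo, delim)
  drug <- read_drug(drug_path, column_map$drug, delim)
  reac <- read_reac(reac_path, column_map$reac, delim)

  excl <- exclude_incomplete(demo)
  dd_drug <- dedupe_rows(drug)
  dd_reac <- dedupe_rows(reac)
  susp <- filter_suspected(dd_drug$kept)
  cases <- link_cases(excl$kept, susp, dd_reac$kept)

  flow <- tibble::tibble(
    stage = c("demo_read", "demo_exclude_missing_sex_age",
              "drug_read", "drug_dedupe", "drug_filter_suspected",
              "drug_link_orphans",
              "reac_read", "reac_dedupe", "reac_link_orphans",
              "cases_linked"),
    rows_in = c(nrow(demo), nrow(demo),
                nrow(drug), nrow(drug), nrow(dd_drug$kept), nrow(susp),
                nrow(reac), nrow(reac), nrow(dd_reac$kept),
                nrow(excl$kept)),
    rows_kept = c(nrow(demo), nrow(excl$kept),
                  nrow(drug), nrow(dd_drug$kept), nrow(susp), nrow(cases$drug),
                  nrow(reac), nrow(dd_reac$kept), nrow(cases$reac),
                  nrow(cases$demo)),
    rows_removed = c(0L, excl$n_excluded,
                     0L, dd_drug$n_removed, nrow(dd_drug$kept) - nrow(susp),
                     cases$n_orphan_drug,
                     0L, dd_reac$n_removed, cases$n_orphan_reac,
                     0L)
  )
  list(cases = cases, flow = flow)
}
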