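#' Create a preferred-term event set
#'
#' A PT set names one adverse-event category and lists the MedDRA
#' preferred-term codes that define it. Classification is always by code;
#' PT names are carried for display only.
#'
#' @param name Display name of the event category.
#' @param codes Character vector of 8-digit MedDRA PT codes (unique,
#'   non-empty). Numeric input is accepted and formatted to 8 digits.
#' @param pt_names Optional character vector of display names, parallel to
#'   `codes` (or named by code).
#' @param source Free-text provenance note.
#' @return An object of class `pt_set`.
#' @export
#' @examples
#' pt_set("IgA nephropathy", "10021263")
pt_set <- function(name, codes, pt_names = NULL, source = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("`name` must be a non-empty string", call. = FALSE)
  }
  codes <- as.character(codes)
  if (length(codes) == 0L) {
    stop("PT set '", name, "' has no codes", call. = FALSE)
  }
  bad <- codes[!grepl("^[0-9]{8}$", codes)]
  if (length(bad) > 0L) {
    stop("PT set '", name, "': malformed PT code(s) (must be 8 digits): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(codes)) {
    codes <- unique(codes)
  }
  if (!is.null(pt_names)) {
    if (is.null(names(pt_names))) names(pt_names) <- codes[seq_along(pt_names)]
    pt_names <- pt_names[codes]
  }
  structure(
    list(name = name, codes = codes, pt_names = pt_names, source = source),
    class = "pt_set"
  )
}

#' @export
print.pt_set <- function(x, ...) {
  cat("<pt_set> ", x$name, ": ", length(x$codes), " PT code(s)\n", sep = "")
  invisible(x)
}

#' Load the default renal event dictionary
#'
#' Returns the three built-in PT sets used for renal adverse-event signal
#' detection after COVID-19 mRNA vaccination: "IgA nephropathy" (1 code),
#' "Nephritis" (37 codes covering glomerulonephritides, tubulointerstitial
#' nephritides and tubulopathies), and "Lupus nephritis" (1 code).
#'
#' @return A named list of [pt_set] objects.
#' @seealso [load_pt_sets()] for user-supplied dictionaries.
#' @export
#' @examples
#' sets <- default_pt_sets()
#' length(sets[["Nephritis"]]$codes)
default_pt_sets <- function() {
  path <- system.file("extdata", "renal_pt_sets.yaml", package = "jpvsignal",
                      mustWork = TRUE)
  load_pt_sets(path)
}

#' Load PT sets from a YAML dictionary file
#'
#' The file holds a top-level `sets:` list; each entry has a `name:`, an
#' optional `source:`, and `codes:` given either as a `code: display name`
#' mapping or as a plain list of codes. Codes may repeat across sets —
#' sets are evaluated independently, so a case can count in several.
#'
#' @param path Path to the YAML dictionary.
#' @return A named list of [pt_set] objects.
#' @export
load_pt_sets <- function(path) {
  if (!file.exists(path)) {
    stop("dictionary file not found: ", path, call. = FALSE)
  }
  doc <- yaml::read_yaml(path)
  entries <- doc$sets %||% doc
  sets <- lapply(entries, function(e) {
    codes <- e$codes
    if (is.list(codes) && !is.null(names(codes))) {
      pt_set(e$name, names(codes), pt_names = unlist(codes),
             source = e$source %||% path)
    } else {
      pt_set(e$name, unlist(codes), source = e$source %||% path)
    }
  })
  names(sets) <- vapply(sets, function(s) s$name, character(1))
  sets
}

#' Which cases carry an event from a PT set?
#'
#' Case-level classification: a case has the event if any of its reaction
#' rows carries a PT code in the set; row multiplicity is ignored, so the
#' answer never changes when a reaction row is duplicated, and adding rows
#' can only turn `FALSE` into `TRUE`.
#'
#' @param cases A `jader_cases` object from [link_cases()].
#' @param pt_set A [pt_set].
#' @return Named logical vector, one element per case (names = case ids).
#' @export
case_has_event <- function(cases, pt_set) {
  stopifnot(inherits(cases, "jader_cases"), inherits(pt_set, "pt_set"))
  hit_ids <- unique(cases$reac$case_id[cases$reac$pt_code %in% pt_set$codes])
  out <- cases$demo$case_id %in% hit_ids
  names(out) <- cases$demo$case_id
  out
}

#' Which cases list a drug among their suspected drugs?
#'
#' Matching is exact on the normalized name (trimmed, case-folded); no
#' fuzzy matching is attempted.
#'
#' @param cases A `jader_cases` object.
#' @param target_drug Drug name to match.
#' @return Named logical vector, one element per case.
#' @export
case_has_drug <- function(cases, target_drug) {
  stopifnot(inherits(cases, "jader_cases"))
  key <- normalize_drug_name(target_drug)
  drug <- cases$drug
  hit_ids <- unique(drug$case_id[drug$role %in% "suspected" &
                                   normalize_drug_name(drug$drug_name) == key])
  out <- cases$demo$case_id %in% hit_ids
  names(out) <- cases$demo$case_id
  out
}
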