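## Reading, validating and writing sample-by-analyte metal tables.
## Canonical dialect: wide CSV, one row per sample, columns sample_id,
## organ, age_months, then analyte columns. Missing or removed cells are NA.

#' Validate a metallome table
#'
#' Checks the schema invariants of a sample-by-analyte table: mandatory
#' metadata columns present, unique sample identifiers, known organ labels,
#' positive ages, nonnegative concentrations and finite deltas (NA cells are
#' the explicit mask for missing or removed measurements).
#'
#' @param m A data frame with columns `sample_id`, `organ`, `age_months` and
#'   at least one analyte column named as in [metal_analytes()].
#' @param organs Allowed organ labels.
#' @return `m` as a tibble, invisibly validated (errors on violation).
#' @export
validate_metal_matrix <- function(m, organs = metal_organs()) {
  m <- tibble::as_tibble(m)
  mandatory <- c("sample_id", "organ", "age_months")
  missing_cols <- setdiff(mandatory, names(m))
  if (length(missing_cols) > 0) {
    abort(
      paste0("missing mandatory column(s): ", paste(missing_cols, collapse = ", ")),
      class = "metalloscope_schema_error"
    )
  }
  if (anyDuplicated(m$sample_id) > 0) {
    dup <- unique(m$sample_id[duplicated(m$sample_id)])
    abort(
      paste0("duplicate sample_id: ", paste(head(dup, 5), collapse = ", ")),
      class = "metalloscope_schema_error"
    )
  }
  if (any(is.na(m$organ)) || any(is.na(m$age_months))) {
    abort("every sample must have organ and age_months",
      class = "metalloscope_schema_error"
    )
  }
  bad_organ <- setdiff(unique(m$organ), organs)
  if (length(bad_organ) > 0) {
    abort(paste0("unknown organ label(s): ", paste(bad_organ, collapse = ", ")),
      class = "metalloscope_schema_error"
    )
  }
  if (any(m$age_months <= 0)) {
    abort("age_months must be positive", class = "metalloscope_schema_error")
  }
  conc <- present_analytes(m, "concentration")
  if (length(present_analytes(m)) == 0) {
    abort("no recognized analyte columns", class = "metalloscope_schema_error")
  }
  for (a in conc) {
    bad <- !is.na(m[[a]]) & m[[a]] < 0
    if (any(bad)) {
      abort(paste0("negative concentration in column ", a),
        class = "metalloscope_schema_error"
      )
    }
  }
  for (a in present_analytes(m, "delta")) {
    bad <- !is.na(m[[a]]) & !is.finite(m[[a]])
    if (any(bad)) {
      abort(paste0("non-finite delta in column ", a),
        class = "metalloscope_schema_error"
      )
    }
  }
  m
}

#' Read a metallome sample table
#'
#' Reads a wide CSV/TSV (one row per sample) or a long table
#' (`sample_id, organ, age_months, analyte, value`, normalized to wide on
#' load). Unparseable numeric cells become NA (the explicit missingness
#' mask) with a warning reporting how many were masked.
#'
#' @param path Path to a delimited text file with a header row.
#' @param format `"wide"` (default) or `"long"`.
#' @param delim Field delimiter; guessed from the extension by default
#'   (`.tsv`/`.txt` tab, otherwise comma).
#' @return A validated metallome tibble.
#' @seealso [validate_metal_matrix()], [write_metal_table()]
#' @export
read_metal_table <- function(path, format = c("wide", "long"), delim = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "metalloscope_io_error")
  }
  delim <- delim %||% if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  raw <- readr::read_delim(path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (format == "long") {
    need <- c("sample_id", "organ", "age_months", "analyte", "value")
    missing_cols <- setdiff(need, names(raw))
    if (length(missing_cols) > 0) {
      abort(
        paste0("long format requires column(s): ", paste(missing_cols, collapse = ", ")),
        class = "metalloscope_schema_error"
      )
    }
    raw <- tidyr::pivot_wider(raw,
      id_cols = c("sample_id", "organ", "age_months"),
      names_from = "analyte", values_from = "value"
    )
  }
  num_cols <- setdiff(names(raw), c("sample_id", "organ"))
  n_masked <- 0L
  for (cc in intersect(num_cols, c("age_months", metal_analytes()$analyte))) {
    x <- raw[[cc]]
    y <- suppressWarnings(as.numeric(x))
    n_masked <- n_masked + sum(!is.na(x) & x != "NA" & is.na(y))
    raw[[cc]] <- y
  }
  if (n_masked > 0) {
    warn(paste0(n_masked, " unparseable numeric cell(s) masked as NA"))
  }
  validate_metal_matrix(raw)
}

#' Write a metallome table to CSV
#'
#' Masked cells are written as the literal `NA` so that
#' `read_metal_table(write_metal_table(m))` round-trips exactly.
#'
#' @param m A validated metallome table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metal_table <- function(m, path) {
  m <- validate_metal_matrix(m)
  readr::write_csv(m, path, na = "NA")
  invisible(path)
}
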