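## GMT feature-set files (MSigDB dialect): one set per line,
## tab-separated: set_id, description, member ids...

#' Read a GMT feature-set database
#'
#' @param path Path to a tab-separated GMT file.
#' @return A tibble with one row per set: `set_id`, `description`, and a
#'   list-column `members` of unique member feature ids. Sets left empty
#'   after deduplication are dropped with a warning; an empty file yields an
#'   empty database with a warning. Duplicate `set_id` lines are an error
#'   (ambiguous definition).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "metalloscope_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warn("empty GMT file: returning empty feature-set database")
    return(tibble::tibble(
      set_id = character(), description = character(),
      members = list()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  set_id <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(set_id) > 0) {
    dup <- unique(set_id[duplicated(set_id)])
    abort(paste0("duplicate set_id in GMT: ", paste(dup, collapse = ", ")),
      class = "metalloscope_schema_error"
    )
  }
  description <- vapply(fields, function(f) if (length(f) >= 2) f[2] else "", character(1))
  members <- lapply(fields, function(f) {
    mm <- unique(f[-(1:2)])
    mm[nzchar(mm)]
  })
  n0 <- lengths(members) == 0
  if (any(n0)) {
    warn(paste0(
      sum(n0), " set(s) empty after deduplication dropped: ",
      paste(head(set_id[n0], 5), collapse = ", ")
    ))
  }
  tibble::tibble(set_id = set_id, description = description, members = members)[!n0, ]
}

#' Write a feature-set database to GMT
#'
#' @param setdb A tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(setdb, path) {
  lines <- vapply(
    seq_len(nrow(setdb)),
    function(i) {
      paste(c(setdb$set_id[i], setdb$description[i], setdb$members[[i]]),
        collapse = "\t"
      )
    },
    character(1)
  )
  writeLines(lines, path)
  invisible(path)
}
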