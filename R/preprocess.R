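## Preprocessing of a metallome table: single-pass z-score outlier removal,
## Na/total normalization, per-organ linear age correction, PCA fingerprints.

#' Remove outlying measurements by z-score
#'
#' Within each group (organ-by-age by default) and analyte, cells with
#' `|x - mean| / sd > z_threshold` are masked (set to NA) in a single pass;
#' the procedure is not re-applied to its own output. Groups with fewer than
#' 3 non-missing values, or zero spread, are skipped with a warning, never
#' an error. A warning is raised if more than 5% of measurements are
#' removed overall.
#'
#' @param m Metallome table.
#' @param z_threshold Removal threshold (default 3).
#' @param group_by Grouping columns (default `c("organ", "age_months")`, so
#'   genuine age trends are not flagged as outliers).
#' @return `m` with outliers masked; the removal log (one row per
#'   group-by-analyte with counts, plus skipped groups) in
#'   `attr(, "removal_log")` and the overall removed fraction in
#'   `attr(, "fraction_removed")`.
#' @export
remove_outliers <- function(m, z_threshold = 3, group_by = c("organ", "age_months")) {
  m <- validate_metal_matrix(m)
  analytes <- present_analytes(m)
  key <- do.call(paste, c(m[group_by], sep = "\r"))
  log_rows <- list()
  n_cells <- 0L
  n_removed <- 0L
  for (a in analytes) {
    for (g in unique(key)) {
      idx <- which(key == g)
      x <- m[[a]][idx]
      ok <- !is.na(x)
      n_cells <- n_cells + sum(ok)
      if (sum(ok) < 3) {
        log_rows[[length(log_rows) + 1]] <-
          tibble::tibble(group = gsub("\r", "/", g), analyte = a, n = sum(ok), removed = NA_integer_, note = "fewer than 3 values")
        next
      }
      s <- sd(x[ok])
      if (s == 0) {
        log_rows[[length(log_rows) + 1]] <-
          tibble::tibble(group = gsub("\r", "/", g), analyte = a, n = sum(ok), removed = NA_integer_, note = "zero spread")
        next
      }
      z <- abs(x - mean(x[ok])) / s
      bad <- ok & z > z_threshold
      if (any(bad)) m[[a]][idx[bad]] <- NA_real_
      n_removed <- n_removed + sum(bad)
      log_rows[[length(log_rows) + 1]] <-
        tibble::tibble(group = gsub("\r", "/", g), analyte = a, n = sum(ok), removed = sum(bad), note = "")
    }
  }
  removal_log <- dplyr::bind_rows(log_rows)
  n_skipped <- sum(removal_log$note != "")
  if (n_skipped > 0) {
    warn(paste0(
      "outlier pass skipped for ", n_skipped,
      " analyte-group(s) (", paste(unique(removal_log$note[removal_log$note != ""]), collapse = "; "),
      "); see the removal log"
    ))
  }
  frac <- if (n_cells > 0) n_removed / n_cells else 0
  if (frac > 0.05) {
    warn(sprintf("outlier removal masked %.1f%% of measurements (> 5%%)", 100 * frac))
  }
  attr(m, "removal_log") <- removal_log
  attr(m, "fraction_removed") <- frac
  m
}

#' Normalize metal concentrations within each sample
#'
#' `mode = "na"` divides every concentration by the sample's Na;
#' `mode = "total"` divides by the sample's total over concentration-role
#' analytes only. Isotope deltas are never part of a denominator and are
#' returned untouched. Samples whose denominator is missing or zero are
#' fully masked with a warning.
#'
#' @param m Metallome table.
#' @param mode `"none"`, `"na"` or `"total"`.
#' @return Normalized table.
#' @export
normalize_metals <- function(m, mode = c("none", "na", "total")) {
  mode <- match.arg(mode)
  m <- validate_metal_matrix(m)
  if (mode == "none") {
    return(m)
  }
  conc <- present_analytes(m, "concentration")
  denom <- if (mode == "na") {
    if (!"Na" %in% conc) abort("mode 'na' requires a Na column")
    m$Na
  } else {
    rowSums(as.matrix(m[conc]), na.rm = FALSE)
  }
  bad <- is.na(denom) | denom == 0
  if (any(bad)) {
    warn(paste0(
      sum(bad), " sample(s) with missing/zero denominator masked: ",
      paste(head(m$sample_id[bad], 5), collapse = ", ")
    ))
  }
  denom[bad] <- NA_real_
  for (a in conc) m[[a]] <- m[[a]] / denom
  m
}

#' Remove the linear age trend per organ and analyte
#'
#' Fits ordinary least squares `value ~ age_months` within each organ and
#' analyte and replaces values by `intercept + residuals`, so the output is
#' uncorrelated with age within the organ. Age-corrected values are intended
#' for visualization and rank correlations; hypothesis tests should use age
#' as a covariate instead (see [associate_pairwise()]).
#'
#' @param m Metallome table.
#' @return The age-corrected table, with per-organ-per-analyte fitted
#'   intercepts and slopes in `attr(, "age_fits")`. Organs with a single
#'   age level are returned unchanged with a warning.
#' @export
age_correct <- function(m) {
  m <- validate_metal_matrix(m)
  analytes <- present_analytes(m)
  fits <- list()
  for (o in unique(m$organ)) {
    idx <- which(m$organ == o)
    age <- m$age_months[idx]
    if (length(unique(age)) < 2) {
      warn(paste0("single age level in organ ", o, ": identity transform"))
      fits[[length(fits) + 1]] <- tibble::tibble(
        organ = o, analyte = analytes, intercept = NA_real_, slope = 0
      )
      next
    }
    for (a in analytes) {
      x <- m[[a]][idx]
      ok <- !is.na(x)
      if (sum(ok) < 3 || sd(age[ok]) == 0) {
        fits[[length(fits) + 1]] <- tibble::tibble(
          organ = o, analyte = a, intercept = NA_real_, slope = 0
        )
        next
      }
      fit <- lm.fit(cbind(1, age[ok]), x[ok])
      m[[a]][idx[ok]] <- fit$coefficients[1] + fit$residuals
      fits[[length(fits) + 1]] <- tibble::tibble(
        organ = o, analyte = a,
        intercept = unname(fit$coefficients[1]),
        slope = unname(fit$coefficients[2])
      )
    }
  }
  attr(m, "age_fits") <- dplyr::bind_rows(fits)
  m
}

#' PCA fingerprint of a metallome table
#'
#' Deterministic SVD-based principal component analysis on z-scored
#' analytes (correlation-matrix scaling: concentrations span orders of
#' magnitude). Missing cells are mean-imputed for the decomposition only,
#' with a message. Component signs are fixed by convention: the analyte
#' with the largest absolute loading is made positive.
#'
#' @param m Metallome table (>= 2 samples).
#' @param log_concentrations Log-transform concentration analytes before
#'   scaling (default TRUE).
#' @return An object of class `metallome_pca`: `scores` (tibble with sample
#'   metadata), `loadings` (matrix), `variance_explained` (sums to 1).
#' @export
pca_fingerprint <- function(m, log_concentrations = TRUE) {
  m <- validate_metal_matrix(m)
  if (nrow(m) < 2) abort("PCA needs at least 2 samples")
  analytes <- present_analytes(m)
  x <- as.matrix(m[analytes])
  if (log_concentrations) {
    conc <- present_analytes(m, "concentration")
    x[, conc] <- log(pmax(x[, conc], .Machine$double.xmin))
  }
  n_imputed <- sum(is.na(x))
  if (n_imputed > 0) {
    inform(paste0("mean-imputing ", n_imputed, " missing cell(s) for PCA"))
    for (j in seq_len(ncol(x))) {
      xj <- x[, j]
      x[is.na(xj), j] <- mean(xj, na.rm = TRUE)
    }
  }
  keep <- apply(x, 2, sd) > 0
  x <- scale(x[, keep, drop = FALSE])
  pc <- prcomp(x, center = FALSE, scale. = FALSE)
  # sign convention: largest-|loading| analyte positive in each component
  for (j in seq_len(ncol(pc$rotation))) {
    i_max <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_max, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- dplyr::bind_cols(
    m[intersect(c("sample_id", "animal_id", "organ", "age_months"), names(m))],
    tibble::as_tibble(pc$x)
  )
  structure(
    list(
      scores = scores, loadings = pc$rotation, variance_explained = ve,
      n_imputed = n_imputed
    ),
    class = "metallome_pca"
  )
}

#' @export
print.metallome_pca <- function(x, ...) {
  cat("<metallome_pca> ", nrow(x$scores), " samples, ",
    ncol(x$loadings), " components\n",
    sep = ""
  )
  cat(
    "variance explained (PC1..PC3):",
    paste0(sprintf("%.1f%%", 100 * head(x$variance_explained, 3)), collapse = ", "), "\n"
  )
  invisible(x)
}
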