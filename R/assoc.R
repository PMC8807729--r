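## Association statistics: BH step-up FDR, Spearman rho, covariate-adjusted
## pairwise association tables, and age-contrast volcano tables.

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `adj_p_(i) = min_{j >= i} (m * p_(j) / j)`, capped at 1, with stable
#' ties. NA entries are excluded from the family size and returned as NA.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (length(ok) == 0) {
    return(out)
  }
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) abort("p-values must lie in [0, 1]")
  m <- length(pv)
  o <- order(pv, decreasing = TRUE)
  adj <- pmin(1, cummin(m * pv[o] / (m:1)))
  out[ok[o]] <- adj
  out
}

#' Spearman rank correlation (mid-rank ties)
#'
#' Pearson correlation of mid-ranks on pairwise-complete observations.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Rho in \[-1, 1\]; NA with a warning if fewer than 3 complete
#'   pairs or if either rank vector has zero variance.
#' @export
spearman_rho <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) {
    warn("fewer than 3 complete pairs: rho undefined")
    return(NA_real_)
  }
  rx <- rank(x[ok], ties.method = "average")
  ry <- rank(y[ok], ties.method = "average")
  if (sd(rx) == 0 || sd(ry) == 0) {
    warn("zero variance in ranks: rho undefined")
    return(NA_real_)
  }
  cor(rx, ry)
}

# residualize x on covariate columns of data (complete cases), returning
# intercept + residuals aligned to x
residualize <- function(x, covars) {
  ok <- !is.na(x) & complete.cases(covars)
  out <- rep(NA_real_, length(x))
  if (sum(ok) < 3) {
    return(out)
  }
  X <- cbind(1, as.matrix(covars[ok, , drop = FALSE]))
  fit <- lm.fit(X, x[ok])
  out[ok] <- fit$coefficients[1] + fit$residuals
  out
}

#' Covariate-adjusted pairwise associations between two layers
#'
#' For every feature pair (a, b) the effect size is the Spearman rho of the
#' covariate-residualized values, and significance comes from the moderated
#' t of `b` in the linear model `a ~ b + covariates` — variance moderation
#' and BH adjustment are shared across all pairs of the family (one family
#' per group and layer pair; with `group_by = NULL` organs are pooled and
#' `organ` enters the model as a covariate). Features are standardized
#' internally, so p-values are invariant to feature scaling.
#'
#' @param x Metallome-style table (must contain `sample_id`, `organ`,
#'   `age_months` and the features).
#' @param y Second layer, or NULL to associate `x` with itself (pairs
#'   a < b only). Joined to `x` by `join_by`.
#' @param features_x,features_y Feature column names (defaults: analyte
#'   columns of `x`; non-key numeric columns of `y`).
#' @param covariates Covariate column names taken from `x`
#'   (default `"age_months"`).
#' @param group_by `"organ"` for per-organ families, or NULL to pool organs
#'   (organ added as a model covariate).
#' @param join_by Key used to join `y` onto `x` (default `"animal_id"` if
#'   present in both, else `"sample_id"`).
#' @param layer Label recorded in the output's `layer` column.
#' @param log_concentrations Log-transform concentration-role analytes
#'   before analysis (default TRUE: tissue concentrations are log-normal
#'   and span organs of very different scale).
#' @return Association tibble: `organ`, `feature_a`, `feature_b`, `rho`,
#'   `beta`, `t_mod`, `p`, `adj_p`, `n`, `layer`.
#' @export
associate_pairwise <- function(x, y = NULL, features_x = NULL, features_y = NULL,
                               covariates = "age_months", group_by = "organ",
                               join_by = NULL, layer = NULL,
                               log_concentrations = TRUE) {
  x <- tibble::as_tibble(x)
  features_x <- features_x %||% present_analytes(x)
  if (log_concentrations) {
    for (a in intersect(features_x, concentration_analytes())) {
      x[[a]] <- log(x[[a]])
    }
  }
  self <- is.null(y)
  if (self) {
    joined <- x
    features_y <- features_x
    layer <- layer %||% "metal-metal"
  } else {
    y <- tibble::as_tibble(y)
    join_by <- join_by %||%
      if ("animal_id" %in% names(x) && "animal_id" %in% names(y)) "animal_id" else "sample_id"
    features_y <- features_y %||%
      setdiff(
        names(y)[vapply(y, is.numeric, logical(1))],
        c(join_by, "age_months", covariates)
      )
    joined <- dplyr::inner_join(x, dplyr::select(y, dplyr::all_of(c(join_by, features_y))),
      by = join_by, suffix = c("", ".y")
    )
    layer <- layer %||% "metal-phenotype"
  }
  groups <- if (is.null(group_by)) list(pooled = joined) else split(joined, joined[[group_by]])
  out <- list()
  for (gname in names(groups)) {
    dat <- groups[[gname]]
    covars <- dat[, covariates, drop = FALSE]
    if (is.null(group_by) && length(unique(dat$organ)) > 1) {
      # organ as covariate when pooling
      covars <- dplyr::bind_cols(
        covars,
        as.data.frame(stats::model.matrix(~organ, data = dat))[, -1, drop = FALSE]
      )
    }
    pairs <- if (self) {
      idx <- which(upper.tri(diag(length(features_x))), arr.ind = TRUE)
      tibble::tibble(a = features_x[idx[, 1]], b = features_y[idx[, 2]])
    } else {
      tidyr::expand_grid(a = features_x, b = features_y)
    }
    rows <- vector("list", nrow(pairs))
    skipped <- 0L
    for (k in seq_len(nrow(pairs))) {
      a <- dat[[pairs$a[k]]]
      b <- dat[[pairs$b[k]]]
      ok <- !is.na(a) & !is.na(b) & complete.cases(covars)
      n_ok <- sum(ok)
      if (n_ok < 5) {
        skipped <- skipped + 1L
        next
      }
      # scale the response by its covariate-residual spread so that null
      # pairs share unit residual variance and moderation across the family
      # is meaningful; p-values stay invariant to feature scaling
      a_res <- residualize(a[ok], covars[ok, , drop = FALSE])
      s_a <- sd(a_res, na.rm = TRUE)
      s_b <- sd(b[ok])
      if (!is.finite(s_a) || s_a == 0 || s_b == 0) { # degenerate feature
        skipped <- skipped + 1L
        next
      }
      av <- (a[ok] - mean(a[ok])) / s_a
      bv <- (b[ok] - mean(b[ok])) / s_b
      X <- cbind(1, b = bv, as.matrix(covars[ok, , drop = FALSE]))
      fit <- lm.fit(X, av)
      dfr <- n_ok - ncol(X)
      if (dfr < 1) {
        skipped <- skipped + 1L
        next
      }
      xtxi <- chol2inv(qr.R(qr(X)))
      rho <- spearman_rho(
        residualize(a[ok], covars[ok, , drop = FALSE]),
        residualize(b[ok], covars[ok, , drop = FALSE])
      )
      rows[[k]] <- tibble::tibble(
        organ = if (is.null(group_by)) NA_character_ else gname,
        feature_a = pairs$a[k], feature_b = pairs$b[k],
        rho = rho, beta = unname(fit$coefficients["b"]),
        s2 = sum(fit$residuals^2) / dfr, v = xtxi[2, 2], df = dfr, n = n_ok
      )
    }
    fam <- dplyr::bind_rows(rows)
    if (skipped > 0) {
      inform(paste0(skipped, " pair(s) skipped (insufficient overlap) in family ", gname))
    }
    if (nrow(fam) == 0) next
    # a single-pair family has nothing to moderate: classical t
    sq <- if (nrow(fam) >= 2) {
      squeeze_variance(fam$s2, fam$df)
    } else {
      list(d0 = 0, s0_2 = fam$s2, s2_post = fam$s2)
    }
    t_mod <- fam$beta / (sqrt(sq$s2_post) * sqrt(fam$v))
    df_total <- fam$df + if (is.finite(sq$d0)) sq$d0 else 1e30
    p <- 2 * pt(-abs(t_mod), df_total)
    fam$t_mod <- t_mod
    fam$p <- p
    fam$adj_p <- bh_adjust(p)
    out[[gname]] <- fam
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(res)
  }
  res$layer <- layer
  dplyr::select(
    res, "organ", "feature_a", "feature_b", "rho", "beta",
    "t_mod", "p", "adj_p", "n", "layer"
  )
}

#' Per-feature correlation of an omics layer with each metal
#'
#' For every (feature, metal) pair within one organ: Pearson r of the
#' feature with the metal, and the two-sided moderated-t p-value of the
#' metal term in `feature ~ metal + covariates`, with variance moderation
#' shared across all features of a metal. These (r, p) pairs feed the
#' enrichment ranking metric.
#'
#' @param omics Wide omics tibble (`sample_id` + feature columns).
#' @param metallome Metallome table (supplies metal values and covariates).
#' @param metals Analyte columns to use (default: all present).
#' @param covariates Covariates (default age).
#' @return Tibble: `metal`, `feature`, `r`, `p`, `n`.
#' @export
associate_features <- function(omics, metallome, metals = NULL,
                               covariates = "age_months") {
  metals <- metals %||% present_analytes(metallome)
  joined <- dplyr::inner_join(
    dplyr::select(
      metallome,
      dplyr::all_of(c("sample_id", covariates, metals))
    ),
    omics,
    by = "sample_id"
  )
  features <- setdiff(names(omics), "sample_id")
  Y <- t(as.matrix(joined[features]))
  out <- vector("list", length(metals))
  for (i in seq_along(metals)) {
    mv <- joined[[metals[i]]]
    ok <- !is.na(mv) & complete.cases(joined[, covariates, drop = FALSE])
    design <- cbind(
      1,
      as.matrix(joined[ok, covariates, drop = FALSE]),
      metal = as.numeric(scale(mv[ok]))
    )
    fit <- moderated_fit(Y[, ok, drop = FALSE], design, coef = "metal")
    r <- apply(Y[, ok, drop = FALSE], 1, function(f) {
      suppressWarnings(cor(f, mv[ok], use = "pairwise.complete.obs"))
    })
    out[[i]] <- tibble::tibble(
      metal = metals[i], feature = features,
      r = unname(r), p = fit$p_value, n = sum(ok)
    )
  }
  dplyr::bind_rows(out)
}

#' Age-contrast table for volcano plots
#'
#' Per organ and analyte, the effect of aging between two age groups:
#' log2 fold change for concentrations (moderated t on log2 values) and the
#' plain difference in per mil for isotope deltas, with BH adjustment within
#' each organ-by-contrast family.
#'
#' @param m Metallome table.
#' @param ages Length-2 vector, contrast is `ages[2]` vs `ages[1]`.
#' @param organs Organs to test (default: all present).
#' @return Tibble: `organ`, `contrast`, `analyte`, `effect`
#'   (log2FC or delta difference), `effect_type`, `t_mod`, `p`, `adj_p`, `n`.
#' @export
age_contrast_volcano <- function(m, ages = c(6, 24), organs = NULL) {
  m <- validate_metal_matrix(m)
  organs <- organs %||% unique(m$organ)
  analytes <- present_analytes(m)
  roles <- setNames(metal_analytes()$role, metal_analytes()$analyte)
  out <- list()
  for (o in organs) {
    dat <- m[m$organ == o & m$age_months %in% ages, ]
    if (length(unique(dat$age_months)) < 2) {
      abort(paste0("organ ", o, " lacks one of the contrast ages"))
    }
    grp <- as.numeric(dat$age_months == ages[2])
    y <- matrix(NA_real_, length(analytes), nrow(dat),
      dimnames = list(analytes, NULL)
    )
    keep <- logical(length(analytes))
    for (i in seq_along(analytes)) {
      x <- dat[[analytes[i]]]
      if (roles[[analytes[i]]] == "concentration") x <- log2(x)
      if (sd(x, na.rm = TRUE) %in% c(0, NA)) next # constant analyte: skipped
      y[i, ] <- x
      keep[i] <- TRUE
    }
    fit <- moderated_fit(y[keep, , drop = FALSE], cbind(1, group = grp), coef = "group")
    out[[o]] <- tibble::tibble(
      organ = o,
      contrast = paste0(ages[2], "v", ages[1]),
      analyte = analytes[keep],
      effect = fit$coefficient,
      effect_type = ifelse(roles[analytes[keep]] == "concentration",
        "log2_fc", "delta_diff"
      ),
      t_mod = fit$t, p = fit$p_value,
      adj_p = bh_adjust(fit$p_value),
      n = rowSums(!is.na(y[keep, , drop = FALSE]))
    )
  }
  dplyr::bind_rows(out)
}
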