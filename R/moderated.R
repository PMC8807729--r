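## Empirical-Bayes moderated t-statistics.
##
## Per feature g, OLS of y_g on a shared design gives beta_g, unscaled
## standard-error factor sqrt(v), residual variance s_g^2 on d_g df. The
## residual variances are shrunk toward a pooled prior s0^2 with prior df
## d0, both estimated by moment-matching the distribution of log s_g^2 to a
## scaled log-F (digamma/trigamma equations):
##   s~_g^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)
##   t~_g   = beta_g / (s~_g sqrt(v)),  p from t with d0 + d_g df.
## d0 -> 0 recovers the classical t; d0 = Inf uses s0^2 for every feature.

# inverse of trigamma by monotone bisection (trigamma is strictly
# decreasing on (0, Inf)); tolerance 1e-8 on x
trigamma_inverse <- function(y) {
  if (y <= trigamma(1e7)) {
    return(Inf)
  }
  if (y >= trigamma(1e-8)) {
    return(1e-8)
  }
  lo <- 1e-8
  hi <- 1e7
  while (hi - lo > 1e-8 * (1 + lo)) {
    mid <- (lo + hi) / 2
    if (trigamma(mid) > y) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Empirical-Bayes shrinkage of residual variances
#'
#' Moment-matching estimate of the prior degrees of freedom `d0` and prior
#' variance `s0^2` from per-feature residual variances, followed by the
#' posterior (moderated) variances. If the log-variances show no excess
#' spread beyond their sampling variance, `d0` is infinite (capped at 1e6)
#' and every posterior variance equals `s0^2`.
#'
#' @param s2 Per-feature residual variances.
#' @param df Per-feature residual degrees of freedom.
#' @param d0 Optional: force the prior df (e.g. 0 for classical t).
#' @return List with `d0`, `s0_2`, `s2_post`.
#' @export
squeeze_variance <- function(s2, df, d0 = NULL) {
  usable <- which(df > 0 & is.finite(s2) & s2 > 0)
  if (is.null(d0)) {
    if (length(usable) < 2) abort("need >= 2 features with residual df >= 1")
    z <- log(s2[usable])
    dfu <- df[usable]
    e <- z - digamma(dfu / 2) + log(dfu / 2)
    evar <- var(z) - mean(trigamma(dfu / 2))
    if (!is.finite(evar) || evar <= 0) {
      # no excess spread beyond sampling noise: point-mass prior at the
      # (geometric) common variance
      d0 <- Inf
      s0_2 <- exp(mean(z))
      inform("residual variances consistent with a single value: d0 = Inf")
    } else {
      d0 <- 2 * trigamma_inverse(evar)
      if (d0 > 1e6) d0 <- Inf
      s0_2 <- if (is.finite(d0)) {
        exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
      } else {
        exp(mean(e))
      }
    }
  } else {
    s0_2 <- if (length(usable) > 0) exp(mean(log(s2[usable]))) else NA_real_
  }
  s2_post <- if (is.infinite(d0)) {
    rep(s0_2, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * s0_2 + df * s2) / (d0 + df)
  }
  list(d0 = d0, s0_2 = s0_2, s2_post = s2_post)
}

#' Moderated linear-model fit across features
#'
#' Fits the same design to every feature (row of `y`) by ordinary least
#' squares, shrinks the residual variances by empirical Bayes
#' ([squeeze_variance()]) and returns moderated t-statistics and two-sided
#' p-values for one coefficient. Features with missing values are fitted on
#' their complete cases.
#'
#' @param y Numeric matrix, features x samples (a single feature may be a
#'   vector).
#' @param design Design matrix, samples x terms (full rank).
#' @param coef Name or index of the tested coefficient (default: last).
#' @param d0 Optional forced prior df (0 = classical t; NULL = estimate).
#' @return Object of class `moderated_fit`; see [tidy.moderated_fit()].
#' @export
moderated_fit <- function(y, design, coef = ncol(design), d0 = NULL) {
  if (is.vector(y)) y <- matrix(y, nrow = 1)
  if (is.data.frame(y)) y <- as.matrix(y)
  n <- ncol(y)
  if (nrow(design) != n) abort("design rows must match samples (columns of y)")
  if (qr(design)$rank < ncol(design)) abort("design is not full rank")
  if (is.character(coef)) coef <- match(coef, colnames(design))
  G <- nrow(y)
  beta <- se_u <- s2 <- dfres <- rep(NA_real_, G)
  complete_all <- !anyNA(y)
  if (complete_all) {
    qr_x <- qr(design)
    cf <- qr.coef(qr_x, t(y))
    res <- t(y) - design %*% cf
    dfr <- n - ncol(design)
    s2 <- colSums(res^2) / dfr
    xtxi <- chol2inv(qr.R(qr_x))
    beta <- unname(cf[coef, ])
    s2 <- unname(s2)
    se_u <- rep(sqrt(xtxi[coef, coef]), G)
    dfres <- rep(dfr, G)
  } else {
    for (g in seq_len(G)) {
      ok <- !is.na(y[g, ]) & complete.cases(design)
      dfr <- sum(ok) - ncol(design)
      if (dfr < 1) next
      X <- design[ok, , drop = FALSE]
      fit <- lm.fit(X, y[g, ok])
      s2[g] <- sum(fit$residuals^2) / dfr
      xtxi <- chol2inv(qr.R(qr(X)))
      beta[g] <- fit$coefficients[coef]
      se_u[g] <- sqrt(xtxi[coef, coef])
      dfres[g] <- dfr
    }
  }
  sq <- squeeze_variance(s2, dfres, d0 = d0)
  df_total <- dfres + if (is.finite(sq$d0)) sq$d0 else 1e30
  t_mod <- beta / (sqrt(sq$s2_post) * se_u)
  p <- 2 * pt(-abs(t_mod), df_total)
  structure(
    list(
      feature = rownames(y) %||% as.character(seq_len(G)),
      coefficient = beta, stdev_unscaled = se_u, sigma2 = s2,
      df_residual = dfres, d0 = sq$d0, s0_2 = sq$s0_2,
      s2_post = sq$s2_post, t = t_mod, p_value = p,
      coef_name = colnames(design)[coef] %||% as.character(coef)
    ),
    class = "moderated_fit"
  )
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat("<moderated_fit> ", length(x$coefficient), " features; coefficient: ",
    x$coef_name, "\n  prior df d0 = ", format(x$d0),
    ", prior variance s0^2 = ", format(x$s0_2, digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a moderated fit
#'
#' @param x A `moderated_fit`.
#' @param ... Unused.
#' @return Tibble: `feature`, `estimate`, `sigma2`, `s2_post`,
#'   `df_residual`, `t_mod`, `p`, `adj_p` (BH within the fit).
#' @export
tidy.moderated_fit <- function(x, ...) {
  tibble::tibble(
    feature = x$feature, estimate = x$coefficient, sigma2 = x$sigma2,
    s2_post = x$s2_post, df_residual = x$df_residual,
    t_mod = x$t, p = x$p_value, adj_p = bh_adjust(x$p_value)
  )
}

#' One-row summary of a moderated fit
#' @param x A `moderated_fit`.
#' @param ... Unused.
#' @return Tibble with `n_features`, `d0`, `s0_2`, `coef_name`.
#' @export
glance.moderated_fit <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$coefficient), d0 = x$d0, s0_2 = x$s0_2,
    coef_name = x$coef_name
  )
}
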