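## Rank-based set enrichment (weighted Kolmogorov-Smirnov running sum):
## ranking metric -log10(p) * Pearson r, signed-maximum enrichment score,
## set-size-preserving permutation NES/p, BH within metal, top-k summaries.

#' Ranking metric for set enrichment
#'
#' `-log10(p) * r`: the signed evidence of a feature's correlation with the
#' target metal. p-values of 0 are floored at 1e-300 with a warning.
#'
#' @param p P-values in (0, 1].
#' @param r Pearson correlation coefficients in \[-1, 1\].
#' @return Metric values.
#' @export
#' @examples
#' rank_metric(0.01, 0.5) # 1.0
rank_metric <- function(p, r) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p must lie in [0, 1]")
  if (any(abs(r) > 1, na.rm = TRUE)) abort("r must lie in [-1, 1]")
  if (any(p == 0, na.rm = TRUE)) {
    warn("p-value(s) of 0 floored at 1e-300")
    p <- pmax(p, 1e-300)
  }
  -log10(p) * r
}

#' Build a ranked feature list for one metal
#'
#' Orders features by descending metric with a deterministic tie-break
#' (lexicographic feature id).
#'
#' @param assoc Tibble with columns `feature`, `r`, `p` (e.g. one metal's
#'   rows from [associate_features()]).
#' @return Tibble `feature`, `metric`, ordered.
#' @export
build_ranked_list <- function(assoc) {
  metric <- rank_metric(assoc$p, assoc$r)
  ord <- order(-metric, assoc$feature)
  tibble::tibble(feature = assoc$feature[ord], metric = metric[ord])
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list: set members ("hits") increment the running sum by
#' `|metric|^w / sum_hits |metric|^w`, non-members decrement by
#' `1 / (N - n_set)`. The enrichment score is the signed maximum deviation
#' from zero (positive taken on ties of absolute value); the leading edge is
#' the members at or before the maximum (at or after the minimum for a
#' negative score).
#'
#' @param ranked A ranked list from [build_ranked_list()].
#' @param members Character vector of set member feature ids.
#' @param w Weight exponent (default 1; `w = 0` gives the classical
#'   unweighted KS statistic).
#' @return List: `es`, `running` (the full running sum), `leading_edge`,
#'   `n_overlap`, `flag` (`"ok"`, `"not testable"` for a disjoint set,
#'   `"degenerate"` when the set spans the whole universe).
#' @export
enrichment_score <- function(ranked, members, w = 1) {
  N <- nrow(ranked)
  hit <- ranked$feature %in% members
  n_hit <- sum(hit)
  if (n_hit == 0) {
    return(list(
      es = NA_real_, running = rep(0, N), leading_edge = character(),
      n_overlap = 0L, flag = "not testable"
    ))
  }
  if (n_hit == N) {
    return(list(
      es = NA_real_, running = rep(0, N), leading_edge = character(),
      n_overlap = n_hit, flag = "degenerate"
    ))
  }
  wts <- abs(ranked$metric)^w
  wts_hit <- wts * hit
  if (sum(wts_hit) == 0) wts_hit[hit] <- 1 # all-zero hit metrics: unweighted
  step <- ifelse(hit, wts_hit / sum(wts_hit), -1 / (N - n_hit))
  running <- cumsum(step)
  i_max <- which.max(running)
  i_min <- which.min(running)
  # signed maximum deviation; positive on (numerical) ties of magnitude
  es <- if (abs(running[i_max]) >= abs(running[i_min]) - 1e-12) {
    running[i_max]
  } else {
    running[i_min]
  }
  leading <- if (es >= 0) {
    ranked$feature[hit & seq_len(N) <= i_max]
  } else {
    ranked$feature[hit & seq_len(N) >= i_min]
  }
  list(
    es = es, running = running, leading_edge = leading,
    n_overlap = n_hit, flag = "ok"
  )
}

# Null enrichment scores for random same-size sets, computed at hit
# positions only (the running sum attains its extrema immediately after a
# hit or immediately before one, so O(k log k) per permutation).
null_es <- function(metric, w, k, n_perm) {
  N <- length(metric)
  mw <- abs(metric)^w
  miss <- 1 / (N - k)
  vapply(seq_len(n_perm), function(i) {
    pos <- sort.int(sample.int(N, k))
    ws <- mw[pos]
    sw <- sum(ws)
    cw <- if (sw > 0) cumsum(ws) / sw else seq_len(k) / k
    drop_before <- (pos - seq_len(k)) * miss
    after <- cw - drop_before # value just after each hit
    before <- c(0, cw[-k]) - drop_before # value just before each hit
    hi <- max(after)
    lo <- min(before)
    if (abs(hi) >= abs(lo) - 1e-12) hi else lo
  }, numeric(1))
}

#' Permutation significance of an enrichment score
#'
#' The null distribution is the enrichment score of `n_perm` random sets of
#' the same size drawn from the ranked universe. `NES = ES / mean(|null ES|
#' of matching sign)` and
#' `p = (1 + #same-sign nulls at least as extreme) / (1 + #same-sign nulls)`.
#'
#' @param ranked Ranked list.
#' @param members Set members.
#' @param n_perm Number of permutations (>= 100).
#' @param w Weight exponent.
#' @param seed Optional seed (identical seed, identical result).
#' @param null Optional precomputed null ES vector (for sharing across
#'   same-size sets of one ranked list).
#' @return List: `es`, `nes`, `p`, `n_overlap`, `leading_edge`, `flag`.
#' @export
permutation_significance <- function(ranked, members, n_perm = 1000, w = 1,
                                     seed = NULL, null = NULL) {
  if (n_perm < 100) abort("n_perm must be >= 100")
  sc <- enrichment_score(ranked, members, w)
  if (sc$flag != "ok") {
    return(list(
      es = sc$es, nes = NA_real_, p = NA_real_,
      n_overlap = sc$n_overlap, leading_edge = sc$leading_edge, flag = sc$flag
    ))
  }
  if (is.null(null)) {
    if (!is.null(seed)) withr::local_seed(seed)
    null <- null_es(ranked$metric, w, sc$n_overlap, n_perm)
  }
  same <- null * sign(sc$es) > 0
  n_same <- sum(same)
  flag <- "ok"
  if (n_same == 0) flag <- "no same-sign permutations"
  nes <- if (n_same > 0) sc$es / mean(abs(null[same])) else NA_real_
  p <- (1 + sum(same & abs(null) >= abs(sc$es))) / (1 + n_same)
  list(
    es = sc$es, nes = nes, p = p, n_overlap = sc$n_overlap,
    leading_edge = sc$leading_edge, flag = flag
  )
}

#' Run set enrichment for every metal
#'
#' Builds one ranked list per metal from per-feature (r, p) associations,
#' scores every set with at least `min_size` members in the universe, and
#' BH-adjusts within each metal. Null distributions are shared across
#' same-size sets of a given ranked list (the permutation null depends only
#' on set size).
#'
#' @param feature_assoc Output of [associate_features()].
#' @param setdb Feature-set database ([read_gmt()]).
#' @param min_size Minimum overlap with the ranked universe (default 5).
#' @param n_perm Permutations per null distribution (default 1000).
#' @param w Weight exponent (default 1).
#' @param seed Seed for the permutation stream.
#' @param metals Restrict to these metals (default: all in `feature_assoc`).
#' @return Enrichment tibble of class `enrichment_result`: `metal`,
#'   `set_id`, `size`, `es`, `nes`, `p`, `adj_p`, `leading_edge`
#'   (semicolon-joined), `flag`.
#' @export
run_enrichment <- function(feature_assoc, setdb, min_size = 5, n_perm = 1000,
                           w = 1, seed = NULL, metals = NULL) {
  if (nrow(setdb) == 0) {
    return(structure(
      tibble::tibble(
        metal = character(), set_id = character(), size = integer(),
        es = double(), nes = double(), p = double(), adj_p = double(),
        leading_edge = character(), flag = character()
      ),
      class = c("enrichment_result", "tbl_df", "tbl", "data.frame")
    ))
  }
  if (!is.null(seed)) withr::local_seed(seed)
  metals <- metals %||% unique(feature_assoc$metal)
  out <- list()
  for (m in metals) {
    ranked <- build_ranked_list(feature_assoc[feature_assoc$metal == m, ])
    sizes <- vapply(
      setdb$members,
      function(mm) sum(ranked$feature %in% mm), integer(1)
    )
    keep <- sizes >= min_size & sizes < nrow(ranked)
    null_cache <- list()
    rows <- vector("list", sum(keep))
    j <- 0L
    for (i in which(keep)) {
      key <- as.character(sizes[i])
      if (is.null(null_cache[[key]])) {
        null_cache[[key]] <- null_es(ranked$metric, w, sizes[i], n_perm)
      }
      ps <- permutation_significance(ranked, setdb$members[[i]],
        n_perm = n_perm,
        w = w, null = null_cache[[key]]
      )
      j <- j + 1L
      rows[[j]] <- tibble::tibble(
        metal = m, set_id = setdb$set_id[i], size = sizes[i],
        es = ps$es, nes = ps$nes, p = ps$p,
        leading_edge = paste(ps$leading_edge, collapse = ";"),
        flag = ps$flag
      )
    }
    fam <- dplyr::bind_rows(rows)
    if (nrow(fam) > 0) fam$adj_p <- bh_adjust(fam$p)
    out[[m]] <- fam
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) > 0) {
    res <- dplyr::select(
      res, "metal", "set_id", "size", "es", "nes", "p",
      "adj_p", "leading_edge", "flag"
    )
  }
  class(res) <- c("enrichment_result", class(tibble::tibble()))
  res
}

#' Top-k enriched sets per metal
#'
#' @param res An `enrichment_result`.
#' @param k Sets per metal (default 3, as in top-3 summary panels).
#' @return The k most significant sets per metal (by adjusted, then raw p,
#'   then |NES|).
#' @export
top_enrichment <- function(res, k = 3) {
  res |>
    dplyr::group_by(.data$metal) |>
    dplyr::arrange(.data$adj_p, .data$p, dplyr::desc(abs(.data$nes)), .by_group = TRUE) |>
    dplyr::slice_head(n = k) |>
    dplyr::ungroup()
}
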