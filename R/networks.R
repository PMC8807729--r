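## Network assembly (threshold-filtered correlation networks, multi-layer
## integration) and cross-study concordance.

node_type_of <- function(id) {
  info <- metal_analytes()
  dplyr::case_when(
    id %in% info$analyte[info$role == "delta"] ~ "isotope",
    id %in% info$analyte ~ "metal",
    TRUE ~ "phenotype"
  )
}

assoc_to_edges <- function(assoc, layer = NULL) {
  if (nrow(assoc) == 0) {
    return(empty_edges())
  }
  tibble::tibble(
    from = assoc$feature_a, to = assoc$feature_b,
    weight = assoc$rho, sign = sign(assoc$rho), adj_p = assoc$adj_p,
    layer = layer %||% assoc$layer,
    organ = if ("organ" %in% names(assoc)) assoc$organ else NA_character_
  )
}

#' Enrichment results as metal-set edges
#'
#' @param res An `enrichment_result` table.
#' @param layer Edge layer label (default `"metal-set"`).
#' @return Edge tibble (weight = NES).
#' @export
enrichment_to_edges <- function(res, layer = "metal-set") {
  res <- res[res$flag == "ok" & !is.na(res$nes), ]
  tibble::tibble(
    from = res$metal, to = res$set_id,
    weight = res$nes, sign = sign(res$nes), adj_p = res$adj_p,
    layer = layer, organ = NA_character_
  )
}

edges_to_network <- function(edges, set_ids = character()) {
  ids <- unique(c(edges$from, edges$to))
  nodes <- tibble::tibble(
    id = sort(ids),
    type = ifelse(sort(ids) %in% set_ids, "feature_set", node_type_of(sort(ids)))
  )
  multilayer_network(nodes, edges)
}

#' Threshold-filtered correlation network
#'
#' One edge per association with `adj_p < edge_alpha`; weight is the
#' Spearman rho, sign its direction. Node ordering is deterministic
#' (lexicographic).
#'
#' @param assoc Association table from [associate_pairwise()].
#' @param edge_alpha Adjusted-p threshold for drawing an edge (default 0.05).
#' @return A `multilayer_network`.
#' @export
build_correlation_network <- function(assoc, edge_alpha = 0.05) {
  keep <- !is.na(assoc$adj_p) & assoc$adj_p < edge_alpha
  edges_to_network(assoc_to_edges(assoc[keep, ]))
}

#' Integrate metal, phenotype and enrichment layers into one network
#'
#' A node is admitted if it participates in at least one association with
#' `adj_p < node_alpha`; all edges with `adj_p < edge_alpha` among admitted
#' nodes are retained. Admitted nodes left isolated are dropped with a
#' message. Conflicting duplicate edges (same pair within a layer/organ
#' family) are an error.
#'
#' @param metal_edges,phenotype_edges Association tables
#'   ([associate_pairwise()]) or edge tibbles.
#' @param enrichment_edges An `enrichment_result` or edge tibble (optional).
#' @param node_alpha Node admission threshold (default 0.01).
#' @param edge_alpha Edge threshold (default 0.05).
#' @return A `multilayer_network`.
#' @export
integrate_layers <- function(metal_edges, phenotype_edges = NULL,
                             enrichment_edges = NULL,
                             node_alpha = 0.01, edge_alpha = 0.05) {
  as_edges <- function(x) {
    if (is.null(x) || nrow(x) == 0) {
      return(empty_edges())
    }
    if (inherits(x, "enrichment_result")) {
      return(enrichment_to_edges(x))
    }
    if (all(c("from", "to", "adj_p") %in% names(x))) {
      return(tibble::as_tibble(x))
    }
    assoc_to_edges(x)
  }
  edges <- dplyr::bind_rows(
    as_edges(metal_edges),
    as_edges(phenotype_edges),
    as_edges(enrichment_edges)
  )
  edges <- edges[!is.na(edges$adj_p), ]
  key <- edge_key(edges)
  if (anyDuplicated(key) > 0) {
    abort(paste0(
      "conflicting duplicate edge(s): ",
      paste(head(unique(key[duplicated(key)]), 3), collapse = "; ")
    ), class = "metalloscope_schema_error")
  }
  admitted <- unique(c(
    edges$from[edges$adj_p < node_alpha],
    edges$to[edges$adj_p < node_alpha]
  ))
  kept <- edges[edges$adj_p < edge_alpha &
    edges$from %in% admitted & edges$to %in% admitted, ]
  isolated <- setdiff(admitted, c(kept$from, kept$to))
  if (length(isolated) > 0) {
    inform(paste0(
      length(isolated), " admitted node(s) isolated and dropped: ",
      paste(head(isolated, 5), collapse = ", ")
    ))
  }
  set_ids <- unique(edges$to[edges$layer == "metal-set"])
  edges_to_network(kept, set_ids = set_ids)
}

#' Cross-study concordance of metal statistics
#'
#' Computes the same statistic in two studies on identically normalized
#' data — per organ either the Spearman rho of each metal with age
#' (`mode = "age_effects"`) or all pairwise metal-metal Spearman rhos
#' (`mode = "metal_pairs"`) — pairs them by analyte (or analyte pair), and
#' summarizes the agreement: Pearson and Spearman concordance r and the OLS
#' regression of study B on study A with 95% confidence intervals.
#'
#' @param mA,mB Metallome tables sharing >= 3 analytes and the organs used.
#' @param mode `"age_effects"` or `"metal_pairs"`.
#' @param normalization Passed to [normalize_metals()] for both studies
#'   (default `"total"`).
#' @param organs Organs to compare (default: organs common to both).
#' @return Object of class `concordance_report`: `pairs` (per-organ paired
#'   statistics) and `summary` (per organ and pooled).
#' @export
cross_study_concordance <- function(mA, mB, mode = c("age_effects", "metal_pairs"),
                                    normalization = c("total", "na", "none"),
                                    organs = NULL) {
  mode <- match.arg(mode)
  normalization <- match.arg(normalization)
  common <- intersect(present_analytes(mA), present_analytes(mB))
  if (length(common) < 3) abort("studies share fewer than 3 analytes")
  organs <- organs %||% intersect(unique(mA$organ), unique(mB$organ))
  if (length(organs) == 0) abort("studies share no organs")
  mA <- normalize_metals(mA, normalization)
  mB <- normalize_metals(mB, normalization)

  study_stats <- function(m) {
    res <- list()
    for (o in organs) {
      dat <- m[m$organ == o, ]
      if (mode == "age_effects") {
        res[[o]] <- tibble::tibble(
          organ = o, id = common,
          stat = vapply(
            common,
            function(a) suppressWarnings(spearman_rho(dat[[a]], dat$age_months)),
            numeric(1)
          )
        )
      } else {
        idx <- which(upper.tri(diag(length(common))), arr.ind = TRUE)
        res[[o]] <- tibble::tibble(
          organ = o,
          id = paste(common[idx[, 1]], common[idx[, 2]], sep = "~"),
          stat = vapply(
            seq_len(nrow(idx)),
            function(k) {
              suppressWarnings(
                spearman_rho(dat[[common[idx[k, 1]]]], dat[[common[idx[k, 2]]]])
              )
            },
            numeric(1)
          )
        )
      }
    }
    dplyr::bind_rows(res)
  }
  pairs <- dplyr::inner_join(
    dplyr::rename(study_stats(mA), stat_a = "stat"),
    dplyr::rename(study_stats(mB), stat_b = "stat"),
    by = c("organ", "id")
  )
  pairs <- pairs[complete.cases(pairs[, c("stat_a", "stat_b")]), ]

  summarize_one <- function(df, label) {
    if (nrow(df) < 3) {
      return(tibble::tibble(
        organ = label, n = nrow(df), r_pearson = NA_real_,
        r_spearman = NA_real_, slope = NA_real_, intercept = NA_real_,
        slope_lo = NA_real_, slope_hi = NA_real_
      ))
    }
    fit <- lm(stat_b ~ stat_a, data = df)
    ci <- suppressWarnings(confint(fit))
    tibble::tibble(
      organ = label, n = nrow(df),
      r_pearson = cor(df$stat_a, df$stat_b),
      r_spearman = spearman_rho(df$stat_a, df$stat_b),
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      slope_lo = ci[2, 1], slope_hi = ci[2, 2]
    )
  }
  summary <- dplyr::bind_rows(
    purrr::imap(split(pairs, pairs$organ), summarize_one) |> dplyr::bind_rows(),
    summarize_one(pairs, "(pooled)")
  )
  structure(
    list(pairs = pairs, summary = summary, mode = mode, normalization = normalization),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report> mode = ", x$mode, ", normalization = ",
    x$normalization, "\n",
    sep = ""
  )
  print(x$summary)
  invisible(x)
}

#' Tidy a concordance report (the paired statistics)
#' @param x A `concordance_report`.
#' @param ... Unused.
#' @return The `pairs` tibble.
#' @export
tidy.concordance_report <- function(x, ...) x$pairs

#' Glance at a concordance report (the pooled summary row)
#' @param x A `concordance_report`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.concordance_report <- function(x, ...) {
  x$summary[x$summary$organ == "(pooled)", ]
}
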