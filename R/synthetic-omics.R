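## Omics (metabolome/proteome) generator with planted set enrichments.

#' Default feature-set database for a synthetic omics layer
#'
#' Builds a GMT-style database over a synthetic feature universe: one
#' planted set per truth enrichment (consecutive feature blocks) plus an
#' equal number of decoy sets drawn from the untouched background block.
#' Assignment is deterministic given the truth and configuration.
#'
#' @param truth A [default_truth()] ground truth.
#' @param cfg A [sim_config()] (supplies the universe size `n_features`).
#' @param layer `"metabolome"` or `"proteome"`.
#' @return A feature-set tibble as from [read_gmt()], with the full feature
#'   universe in `attr(, "universe")`.
#' @export
default_feature_sets <- function(truth, cfg = sim_config(), layer = c("metabolome", "proteome")) {
  layer <- match.arg(layer)
  prefix <- if (layer == "metabolome") "met" else "prot"
  enr <- truth$enrichments[truth$enrichments$layer == layer, ]
  need <- 2 * sum(enr$size)
  if (need > cfg$n_features) {
    abort(paste0(
      "n_features (", cfg$n_features, ") too small for planted + decoy sets (",
      need, " members)"
    ))
  }
  universe <- sprintf("%s_%04d", prefix, seq_len(cfg$n_features))
  pos <- 0L
  planted <- vector("list", nrow(enr))
  for (i in seq_len(nrow(enr))) {
    planted[[i]] <- universe[pos + seq_len(enr$size[i])]
    pos <- pos + enr$size[i]
  }
  decoys <- vector("list", nrow(enr))
  for (i in seq_len(nrow(enr))) {
    decoys[[i]] <- universe[pos + seq_len(enr$size[i])]
    pos <- pos + enr$size[i]
  }
  db <- tibble::tibble(
    set_id = c(enr$set_id, sprintf("DECOY_%s_%02d", toupper(prefix), seq_len(nrow(enr)))),
    description = c(
      paste0("planted: tracks ", enr$target, " at strength ", enr$strength),
      rep("decoy: independent background features", nrow(enr))
    ),
    members = c(planted, decoys)
  )
  attr(db, "universe") <- universe
  db
}

#' Generate a synthetic omics matrix with planted enrichments
#'
#' Features belonging to a planted set are generated as
#' `strength * z(target analyte) + sqrt(1 - strength^2) * noise` across the
#' samples of one organ, so their Pearson correlation with the target is
#' approximately `strength`; all other features are independent standard
#' normal intensities (log scale).
#'
#' @param truth Ground truth (supplies the planted enrichment spec).
#' @param metallome Metallome table from [generate_metallome()].
#' @param setdb Feature-set database containing the planted sets; its
#'   `universe` attribute (or the union of members) defines the features.
#' @param cfg A [sim_config()].
#' @param layer `"metabolome"` or `"proteome"`.
#' @param organ Organ whose samples carry the omics layer (default liver).
#' @param seed Optional seed.
#' @return A wide tibble: `sample_id` plus one column per feature, with the
#'   layer tag in `attr(, "layer")`.
#' @export
generate_omics <- function(truth, metallome, setdb, cfg = sim_config(),
                           layer = c("metabolome", "proteome"),
                           organ = "liver", seed = NULL) {
  layer <- match.arg(layer)
  if (!is.null(seed)) withr::local_seed(seed)
  enr <- truth$enrichments[truth$enrichments$layer == layer, ]
  if (any(abs(enr$strength) > 1)) abort("enrichment strength outside [-1, 1]")
  missing_sets <- setdiff(enr$set_id, setdb$set_id)
  if (length(missing_sets) > 0) {
    abort(paste0(
      "planted set(s) absent from set database: ",
      paste(missing_sets, collapse = ", ")
    ))
  }
  universe <- attr(setdb, "universe") %||% sort(unique(unlist(setdb$members)))
  samples <- metallome[metallome$organ == organ, ]
  n <- nrow(samples)
  if (n < 3) abort("need at least 3 samples in the omics organ")

  x <- matrix(rnorm(n * length(universe)),
    nrow = n,
    dimnames = list(NULL, universe)
  )
  for (i in seq_len(nrow(enr))) {
    members <- setdb$members[[which(setdb$set_id == enr$set_id[i])]]
    if (length(members) == 1) {
      inform(paste0("planted set of size 1: ", enr$set_id[i]))
    }
    target <- samples[[enr$target[i]]]
    zt <- as.numeric(scale(target))
    s <- enr$strength[i]
    for (m in members) {
      x[, m] <- s * zt + sqrt(1 - s^2) * x[, m]
    }
  }
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = samples$sample_id),
    tibble::as_tibble(x)
  )
  attr(out, "layer") <- layer
  out
}
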