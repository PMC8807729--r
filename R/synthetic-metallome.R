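## Metallome + phenotype generator.
##
## Model per animal a, organ o, analyte j with factor loadings lambda_j
## (own-group loading sqrt(rho_g) plus any cross-group loadings):
##   z_aoj = sum_f lambda_jf L_aof + sqrt(1 - |lambda_j|^2) e_aoj,  L, e ~ N(0,1)
##   concentrations:  x = baseline * exp(slope (age - age_min) + cv * z)
##   deltas:          x = baseline + slope (age - age_min) + cv * z
##   d66Zn additionally receives coupling[organ] * z_Zn (Zn routing link)
##   measured = x * exp(sd_meas * e')   (concentrations, multiplicative)
##            = x + sd_meas * e'        (deltas, additive)
## Phenotypes are linear combinations of the *biological* standardized
## deviations z (the biology exists whether or not the organ was assayed),
## plus independent noise.

#' Generate a synthetic metallome and phenotype table
#'
#' Draws a full study from a ground truth and design configuration:
#' log-normal concentrations around organ baselines with group-correlated
#' latent factors, normal isotope deltas, linear age trends applied before
#' measurement noise, and per-animal phenotypes loaded on designated
#' analytes. Each organ is assayed on `cfg$n_per_group` animals per age.
#'
#' @param truth A [default_truth()]-style ground truth.
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed (defaults to `cfg$seed`).
#' @return A list with `metallome` (one row per organ sample; columns
#'   `sample_id`, `animal_id`, `organ`, `age_months`, analytes) and
#'   `phenotypes` (one row per animal, keyed by `animal_id`). Both carry a
#'   provenance attribute (seed and truth hash).
#' @export
generate_metallome <- function(truth, cfg = sim_config(), seed = cfg$seed) {
  validate_truth(truth)
  if (!is.null(seed)) withr::local_seed(seed)

  ages <- cfg$ages
  n_animals <- cfg$n_animals
  # split animals across ages as evenly as possible (e.g. 49 -> 17/16/16)
  age_of <- sort(rep_len(ages, n_animals))
  animals <- tibble::tibble(
    animal_id = sprintf("M%03d", seq_len(n_animals)),
    age_months = age_of
  )

  grid <- tidyr::expand_grid(animals, organ = cfg$organs)
  n_ao <- nrow(grid)
  analytes <- metal_analytes()$analyte

  lam <- truth_loadings(truth)
  L <- matrix(rnorm(n_ao * ncol(lam)),
    nrow = n_ao,
    dimnames = list(NULL, colnames(lam))
  )
  eps <- matrix(rnorm(n_ao * length(analytes)),
    nrow = n_ao,
    dimnames = list(NULL, analytes)
  )
  # z has unit variance: factor loadings plus independent uniqueness
  uniq <- sqrt(1 - rowSums(lam^2))
  z <- L %*% t(lam[analytes, , drop = FALSE]) +
    eps * matrix(uniq[analytes], n_ao, length(analytes), byrow = TRUE)
  colnames(z) <- analytes

  base_wide <- truth$baselines |>
    dplyr::select("organ", "analyte", "baseline") |>
    tidyr::pivot_wider(names_from = "analyte", values_from = "baseline")
  cv_wide <- truth$baselines |>
    dplyr::select("organ", "analyte", "cv") |>
    tidyr::pivot_wider(names_from = "analyte", values_from = "cv")
  slope_of <- function(organ, analyte) {
    s <- truth$age_slopes
    hit <- s$organ == organ & s$analyte == analyte
    if (any(hit)) s$slope[hit][1] else 0
  }

  roles <- setNames(metal_analytes()$role, metal_analytes()$analyte)
  age_rel <- grid$age_months - min(ages)
  orow <- match(grid$organ, base_wide$organ)
  bio <- matrix(NA_real_, n_ao, length(analytes), dimnames = list(NULL, analytes))
  for (a in analytes) {
    base <- base_wide[[a]][orow]
    cv <- cv_wide[[a]][orow]
    slope <- vapply(
      seq_len(n_ao),
      function(i) slope_of(grid$organ[i], a), numeric(1)
    )
    if (roles[[a]] == "concentration") {
      bio[, a] <- base * exp(slope * age_rel + cv * z[, a])
    } else {
      bio[, a] <- base + slope * age_rel + cv * z[, a]
    }
  }
  # d66Zn tracks (inversely) the biological Zn deviation in coupled organs
  coup <- setNames(truth$zn_coupling$coupling, truth$zn_coupling$organ)
  bio[, "d66Zn"] <- bio[, "d66Zn"] + unname(coup[grid$organ]) * z[, "Zn"]

  meas_e <- matrix(rnorm(n_ao * length(analytes)),
    nrow = n_ao,
    dimnames = list(NULL, analytes)
  )
  meas <- bio
  sd_conc <- cfg$conc_noise_2sd / 2
  sd_delta <- cfg$delta_noise_2sd / 2
  for (a in analytes) {
    if (roles[[a]] == "concentration") {
      meas[, a] <- bio[, a] * exp(sd_conc * meas_e[, a])
    } else {
      meas[, a] <- bio[, a] + sd_delta * meas_e[, a]
    }
  }

  # which animals are assayed for each organ x age
  keep <- logical(n_ao)
  for (o in cfg$organs) {
    for (ag in ages) {
      idx <- which(grid$organ == o & grid$age_months == ag)
      take <- if (length(idx) <= cfg$n_per_group) idx else sort(sample(idx, cfg$n_per_group))
      keep[take] <- TRUE
    }
  }

  metallome <- dplyr::bind_cols(
    tibble::tibble(
      sample_id = paste(grid$animal_id, grid$organ, sep = "_"),
      animal_id = grid$animal_id,
      organ = grid$organ,
      age_months = grid$age_months
    ),
    tibble::as_tibble(meas)
  )[keep, ]

  phenotypes <- generate_phenotypes(truth, animals, grid, z)

  prov <- list(seed = seed, truth_hash = rlang::hash(unclass(truth)))
  attr(metallome, "provenance") <- prov
  attr(phenotypes, "provenance") <- prov
  list(metallome = metallome, phenotypes = phenotypes)
}

generate_phenotypes <- function(truth, animals, grid, z) {
  loadings <- truth$phenotype_loadings
  scales <- truth$phenotype_scales
  out <- tibble::tibble(
    animal_id = animals$animal_id,
    age_months = animals$age_months
  )
  for (k in seq_len(nrow(scales))) {
    ph <- scales$phenotype[k]
    ld <- loadings[loadings$phenotype == ph, ]
    signal <- numeric(nrow(animals))
    for (j in seq_len(nrow(ld))) {
      rows <- match(paste(animals$animal_id, ld$organ[j]), paste(grid$animal_id, grid$organ))
      signal <- signal + ld$loading[j] * z[rows, ld$analyte[j]]
    }
    noise_sd <- sqrt(max(0.25, 1 - sum(ld$loading^2)))
    val <- scales$base[k] + scales$scale[k] * (signal + noise_sd * rnorm(nrow(animals)))
    out[[ph]] <- val
  }
  out
}
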