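## Ground truth and configuration for the synthetic study generator.
## The defaults emulate the reference design: 49 male mice at 6/16/24 months,
## five organs, 15 metal concentrations + d65Cu/d66Zn, organ-specific
## baselines, a small number of planted age trends and phenotype loadings,
## four correlated metal groups, and planted metabolite/protein set
## enrichments in the liver.

# organ x analyte baseline concentrations (ug/g dry mass) and delta
# baselines (per mil). Values are realistic order-of-magnitude tissue
# compositions for mouse; they set the scale, not a claim about any dataset.
default_baselines <- function() {
  organs <- metal_organs() # brain heart kidney liver muscle
  base <- c(
    K  = NA, Mg = NA, Na = NA, P = NA, S = NA, Ca = NA, Fe = NA, Cu = NA,
    Rb = NA, Zn = NA, Se = NA, Co = NA, Mo = NA, Cd = NA, Mn = NA
  )
  tab <- rbind(
    K     = c(12000, 9000, 8500, 9500, 13000),
    Mg    = c(500, 800, 700, 650, 900),
    Na    = c(4500, 2800, 6500, 2000, 1500),
    P     = c(10000, 8000, 9000, 9500, 8500),
    S     = c(6000, 7000, 7500, 7000, 8000),
    Ca    = c(150, 180, 350, 120, 160),
    Fe    = c(60, 250, 250, 300, 40),
    Cu    = c(20, 20, 25, 15, 5),
    Rb    = c(8, 12, 10, 15, 12),
    Zn    = c(45, 70, 90, 100, 50),
    Se    = c(0.5, 1.0, 4.0, 2.5, 0.8),
    Co    = c(0.02, 0.04, 0.08, 0.15, 0.02),
    Mo    = c(0.2, 0.4, 1.2, 2.5, 0.1),
    Cd    = c(0.02, 0.05, 0.5, 0.3, 0.01),
    Mn    = c(1.5, 2.0, 3.5, 8.0, 0.8),
    d65Cu = c(0.20, -0.10, 0.60, 0.00, -0.30),
    d66Zn = c(0.20, -0.40, 0.40, -0.10, -0.60)
  )
  colnames(tab) <- organs
  out <- tibble::as_tibble(tab, rownames = "analyte") |>
    tidyr::pivot_longer(-"analyte", names_to = "organ", values_to = "baseline")
  roles <- metal_analytes()
  out <- dplyr::left_join(out, roles, by = "analyte")
  # cv: biological spread; log-sd for concentrations, per-mil sd for deltas
  out$cv <- ifelse(out$role == "concentration", 0.12, 0.08)
  out[, c("organ", "analyte", "role", "baseline", "cv")]
}

default_age_slopes <- function() {
  tibble::tribble(
    ~organ, ~analyte, ~slope,
    # log-units per month for concentrations
    "brain", "Fe", 0.025,
    "brain", "Cu", 0.025,
    "brain", "Ca", 0.012,
    "brain", "Co", 0.012,
    "brain", "Rb", -0.012,
    "muscle", "Rb", -0.012,
    "kidney", "Rb", -0.012,
    "kidney", "Cd", 0.025,
    # per mil per month for deltas
    "liver", "d65Cu", -0.022
  )
}

default_groups <- function() {
  tibble::tibble(
    analyte = c(
      "S", "Mg", "P", "Rb", "K", "Cu", "Zn", "Mn", # group I
      "Na", "Ca", # group II
      "d65Cu", # group III
      "Fe", "d66Zn" # group IV
    ),
    group = c(rep("I", 8), rep("II", 2), "III", rep("IV", 2)),
    rho = c(rep(0.75, 8), rep(0.40, 2), 0, rep(0.7, 2)),
    loading_sign = 1
  )
}

# cross-group factor loadings: Ca and Na (and more weakly Fe) run against
# the Group I axis, mirroring the anticorrelation of Ca/Fe with other
# elements seen in organ correlation networks; Co and Cd track the
# metabolic (I) and electrolyte (II) axes moderately. Se and Mo carry no
# structure at all (null analytes for calibration).
default_cross_loadings <- function() {
  tibble::tribble(
    ~analyte, ~factor, ~loading,
    "Na", "I", -0.55,
    "Ca", "I", -0.55,
    "Fe", "I", -0.35,
    "Co", "I", 0.50,
    "Cd", "II", 0.45
  )
}

default_phenotype_loadings <- function() {
  tibble::tribble(
    ~phenotype, ~organ, ~analyte, ~loading,
    "body_weight_g", "liver", "d65Cu", -0.85,
    "fat_pct", "liver", "d65Cu", -0.60,
    "fat_pct", "liver", "Fe", 0.50,
    "ipgtt_auc", "liver", "d65Cu", -0.50,
    "muscle_ros", "liver", "Fe", 0.60,
    "complex1_activity", "liver", "Fe", 0.50,
    "complex1_activity", "liver", "d65Cu", 0.50,
    "complex4_activity", "liver", "Ca", 0.70,
    "vo2_increase", "kidney", "Fe", 0.60,
    "mtdna_ratio", "liver", "Fe", -0.50,
    "mtdna_ratio", "liver", "d65Cu", -0.50
  )
}

default_phenotype_scales <- function() {
  tibble::tribble(
    ~phenotype, ~base, ~scale,
    "body_weight_g", 38, 4,
    "fat_pct", 20, 5,
    "ipgtt_auc", 1500, 300,
    "muscle_ros", 10, 2,
    "complex1_activity", 100, 20,
    "complex4_activity", 100, 20,
    "vo2_increase", 30, 6,
    "mtdna_ratio", 1.0, 0.2
  )
}

default_enrichments <- function(strength = 0.8, size = 12L) {
  analytes <- metal_analytes()$analyte
  dplyr::bind_rows(
    tibble::tibble(
      set_id = paste0(toupper(analytes), "_RESPONSIVE_MET"),
      target = analytes, strength = strength, size = size,
      layer = "metabolome"
    ),
    tibble::tibble(
      set_id = paste0(toupper(analytes), "_RESPONSIVE_PROT"),
      target = analytes, strength = strength, size = size,
      layer = "proteome"
    )
  )
}

default_isotope_run_spec <- function() {
  list(
    samples = tibble::tribble(
      ~label, ~element, ~delta_true, ~n_replicates,
      "liver_pool", "Cu", -0.30, 3L,
      "brain_pool", "Cu", 0.20, 3L,
      "liver_pool", "Zn", -0.10, 3L,
      "kidney_pool", "Zn", 0.40, 3L
    ),
    # reference materials carried in every sequence, with certified deltas
    references = tibble::tribble(
      ~label, ~element, ~delta_true, ~n_replicates,
      "OEP", "Cu", -1.10, 3L,
      "SRM-1577c", "Cu", 0.43, 4L,
      "OEP", "Zn", 0.76, 3L,
      "SRM-1577c", "Zn", -0.18, 4L
    ),
    f0 = 1.5, # mass-bias exponent at run start
    f_slope = -2e-5, # drift of the exponent per second (linear default)
    cycle_interval_s = 60,
    # clean standard solutions repeat far better than full sample
    # preparations: long-term 2SD on pure reference solutions (per mil)
    reference_noise_2sd = 0.06
  )
}

#' Ground truth for the synthetic study
#'
#' Bundles every planted parameter the generators use: organ-by-analyte
#' baselines and coefficients of variation, age slopes (log-units per month
#' for concentrations, per-mil per month for isotope deltas), correlated
#' metal groups (I: S, Mg, P, Rb, K, Cu, Zn, Mn; II: Na, Ca; III: d65Cu;
#' IV: Fe, d66Zn) with within-group correlation `rho`, a negative coupling
#' of d66Zn to Zn concentration in liver/brain/muscle/heart, phenotype
#' loadings (e.g. body weight driven negatively by liver d65Cu), planted
#' feature-set enrichments, and the bracketed isotope-run layout.
#'
#' @param planted If `FALSE`, all age slopes, phenotype loadings, group
#'   correlations, Zn coupling and enrichment strengths are zeroed — a
#'   structure-free null truth for calibration tests.
#' @return A list of class `ground_truth`.
#' @seealso [sim_config()], [simulate_study()]
#' @export
default_truth <- function(planted = TRUE) {
  truth <- list(
    baselines = default_baselines(),
    age_slopes = default_age_slopes(),
    groups = default_groups(),
    cross_loadings = default_cross_loadings(),
    # per-mil shift of d66Zn per SD of (log) Zn; kidney decoupled
    zn_coupling = tibble::tibble(
      organ = metal_organs(),
      coupling = c(-0.05, -0.05, 0, -0.05, -0.05)
    ),
    phenotype_loadings = default_phenotype_loadings(),
    phenotype_scales = default_phenotype_scales(),
    enrichments = default_enrichments(),
    isotope_runs = default_isotope_run_spec()
  )
  if (!planted) {
    truth$age_slopes <- truth$age_slopes[0, ]
    truth$groups$rho <- 0
    truth$cross_loadings <- truth$cross_loadings[0, ]
    truth$zn_coupling$coupling <- 0
    truth$phenotype_loadings$loading <- 0
    truth$enrichments$strength <- 0
  }
  structure(truth, class = "ground_truth")
}

# analyte x factor loading matrix: sign * sqrt(rho) on the own-group factor
# plus any cross-group loadings
truth_loadings <- function(truth) {
  analytes <- metal_analytes()$analyte
  factors <- unique(c(truth$groups$group, truth$cross_loadings$factor))
  lam <- matrix(0, length(analytes), length(factors),
    dimnames = list(analytes, factors)
  )
  g <- truth$groups
  for (k in seq_len(nrow(g))) {
    lam[g$analyte[k], g$group[k]] <-
      g$loading_sign[k] * sqrt(max(g$rho[k], 0))
  }
  cl <- truth$cross_loadings
  for (k in seq_len(nrow(cl))) {
    lam[cl$analyte[k], cl$factor[k]] <- lam[cl$analyte[k], cl$factor[k]] + cl$loading[k]
  }
  lam
}

#' Validate a ground-truth object
#'
#' @param truth A `ground_truth` list.
#' @return `truth`, invisibly validated (errors on violation).
#' @export
validate_truth <- function(truth) {
  b <- truth$baselines
  if (any(b$cv < 0)) abort("baseline CVs must be nonnegative")
  if (any(b$baseline[b$role == "concentration"] < 0, na.rm = TRUE)) {
    abort("concentration baselines must be nonnegative")
  }
  g <- truth$groups
  if (any(abs(g$rho) >= 1)) abort("group correlations must satisfy |rho| < 1")
  # correlation induced by one latent factor per group: a negative rho
  # cannot make >= 3 analytes mutually negatively correlated
  bad <- g |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), rho = .data$rho[1], .groups = "drop") |>
    dplyr::filter(.data$rho < 0, .data$n > 2)
  if (nrow(bad) > 0) {
    abort(paste0(
      "group(s) not positive-definite under a single latent factor: ",
      paste(bad$group, collapse = ", ")
    ))
  }
  lam <- truth_loadings(truth)
  comm <- rowSums(lam^2)
  if (any(comm >= 1)) {
    abort(paste0(
      "total factor loading squared >= 1 (not positive-definite) for: ",
      paste(rownames(lam)[comm >= 1], collapse = ", ")
    ))
  }
  if (any(abs(truth$enrichments$strength) > 1)) {
    abort("enrichment strengths must lie in [-1, 1]")
  }
  if (any(truth$phenotype_loadings$analyte %in% setdiff(
    truth$phenotype_loadings$analyte, metal_analytes()$analyte
  ))) {
    abort("phenotype loading on unknown analyte")
  }
  invisible(truth)
}

#' Configuration of the synthetic study design
#'
#' @param n_animals Total animals (default 49, split as evenly as possible
#'   across ages).
#' @param n_per_group Animals assayed per organ-by-age cell (default 16,
#'   i.e. essentially every animal contributes every organ, as in the
#'   reference design; smaller values measure each organ on a per-age
#'   subset of the animals).
#' @param ages Ages in months (default 6, 16, 24).
#' @param organs Organs to simulate.
#' @param conc_noise_2sd Measurement noise on concentrations as a 2SD
#'   fraction (default 0.10, i.e. 10%).
#' @param delta_noise_2sd Measurement noise on isotope deltas, 2SD in
#'   per mil (default 0.12).
#' @param n_features Features per omics layer (default 500).
#' @param seed Integer seed used by [simulate_study()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_animals = 49L, n_per_group = 16L,
                       ages = c(6, 16, 24), organs = metal_organs(),
                       conc_noise_2sd = 0.10, delta_noise_2sd = 0.12,
                       n_features = 500L, seed = NULL) {
  if (n_per_group < 3) abort("n_per_group must be >= 3")
  if (conc_noise_2sd < 0 || delta_noise_2sd < 0) {
    abort("noise parameters must be nonnegative")
  }
  if (length(ages) < 2) abort("need at least two ages")
  if (n_animals < n_per_group * length(ages)) {
    abort("n_animals too small for n_per_group animals per age")
  }
  structure(
    list(
      n_animals = as.integer(n_animals), n_per_group = as.integer(n_per_group),
      ages = sort(ages), organs = organs,
      conc_noise_2sd = conc_noise_2sd, delta_noise_2sd = delta_noise_2sd,
      n_features = as.integer(n_features), seed = seed
    ),
    class = "sim_config"
  )
}
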