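## Isotope-ratio data reduction: delta computation, exponential-law mass-bias
## correction via elemental doping, standard-sample bracketing, QC.

# isotope masses (unified atomic mass units, standard atomic-mass tables)
ISOTOPE_MASSES <- c(
  Cu63 = 62.929597, Cu65 = 64.927790,
  Zn64 = 63.929142, Zn66 = 65.926034
)

# reference standard heavy/light ratios: 65Cu/63Cu of SRM 976 and
# 66Zn/64Zn of JMC-Lyon (conventional values; deltas are relative anyway)
STANDARD_RATIOS <- c(Cu = 0.44563, Zn = 0.56502)

#' Mass-bias model for a Cu or Zn isotope run
#'
#' Cu solutions are doped with Zn of known isotope composition and vice
#' versa; the dopant's measured ratio gives the instantaneous exponential
#' mass-bias exponent, which is transferred to the analyte pair (equal
#' exponent for both elements in the same run).
#'
#' @param element `"Cu"` (65/63 pair, Zn dopant) or `"Zn"` (66/64 pair,
#'   Cu dopant).
#' @return A list with analyte/dopant masses, the dopant's certified true
#'   ratio and the bracketing standard's ratio.
#' @export
mass_bias_model <- function(element = c("Cu", "Zn")) {
  element <- match.arg(element)
  if (element == "Cu") {
    list(
      element = "Cu", delta_name = "d65Cu",
      m_heavy = ISOTOPE_MASSES[["Cu65"]], m_light = ISOTOPE_MASSES[["Cu63"]],
      dopant = "Zn",
      dopant_m_heavy = ISOTOPE_MASSES[["Zn66"]],
      dopant_m_light = ISOTOPE_MASSES[["Zn64"]],
      dopant_true = STANDARD_RATIOS[["Zn"]],
      r_standard = STANDARD_RATIOS[["Cu"]]
    )
  } else {
    list(
      element = "Zn", delta_name = "d66Zn",
      m_heavy = ISOTOPE_MASSES[["Zn66"]], m_light = ISOTOPE_MASSES[["Zn64"]],
      dopant = "Cu",
      dopant_m_heavy = ISOTOPE_MASSES[["Cu65"]],
      dopant_m_light = ISOTOPE_MASSES[["Cu63"]],
      dopant_true = STANDARD_RATIOS[["Cu"]],
      r_standard = STANDARD_RATIOS[["Zn"]]
    )
  }
}

#' Per-mil delta of a sample ratio against a standard ratio
#'
#' `delta = (r_sample / r_standard - 1) * 1000`, the conventional
#' delta-notation for heavy/light isotope ratios (e.g. 65Cu/63Cu against
#' SRM 976, 66Zn/64Zn against JMC-Lyon).
#'
#' @param r_sample,r_standard Positive isotope ratios.
#' @return Delta in per mil.
#' @export
#' @examples
#' compute_delta(1.001, 1) # +1 per mil
compute_delta <- function(r_sample, r_standard) {
  if (any(r_sample <= 0) || any(r_standard <= 0)) {
    abort("isotope ratios must be positive", class = "metalloscope_domain_error")
  }
  (r_sample / r_standard - 1) * 1000
}

#' Estimate the exponential-law mass-bias exponent from a doped element
#'
#' The sign convention is pinned operationally: applying [correct_ratio()]
#' with the returned exponent to the dopant's measured ratio recovers its
#' certified true ratio exactly, i.e. `r_meas = r_true * (m_h/m_l)^(-f)` and
#' `f = log(r_true / r_meas) / log(m_h / m_l)`.
#'
#' @param doped_meas Measured dopant ratio (heavy/light).
#' @param doped_true Certified dopant ratio.
#' @param m_heavy,m_light Dopant isotope masses.
#' @return The fractionation exponent `f`.
#' @export
estimate_mass_bias <- function(doped_meas, doped_true, m_heavy, m_light) {
  if (any(doped_meas <= 0) || any(doped_true <= 0)) {
    abort("ratios must be positive", class = "metalloscope_domain_error")
  }
  if (m_heavy <= 0 || m_light <= 0 || m_heavy == m_light) {
    abort("masses must be positive and unequal", class = "metalloscope_domain_error")
  }
  log(doped_true / doped_meas) / log(m_heavy / m_light)
}

#' Correct a measured ratio for instrumental mass bias
#'
#' `r_corrected = r_meas * (m_heavy/m_light)^f`, with `f` estimated on the
#' dopant pair ([estimate_mass_bias()]) and transferred to the analyte's own
#' mass pair.
#'
#' @param r_meas Measured analyte ratio.
#' @param f Fractionation exponent.
#' @param m_heavy,m_light Analyte isotope masses.
#' @return Corrected ratio.
#' @export
correct_ratio <- function(r_meas, f, m_heavy, m_light) {
  if (any(r_meas <= 0)) {
    abort("ratios must be positive", class = "metalloscope_domain_error")
  }
  if (m_heavy <= 0 || m_light <= 0 || m_heavy == m_light) {
    abort("masses must be positive and unequal", class = "metalloscope_domain_error")
  }
  r_meas * (m_heavy / m_light)^f
}

#' Generate synthetic bracketed isotope runs
#'
#' Emits, per element, a run of cycles in the pattern STD, SAMPLE, STD,
#' SAMPLE, ..., STD. The measured analyte ratio is the true ratio distorted
#' by an exponential mass bias whose exponent drifts linearly in time; the
#' doped-element channels carry a reference of known ratio subject to the
#' same exponent. Gaussian noise calibrated to `cfg$delta_noise_2sd` (2SD,
#' per mil) is applied multiplicatively to the analyte ratio of sample
#' cycles; reference-material cycles use the (smaller) long-term precision
#' of clean standard solutions, `spec$reference_noise_2sd`.
#'
#' @param truth Ground truth with an `isotope_runs` spec (true deltas per
#'   label, drift model `f0 + f_slope * t`, cycle interval).
#' @param cfg A [sim_config()] (supplies the delta noise level).
#' @param seed Optional seed.
#' @param noise Set `FALSE` for noiseless runs (exactness tests).
#' @return Named list of run tibbles (one per element) with columns
#'   `cycle, time_s, role, label, element, I_heavy, I_light,
#'   I_dopant_heavy, I_dopant_light`.
#' @export
generate_isotope_runs <- function(truth, cfg = sim_config(), seed = NULL, noise = TRUE) {
  spec <- truth$isotope_runs
  if (is.null(spec)) abort("truth has no isotope-run spec")
  if (!is.null(seed)) withr::local_seed(seed)
  sd_rel <- if (noise) (cfg$delta_noise_2sd / 2) / 1000 else 0
  ref_2sd <- spec$reference_noise_2sd %||% cfg$delta_noise_2sd
  sd_rel_ref <- if (noise) (ref_2sd / 2) / 1000 else 0
  runs <- list()
  for (el in c("Cu", "Zn")) {
    model <- mass_bias_model(el)
    items <- dplyr::bind_rows(
      dplyr::mutate(spec$samples[spec$samples$element == el, ], role = "sample"),
      dplyr::mutate(spec$references[spec$references$element == el, ], role = "reference_material")
    )
    if (nrow(items) == 0) next
    # one cycle per replicate, interleaved with bracketing standards
    reps <- items[rep(seq_len(nrow(items)), items$n_replicates), ]
    reps <- reps[sample(nrow(reps)), ] # measurement order randomized
    n_meas <- nrow(reps)
    role <- c(rbind(rep("standard", n_meas), reps$role), "standard")
    label <- c(rbind(rep(paste0(el, "_std"), n_meas), reps$label), paste0(el, "_std"))
    delta_true <- c(rbind(rep(0, n_meas), reps$delta_true), 0)
    n_cyc <- length(role)
    time_s <- spec$cycle_interval_s * (seq_len(n_cyc) - 1)
    f <- spec$f0 + spec$f_slope * time_s
    r_true <- model$r_standard * (1 + delta_true / 1000)
    r_meas <- r_true * (model$m_heavy / model$m_light)^(-f)
    noisy <- role != "standard"
    sds <- ifelse(role == "sample", sd_rel, sd_rel_ref)
    r_meas[noisy] <- r_meas[noisy] * exp(rnorm(sum(noisy), 0, sds[noisy]))
    r_dop <- model$dopant_true *
      (model$dopant_m_heavy / model$dopant_m_light)^(-f)
    I_light <- rep(3.0, n_cyc) # ~300 ppb analyte beam, arbitrary volts
    I_dop_light <- rep(2.0, n_cyc)
    runs[[el]] <- tibble::tibble(
      cycle = seq_len(n_cyc), time_s = time_s, role = role, label = label,
      element = el,
      I_heavy = r_meas * I_light, I_light = I_light,
      I_dopant_heavy = r_dop * I_dop_light, I_dopant_light = I_dop_light
    )
  }
  runs
}

validate_run <- function(run) {
  need <- c(
    "cycle", "time_s", "role", "label", "I_heavy", "I_light",
    "I_dopant_heavy", "I_dopant_light"
  )
  missing_cols <- setdiff(need, names(run))
  if (length(missing_cols) > 0) {
    abort(paste0("run missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "metalloscope_schema_error"
    )
  }
  if (is.unsorted(run$time_s, strictly = TRUE)) {
    abort("cycle times must be strictly increasing", class = "metalloscope_schema_error")
  }
  ints <- c(run$I_heavy, run$I_light, run$I_dopant_heavy, run$I_dopant_light)
  if (any(ints <= 0)) {
    abort("intensities must be positive", class = "metalloscope_schema_error")
  }
  if (sum(run$role == "standard") < 2) {
    abort("bracketing impossible: fewer than 2 standard cycles",
      class = "metalloscope_schema_error"
    )
  }
  if (run$role[1] != "standard" || run$role[nrow(run)] != "standard") {
    abort("first and last cycle must be standards", class = "metalloscope_schema_error")
  }
  run
}

#' Reduce a bracketed isotope run to per-sample deltas
#'
#' Per cycle, the mass-bias exponent is estimated from the doped-element
#' channels and the analyte ratio corrected with the exponential law; each
#' sample cycle's delta is then computed against the time-linear
#' interpolation of the corrected ratios of its two flanking standard
#' cycles. Replicates of a label are aggregated to mean and 2SD.
#'
#' @param run A run tibble (see [generate_isotope_runs()] for the layout).
#' @param model A [mass_bias_model()].
#' @param interpolation `"linear"` (time-weighted between flanking
#'   standards, default) or `"mean"` (unweighted mean of the flanking
#'   standards).
#' @param use_dopant If `FALSE`, skip the dopant-based mass-bias correction
#'   and rely on bracketing alone (for drift-handling comparisons).
#' @return A delta table: `label`, `element`, `role`, `n`, `delta_permil`,
#'   `two_sd`.
#' @export
bracket_reduce <- function(run, model,
                           interpolation = c("linear", "mean"),
                           use_dopant = TRUE) {
  interpolation <- match.arg(interpolation)
  validate_run(run)
  r_meas <- run$I_heavy / run$I_light
  if (use_dopant) {
    r_dop <- run$I_dopant_heavy / run$I_dopant_light
    f <- estimate_mass_bias(
      r_dop, model$dopant_true,
      model$dopant_m_heavy, model$dopant_m_light
    )
    r_corr <- correct_ratio(r_meas, f, model$m_heavy, model$m_light)
  } else {
    r_corr <- r_meas
  }
  is_std <- run$role == "standard"
  std_idx <- which(is_std)
  meas_idx <- which(!is_std)
  deltas <- tibble::tibble(
    label = run$label[meas_idx], role = run$role[meas_idx],
    delta = NA_real_
  )
  for (k in seq_along(meas_idx)) {
    i <- meas_idx[k]
    lo <- std_idx[std_idx < i]
    hi <- std_idx[std_idx > i]
    if (length(lo) == 0 || length(hi) == 0) {
      abort(paste0("sample cycle ", run$cycle[i], " has no flanking standard"),
        class = "metalloscope_schema_error"
      )
    }
    lo <- max(lo)
    hi <- min(hi)
    r_std <- if (interpolation == "linear") {
      w <- (run$time_s[i] - run$time_s[lo]) / (run$time_s[hi] - run$time_s[lo])
      (1 - w) * r_corr[lo] + w * r_corr[hi]
    } else {
      (r_corr[lo] + r_corr[hi]) / 2
    }
    deltas$delta[k] <- compute_delta(r_corr[i], r_std)
  }
  deltas |>
    dplyr::group_by(.data$label, .data$role) |>
    dplyr::summarise(
      n = dplyr::n(),
      delta_permil = mean(.data$delta),
      two_sd = if (dplyr::n() > 1) 2 * sd(.data$delta) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(element = model$element, .after = "label")
}

#' Reference windows for isotope QC
#'
#' Certified / consensus deltas (per mil) and 2SD windows for the in-house
#' sheep-plasma standard (OEP) and bovine liver SRM-1577c.
#' @return Tibble with `label`, `element`, `expected`, `tol`.
#' @export
default_reference_ranges <- function() {
  tibble::tribble(
    ~label, ~element, ~expected, ~tol,
    "OEP", "Zn", 0.76, 0.08,
    "SRM-1577c", "Zn", -0.18, 0.05,
    "OEP", "Cu", -1.10, 0.15,
    "SRM-1577c", "Cu", 0.43, 0.04
  )
}

#' QC check of reduced deltas against reference materials
#'
#' Flags any reference material whose mean delta falls outside its
#' configured window (`expected` plus/minus `tol * tol_multiplier`). This is
#' report-only: no error is raised.
#'
#' @param deltas A delta table from [bracket_reduce()].
#' @param reference_ranges Windows, defaults to [default_reference_ranges()].
#' @param tol_multiplier Widens (or narrows) the windows.
#' @return A QC tibble (`label`, `element`, `measured`, `expected`, `tol`,
#'   `pass`); if no reference-material rows are present, a zero-row tibble
#'   with `attr(, "status") = "no QC possible"` and a message.
#' @export
qc_check <- function(deltas, reference_ranges = default_reference_ranges(),
                     tol_multiplier = 1) {
  refs <- deltas[deltas$role == "reference_material", ]
  if (nrow(refs) == 0) {
    inform("no reference-material cycles: no QC possible")
    out <- tibble::tibble(
      label = character(), element = character(), measured = double(),
      expected = double(), tol = double(), pass = logical()
    )
    attr(out, "status") <- "no QC possible"
    return(out)
  }
  out <- refs |>
    dplyr::left_join(reference_ranges, by = c("label", "element")) |>
    dplyr::mutate(
      measured = .data$delta_permil,
      pass = !is.na(.data$expected) &
        abs(.data$measured - .data$expected) <= .data$tol * tol_multiplier
    ) |>
    dplyr::select("label", "element", "measured", "expected", "tol", "pass")
  attr(out, "status") <- if (all(out$pass)) "pass" else "flagged"
  if (!all(out$pass)) {
    warn(paste0(
      "QC flag: ",
      paste(out$label[!out$pass], out$element[!out$pass], collapse = ", "),
      " outside reference window"
    ))
  }
  out
}
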