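test_that("delta computation matches its defining identities", {
  expect_identical(compute_delta(0.4456, 0.4456), 0)
  expect_equal(compute_delta(1.001 * 0.5, 0.5), 1.0, tolerance = 1e-12)
  expect_equal(compute_delta(0.999 * 0.5, 0.5), -1.0, tolerance = 1e-12)
  expect_error(compute_delta(-1, 0.5), class = "metalloscope_domain_error")
  # end-to-end linearity: doubling the ratio offset doubles delta
  d1 <- compute_delta(0.5 * 1.0004, 0.5)
  d2 <- compute_delta(0.5 * 1.0008, 0.5)
  expect_equal(d2, 2 * d1, tolerance = 1e-9)
})

test_that("mass-bias estimate and correction invert the forward model", {
  model <- mass_bias_model("Cu")
  withr::local_seed(11)
  for (i in 1:50) {
    f <- runif(1, -2, 2)
    r_true <- runif(1, 0.3, 0.7)
    r_meas <- r_true * (model$m_heavy / model$m_light)^(-f)
    f_hat <- estimate_mass_bias(r_meas, r_true, model$m_heavy, model$m_light)
    expect_equal(f_hat, f, tolerance = 1e-10)
    expect_equal(
      correct_ratio(r_meas, f_hat, model$m_heavy, model$m_light),
      r_true,
      tolerance = 1e-12 * r_true
    )
  }
  expect_identical(estimate_mass_bias(0.5, 0.5, 65, 63), 0)
  expect_identical(correct_ratio(0.5, 0, 65, 63), 0.5)
  expect_error(estimate_mass_bias(0.5, 0.5, 63, 63), class = "metalloscope_domain_error")
})

test_that("corrected ratio is strictly increasing in f for m_heavy > m_light", {
  f <- seq(-1, 1, by = 0.25)
  r <- correct_ratio(0.5, f, 65, 63)
  expect_true(all(diff(r) > 0))
})

test_that("bracket reduction is exact on noiseless drifting runs", {
  truth <- default_truth()
  truth$isotope_runs$samples <- tibble::tibble(
    label = c("a", "b", "c"), element = "Cu",
    delta_true = c(-0.30, 0, 0.50), n_replicates = 3L
  )
  truth$isotope_runs$references <- truth$isotope_runs$references[0, ]
  runs <- generate_isotope_runs(truth, sim_config(), seed = 2, noise = FALSE)
  dt <- bracket_reduce(runs$Cu, mass_bias_model("Cu"))
  expect_equal(dt$delta_permil[match(c("a", "b", "c"), dt$label)],
    c(-0.30, 0, 0.50),
    tolerance = 1e-9
  )
  # sample ratio equal to the standard: delta 0 throughout
  run0 <- runs$Cu
  run0$I_heavy <- run0$I_light * mass_bias_model("Cu")$r_standard
  run0$I_dopant_heavy <- run0$I_dopant_light * mass_bias_model("Cu")$dopant_true
  dt0 <- bracket_reduce(run0, mass_bias_model("Cu"))
  expect_equal(dt0$delta_permil, rep(0, nrow(dt0)), tolerance = 1e-12)
})

test_that("bracketing beats a first-standard-only reduction under drift", {
  truth <- default_truth()
  truth$isotope_runs$samples <- tibble::tibble(
    label = "a", element = "Cu", delta_true = -0.30, n_replicates = 5L
  )
  truth$isotope_runs$references <- truth$isotope_runs$references[0, ]
  run <- generate_isotope_runs(truth, sim_config(), seed = 3, noise = FALSE)$Cu
  model <- mass_bias_model("Cu")
  bracketed <- bracket_reduce(run, model, use_dopant = FALSE)
  # first-standard-only: freeze every standard at the first standard's ratio
  r1 <- run$I_heavy[1] / run$I_light[1]
  frozen <- run
  frozen$I_heavy[frozen$role == "standard"] <- r1 * frozen$I_light[frozen$role == "standard"]
  first_only <- bracket_reduce(frozen, model, use_dopant = FALSE)
  err_bracket <- abs(bracketed$delta_permil - (-0.30))
  err_first <- abs(first_only$delta_permil - (-0.30))
  expect_lt(err_bracket, err_first)
})

test_that("malformed runs are rejected with named errors", {
  truth <- default_truth()
  run <- generate_isotope_runs(truth, sim_config(), seed = 4, noise = FALSE)$Cu
  bad <- run[run$role != "standard", ]
  expect_error(bracket_reduce(bad, mass_bias_model("Cu")), "standard")
  bad2 <- run
  bad2$time_s[2] <- bad2$time_s[1]
  expect_error(bracket_reduce(bad2, mass_bias_model("Cu")), "increasing")
  bad3 <- run[-nrow(run), ] # no closing standard
  expect_error(bracket_reduce(bad3, mass_bias_model("Cu")), "standard")
})

test_that("QC flags reference materials outside their windows", {
  truth <- default_truth()
  runs <- generate_isotope_runs(truth, sim_config(), seed = 5, noise = FALSE)
  dt <- bracket_reduce(runs$Cu, mass_bias_model("Cu"))
  qc <- qc_check(dt)
  expect_true(all(qc$pass))
  expect_identical(attr(qc, "status"), "pass")

  # shift a reference 3 windows away: flagged
  shifted <- dt
  shifted$delta_permil[shifted$label == "OEP"] <-
    -1.10 + 3 * 0.15
  expect_warning(qc2 <- qc_check(shifted), "QC flag")
  expect_false(qc2$pass[qc2$label == "OEP"])

  # no reference material at all: report-only, "no QC possible"
  none <- dt[dt$role == "sample", ]
  expect_message(qc3 <- qc_check(none), "no QC possible")
  expect_identical(attr(qc3, "status"), "no QC possible")
})

test_that("replicate 2SD from noisy runs calibrates to the injected noise", {
  truth <- default_truth()
  truth$isotope_runs$samples <- tibble::tibble(
    label = "a", element = "Cu", delta_true = -0.30, n_replicates = 30L
  )
  truth$isotope_runs$references <- truth$isotope_runs$references[0, ]
  cfg <- sim_config(delta_noise_2sd = 0.12)
  est <- sapply(1:20, function(s) {
    run <- generate_isotope_runs(truth, cfg, seed = s)$Cu
    bracket_reduce(run, mass_bias_model("Cu"))$two_sd
  })
  # unbiased within Monte-Carlo error over 20 x 30 replicate deltas
  expect_equal(mean(est), 0.12, tolerance = 0.1)
})
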