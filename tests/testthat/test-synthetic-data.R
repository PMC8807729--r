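test_that("identical (truth, cfg, seed) give bit-identical studies", {
  a <- simulate_study(seed = 42)
  b <- simulate_study(seed = 42)
  expect_identical(a$metallome, b$metallome)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$metabolome, b$metabolome)
  expect_identical(a$runs, b$runs)
  c <- simulate_study(seed = 43)
  expect_false(identical(a$metallome, c$metallome))
})

test_that("zero noise, zero spread and zero slopes reproduce baselines exactly", {
  truth <- default_truth(planted = FALSE)
  truth$baselines$cv <- 0
  cfg <- sim_config(conc_noise_2sd = 0, delta_noise_2sd = 0)
  m <- generate_metallome(truth, cfg, seed = 1)$metallome
  base <- truth$baselines
  for (o in metal_organs()) {
    for (a in c("Fe", "K", "d65Cu")) {
      expected <- base$baseline[base$organ == o & base$analyte == a]
      expect_equal(unique(m[[a]][m$organ == o]), expected, tolerance = 1e-12)
    }
  }
})

test_that("planted brain Fe age slope is recovered by OLS across seeds", {
  truth <- default_truth()
  planted <- truth$age_slopes$slope[
    truth$age_slopes$organ == "brain" & truth$age_slopes$analyte == "Fe"
  ]
  covered <- 0L
  for (s in 1:20) {
    m <- generate_metallome(truth, sim_config(), seed = s)$metallome
    brain <- m[m$organ == "brain", ]
    fit <- lm(log(Fe) ~ age_months, data = brain)
    ci <- confint(fit)["age_months", ]
    covered <- covered + (planted >= ci[1] && planted <= ci[2])
  }
  expect_gte(covered, 18L)
})

test_that("group I analytes are positively inter-correlated in the liver", {
  g1 <- c("S", "Mg", "P", "Rb", "K", "Cu", "Zn", "Mn")
  all_positive <- 0L
  for (s in 1:20) {
    m <- generate_metallome(default_truth(), sim_config(), seed = s)$metallome
    liver <- log(as.matrix(m[m$organ == "liver", g1]))
    rho <- cor(liver, method = "spearman")
    all_positive <- all_positive + all(rho[upper.tri(rho)] > 0)
  }
  expect_gt(all_positive, 10L) # majority of seeds
})

test_that("planted omics sets out-correlate the background with their target", {
  truth <- default_truth()
  cfg <- sim_config()
  setdb <- default_feature_sets(truth, cfg, "metabolome")
  fe_set <- setdb$members[[which(setdb$set_id == "FE_RESPONSIVE_MET")]]
  decoys <- unlist(setdb$members[grepl("^DECOY", setdb$set_id)])
  wins <- 0L
  for (s in 1:10) {
    mp <- generate_metallome(truth, cfg, seed = s)
    om <- generate_omics(truth, mp$metallome, setdb, cfg, seed = s + 100)
    liver <- mp$metallome[mp$metallome$organ == "liver", ]
    om <- om[match(liver$sample_id, om$sample_id), ]
    r_set <- sapply(fe_set, function(f) abs(cor(om[[f]], liver$Fe)))
    r_bg <- sapply(decoys, function(f) abs(cor(om[[f]], liver$Fe)))
    wins <- wins + (mean(r_set) > mean(r_bg))
  }
  expect_gte(wins, 9L)
})

test_that("zero-strength enrichments leave feature-metal correlations null", {
  truth <- default_truth(planted = FALSE)
  cfg <- sim_config()
  setdb <- default_feature_sets(truth, cfg, "metabolome")
  mp <- generate_metallome(truth, cfg, seed = 3)
  om <- generate_omics(truth, mp$metallome, setdb, cfg, seed = 4)
  liver <- mp$metallome[mp$metallome$organ == "liver", ]
  om <- om[match(liver$sample_id, om$sample_id), ]
  feats <- setdiff(names(om), "sample_id")[1:200]
  r <- sapply(feats, function(f) cor(om[[f]], liver$Fe))
  expect_lt(abs(mean(r)), 0.1)
  expect_lt(max(abs(r)), 0.7)
})

test_that("degenerate truths are rejected with informative errors", {
  truth <- default_truth()
  truth$groups$rho[truth$groups$group == "I"] <- -0.5
  expect_error(validate_truth(truth), "positive-definite")

  truth2 <- default_truth()
  truth2$enrichments$strength[1] <- 1.5
  expect_error(validate_truth(truth2), "\\[-1, 1\\]")

  truth3 <- default_truth()
  truth3$cross_loadings$loading[1] <- -0.9 # Na: 0.4 + 0.81 > 1
  expect_error(validate_truth(truth3), "positive-definite")
})

test_that("a planted set of size 1 is still generated and flagged", {
  truth <- default_truth()
  cfg <- sim_config()
  setdb <- default_feature_sets(truth, cfg, "metabolome")
  setdb$members[[1]] <- setdb$members[[1]][1]
  mp <- generate_metallome(truth, cfg, seed = 5)
  expect_message(
    om <- generate_omics(truth, mp$metallome, setdb, cfg, seed = 6),
    "size 1"
  )
  expect_true(setdb$members[[1]] %in% names(om))
})

test_that("synthetic runs satisfy the bracketing layout and noiseless identity", {
  truth <- default_truth()
  runs <- generate_isotope_runs(truth, sim_config(), seed = 1, noise = FALSE)
  for (el in c("Cu", "Zn")) {
    run <- runs[[el]]
    expect_identical(run$role[1], "standard")
    expect_identical(run$role[nrow(run)], "standard")
    expect_true(all(diff(run$time_s) > 0))
  }
  # f identically zero, no noise: measured ratios equal true ratios
  truth0 <- default_truth()
  truth0$isotope_runs$f0 <- 0
  truth0$isotope_runs$f_slope <- 0
  run <- generate_isotope_runs(truth0, sim_config(), seed = 1, noise = FALSE)$Cu
  model <- mass_bias_model("Cu")
  r_meas <- run$I_heavy / run$I_light
  spec <- truth0$isotope_runs$samples
  lab <- run$label[run$role == "sample"][1]
  d_true <- spec$delta_true[spec$label == lab & spec$element == "Cu"]
  expect_equal(
    r_meas[run$role == "sample"][1],
    model$r_standard * (1 + d_true / 1000),
    tolerance = 1e-12
  )
})
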