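test_that("z-score outlier removal follows the hand-computed rule", {
  # [1, 1, 1, 10]: mean 3.25, sd 4.5, max |z| = 1.5 -> nothing removed at 3
  m <- tiny_metal_table()
  m$organ <- "liver"
  m$age_months <- 6
  m$Fe <- c(1, 1, 1, 10)
  out <- remove_outliers(m, z_threshold = 3)
  expect_identical(sum(is.na(out$Fe)), 0L)
  expect_identical(attr(out, "fraction_removed"), 0)
  # the same values at threshold 1.4 lose the 10
  out2 <- suppressWarnings(remove_outliers(m, z_threshold = 1.4))
  expect_identical(which(is.na(out2$Fe)), 4L)
})

test_that("degenerate outlier groups are skipped with warnings, never errors", {
  m <- tiny_metal_table()
  m$organ <- "liver"
  m$age_months <- 6
  m$Cu <- rep(5, 4) # zero spread
  expect_warning(out <- remove_outliers(m), "zero spread")
  expect_identical(sum(is.na(out$Cu)), 0L)
  lg <- attr(out, "removal_log")
  expect_true(any(lg$analyte == "Cu" & lg$note == "zero spread"))

  m2 <- tiny_metal_table() # groups of 2 per organ x age: too small
  expect_warning(out2 <- remove_outliers(m2), "fewer than 3")
})

test_that("a gross outlier among normal draws is removed at threshold 3", {
  removed <- 0L
  for (s in 1:20) {
    withr::local_seed(s)
    m <- tibble::tibble(
      sample_id = sprintf("S%02d", 1:21),
      organ = "liver", age_months = 6,
      Fe = c(rnorm(20, 100, 5), NA)
    )
    m$Fe[21] <- mean(m$Fe[1:20]) + 10 * sd(m$Fe[1:20])
    out <- remove_outliers(m, z_threshold = 3)
    removed <- removed + is.na(out$Fe[21])
  }
  expect_gte(removed, 19L)
})

test_that("outlier removal is single-pass and idempotent at zero removal", {
  withr::local_seed(1)
  m <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:30), organ = "liver", age_months = 6,
    Fe = rnorm(30, 100, 5)
  )
  once <- remove_outliers(m, z_threshold = 4)
  twice <- remove_outliers(once, z_threshold = 4)
  expect_identical(once$Fe, twice$Fe)
})

test_that("normalization modes behave as defined and deltas are untouched", {
  m <- tiny_metal_table()
  expect_identical(normalize_metals(m, "none"), validate_metal_matrix(m))

  tot <- normalize_metals(m, "total")
  conc <- as.matrix(tot[metal_analytes()$analyte[1:15]])
  expect_equal(unname(rowSums(conc)), rep(1, 4), tolerance = 1e-12)
  expect_identical(tot$d65Cu, m$d65Cu)
  # idempotent
  tot2 <- normalize_metals(tot, "total")
  expect_equal(as.data.frame(tot2), as.data.frame(tot), tolerance = 1e-12)

  na <- normalize_metals(m, "na")
  expect_equal(na$Na, rep(1, 4), tolerance = 1e-12)

  m$Na[2] <- 0
  expect_warning(bad <- normalize_metals(m, "na"), "masked")
  expect_true(all(is.na(as.matrix(bad[bad$sample_id == "S2", metal_analytes()$analyte[1:15]]))))
})

test_that("age correction orthogonalizes values against age per organ", {
  m <- generate_metallome(default_truth(), sim_config(), seed = 8)$metallome
  ac <- age_correct(m)
  for (o in c("brain", "liver")) {
    sub <- ac[ac$organ == o, ]
    expect_lt(abs(cor(sub$Fe, sub$age_months)), 1e-10)
    expect_lt(abs(cor(sub$d65Cu, sub$age_months)), 1e-10)
  }
  # planted linear trend, zero noise: slope recovered exactly, output constant
  grid <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:12), organ = "liver",
    age_months = rep(c(6, 16, 24), each = 4)
  )
  grid$Fe <- 100 + 2 * grid$age_months
  acg <- age_correct(grid)
  fits <- attr(acg, "age_fits")
  expect_equal(fits$slope[fits$analyte == "Fe"], 2, tolerance = 1e-10)
  expect_equal(acg$Fe, rep(100, 12), tolerance = 1e-9) # intercept + residuals
  expect_lt(diff(range(acg$Fe)), 1e-9)

  # zero planted slope, zero noise: identity
  grid$Fe <- 100
  expect_equal(age_correct(grid)$Fe, grid$Fe, tolerance = 1e-12)

  # single age level: identity with warning
  one_age <- grid[grid$age_months == 6, ]
  expect_warning(same <- age_correct(one_age), "single age")
  expect_identical(same$Fe, one_age$Fe)
})

test_that("PCA fingerprint is a deterministic orthonormal decomposition", {
  m <- generate_metallome(default_truth(), sim_config(), seed = 9)$metallome
  pca <- pca_fingerprint(m)
  expect_equal(sum(pca$variance_explained), 1, tolerance = 1e-10)
  expect_true(all(diff(pca$variance_explained) <= 1e-12))
  # loadings orthonormal
  ltl <- t(pca$loadings) %*% pca$loadings
  expect_equal(ltl, diag(ncol(pca$loadings)), tolerance = 1e-8, ignore_attr = TRUE)
  # reconstruction from all retained components
  x <- as.matrix(m[rownames(pca$loadings)])
  conc <- intersect(colnames(x), metal_analytes()$analyte[1:15])
  x[, conc] <- log(x[, conc])
  xs <- scale(x)
  scores <- as.matrix(pca$scores[, colnames(pca$loadings)])
  expect_lt(max(abs(scores %*% t(pca$loadings) - xs)), 1e-8)
  # determinism including the sign convention
  pca2 <- pca_fingerprint(m)
  expect_identical(pca$loadings, pca2$loadings)
})

test_that("a single varying analyte gives PC1 all the variance", {
  m <- tiny_metal_table()
  for (a in metal_analytes()$analyte) m[[a]] <- 1
  m$Fe <- c(1, 2, 3, 4)
  pca <- pca_fingerprint(m, log_concentrations = FALSE)
  expect_equal(pca$variance_explained[1], 1, tolerance = 1e-12)
  expect_error(pca_fingerprint(m[1, ]), "at least 2")
})
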