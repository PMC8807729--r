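fake_assoc <- function() {
  tibble::tibble(
    organ = "liver",
    feature_a = c("Fe", "Fe", "Cu", "d65Cu"),
    feature_b = c("Cu", "Zn", "Zn", "body_weight_g"),
    rho = c(0.8, 0.5, -0.6, -0.7),
    beta = c(0.8, 0.5, -0.6, -0.7),
    t_mod = c(5, 2, -4, -4.5),
    p = c(1e-5, 0.04, 1e-3, 5e-4),
    adj_p = c(4e-5, 0.04, 2e-3, 1e-3),
    n = 48,
    layer = c("metal-metal", "metal-metal", "metal-metal", "metal-phenotype")
  )
}

test_that("correlation networks threshold on Adj.P and are monotone in alpha", {
  assoc <- fake_assoc()
  net <- build_correlation_network(assoc, edge_alpha = 0.05)
  expect_identical(nrow(net$edges), 4L)
  expect_identical(net$edges$sign, sign(net$edges$weight))

  tight <- build_correlation_network(assoc, edge_alpha = 0.01)
  expect_identical(nrow(tight$edges), 3L)
  none <- build_correlation_network(assoc, edge_alpha = 1e-9)
  expect_identical(nrow(none$edges), 0L)
  # lowering alpha never adds edges
  alphas <- c(1e-6, 1e-4, 0.01, 0.05, 0.5)
  counts <- sapply(alphas, function(a) nrow(build_correlation_network(assoc, a)$edges))
  expect_true(all(diff(counts) >= 0))
})

test_that("node typing distinguishes metals, isotopes and phenotypes", {
  net <- build_correlation_network(fake_assoc(), edge_alpha = 0.05)
  types <- setNames(net$nodes$type, net$nodes$id)
  expect_identical(unname(types["Fe"]), "metal")
  expect_identical(unname(types["d65Cu"]), "isotope")
  expect_identical(unname(types["body_weight_g"]), "phenotype")
})

test_that("layer integration admits by node_alpha and prunes by edge_alpha", {
  assoc <- fake_assoc()
  # node admission at 0.01 excludes the Fe~Zn edge participant only if no
  # other association carries it; Zn has Cu~Zn at 0.002 so it stays
  net <- integrate_layers(assoc, node_alpha = 0.01, edge_alpha = 0.05)
  expect_setequal(net$nodes$id, c("Fe", "Cu", "Zn", "d65Cu", "body_weight_g"))
  expect_identical(nrow(net$edges), 4L)

  # a node whose best Adj.P is above node_alpha is dropped with its edges
  assoc2 <- assoc
  assoc2$adj_p[assoc2$feature_b == "body_weight_g"] <- 0.03
  net2 <- integrate_layers(assoc2, node_alpha = 0.01, edge_alpha = 0.05)
  expect_false("body_weight_g" %in% net2$nodes$id)

  # node_alpha = edge_alpha degenerates to plain thresholding
  net3 <- integrate_layers(assoc, node_alpha = 0.05, edge_alpha = 0.05)
  expect_identical(
    nrow(net3$edges),
    nrow(build_correlation_network(assoc, 0.05)$edges)
  )

  # conflicting duplicate edges are an error
  expect_error(
    integrate_layers(dplyr::bind_rows(assoc, assoc[1, ])),
    "duplicate"
  )
})

test_that("integration keeps enrichment edges with NES weights", {
  assoc <- fake_assoc()
  enr <- structure(
    tibble::tibble(
      metal = "Fe", set_id = "OXPHOS_SET", size = 12L,
      es = 0.9, nes = 1.8, p = 0.001, adj_p = 0.004,
      leading_edge = "a;b", flag = "ok"
    ),
    class = c("enrichment_result", class(tibble::tibble()))
  )
  net <- integrate_layers(assoc, enrichment_edges = enr)
  expect_true("OXPHOS_SET" %in% net$nodes$id)
  expect_identical(
    net$nodes$type[net$nodes$id == "OXPHOS_SET"],
    "feature_set"
  )
  expect_equal(net$edges$weight[net$edges$layer == "metal-set"], 1.8)
})

test_that("identical studies give perfect concordance, r symmetric on swap", {
  m <- generate_metallome(default_truth(), sim_config(), seed = 51)$metallome
  cc <- cross_study_concordance(m, m, mode = "metal_pairs", normalization = "total")
  gl <- glance(cc)
  expect_equal(gl$r_pearson, 1, tolerance = 1e-12)
  expect_equal(gl$slope, 1, tolerance = 1e-12)

  m2 <- generate_metallome(default_truth(), sim_config(), seed = 52)$metallome
  ab <- glance(cross_study_concordance(m, m2, mode = "metal_pairs"))
  ba <- glance(cross_study_concordance(m2, m, mode = "metal_pairs"))
  expect_equal(ab$r_pearson, ba$r_pearson, tolerance = 1e-12)
  # on the noiseless (identical) case the slope inverts on swap
  expect_equal(
    glance(cross_study_concordance(m, m, mode = "age_effects"))$slope,
    1 / glance(cross_study_concordance(m, m, mode = "age_effects"))$slope,
    tolerance = 1e-12
  )
  expect_error(
    cross_study_concordance(m[, 1:6], m2, mode = "metal_pairs"),
    "fewer than 3 analytes"
  )
})

test_that("integrated networks serialize losslessly", {
  assoc <- fake_assoc()
  net <- integrate_layers(assoc, node_alpha = 0.05, edge_alpha = 0.05)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, path, format = "graphml")
  back <- read_network(path, format = "graphml")
  expect_equal(
    dplyr::arrange(back$nodes, .data$id),
    dplyr::arrange(net$nodes, .data$id)
  )
  key <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to))
  expect_equal(
    back$edges$weight[order(key(back$edges))],
    net$edges$weight[order(key(net$edges))]
  )
})
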