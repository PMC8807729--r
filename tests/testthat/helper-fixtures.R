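# Shared fixtures and independent oracles for the test suite.

# a tiny valid metallome table (4 samples, all 17 analytes)
tiny_metal_table <- function() {
  analytes <- metal_analytes()$analyte
  m <- tibble::tibble(
    sample_id = paste0("S", 1:4),
    animal_id = paste0("M", 1:4),
    organ = c("liver", "liver", "brain", "brain"),
    age_months = c(6, 24, 6, 24)
  )
  for (i in seq_along(analytes)) {
    m[[analytes[i]]] <- if (grepl("^d6", analytes[i])) {
      c(-0.2, 0.1, 0.3, -0.4) + i / 10
    } else {
      c(10, 12, 9, 11) * i
    }
  }
  m
}

# brute-force Benjamini-Hochberg step-up: for each p_i, the minimum over all
# p_j >= p_i of m * p_j / rank(p_j), capped at 1 (independent of the
# vectorized implementation)
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(1, min(m * ranked[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# brute-force weighted KS enrichment score: evaluate the running sum
# position by position and take the signed maximum deviation
es_brute_force <- function(metric, hit, w = 1) {
  N <- length(metric)
  wts <- abs(metric)^w
  if (sum(wts[hit]) == 0) wts[hit] <- 1
  running <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- if (hit[i]) {
      cur + wts[i] / sum(wts[hit])
    } else {
      cur - 1 / (N - sum(hit))
    }
    running[i] <- cur
  }
  mx <- max(running)
  mn <- min(running)
  if (abs(mx) >= abs(mn) - 1e-12) mx else mn # positive on magnitude ties

}

# mean silhouette width of labels on a score matrix
mean_silhouette <- function(scores, labels) {
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(scores))
  mean(sil[, 3])
}

# a small deterministic ranked list for enrichment tests
toy_ranked <- function(n = 10) {
  tibble::tibble(
    feature = sprintf("f%02d", seq_len(n)),
    metric = seq(n, 1) / n
  )
}
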