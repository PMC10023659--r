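test_that("CPM filtering follows the threshold rule and matches a brute-force scan", {
  # all-zero gene always removed
  m <- make_counts(20, 6, mu = 300, seed = 2)
  m[3, ] <- 0L
  f <- filter_genes(m, min_fraction = 0.5)
  expect_false("g003" %in% rownames(f))

  # forced arithmetic: libraries of 1e6, counts (2, 0) -> CPM (2, 0); kept at 50%
  m2 <- matrix(0L, 2, 2, dimnames = list(c("gx", "gy"), c("s1", "s2")))
  m2[1, ] <- c(2L, 0L)
  m2[2, ] <- c(999998L, 1000000L)   # filler so libraries are exactly 1e6
  f2 <- filter_genes(m2, cpm_threshold = 1, min_fraction = 0.5)
  expect_true("gx" %in% rownames(f2))

  # oracle equivalence on a random matrix
  m3 <- make_counts(500, 20, mu = 50, seed = 3)
  f3 <- filter_genes(m3, cpm_threshold = 1, min_fraction = 0.5)
  keep <- logical(nrow(m3))
  lib <- colSums(m3)
  for (g in seq_len(nrow(m3))) {
    n_pass <- 0
    for (s in seq_len(ncol(m3))) if (m3[g, s] / lib[s] * 1e6 > 1) n_pass <- n_pass + 1
    keep[g] <- n_pass >= ceiling(0.5 * ncol(m3))
  }
  expect_identical(rownames(f3), rownames(m3)[keep])

  # idempotence
  expect_identical(filter_genes(f3, min_fraction = 0.5), f3)
  expect_error(filter_genes(m3, cpm_threshold = 1e9, min_fraction = 0.5), "all genes")
  expect_error(filter_genes(m3, min_fraction = 0.5, min_samples = 3), "exactly one")
})

test_that("TMM factors match the published formula computed step by step", {
  m <- make_counts(30, 3, mu = 400, seed = 4)
  same <- cbind(m[, 1], m[, 1], m[, 2])
  dimnames(same) <- list(rownames(m), c("a", "b", "c"))
  f <- tmm_factors(same)
  expect_equal(f[["a"]], f[["b"]], tolerance = 1e-12)

  # exact scaling leaves factors at 1
  tripled <- cbind(m[, 1], 3L * m[, 1])
  dimnames(tripled) <- list(rownames(m), c("a", "b"))
  f2 <- tmm_factors(tripled)
  expect_equal(unname(f2), c(1, 1), tolerance = 1e-12)

  # oracle equivalence on NB data
  m3 <- make_counts(200, 4, mu = 150, size = 3, seed = 5)
  expect_equal(unname(tmm_factors(m3)), unname(oracle_tmm(m3)), tolerance = 1e-10)

  # invariance to sample and gene order
  perm_s <- c(3, 1, 4, 2); perm_g <- sample(seq_len(200))
  f_perm <- tmm_factors(m3[perm_g, perm_s])
  expect_equal(unname(f_perm), unname(tmm_factors(m3)[perm_s]), tolerance = 1e-12)
})

test_that("logCPM follows the prior-count formula exactly", {
  m <- matrix(0L, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  m[1, 1] <- 0L; m[2, 1] <- 1000000L
  m[1, 2] <- 10L; m[2, 2] <- 999990L
  ne <- log_cpm(m, factors = c(1, 1), prior_count = 0.5)
  expect_equal(ne$logcpm[1, 1], log2(0.5 / (1e6 + 1) * 1e6), tolerance = 1e-12)
  expect_equal(ne$logcpm[1, 1], -1.0000014, tolerance = 1e-6)
  expect_equal(ne$logcpm[1, 2], log2(10.5 / (1e6 + 1) * 1e6), tolerance = 1e-12)

  # doubling counts and libraries is a no-op up to the prior-count term
  m2 <- make_counts(50, 4, mu = 500, seed = 6)
  d <- log_cpm(2L * m2)$logcpm - log_cpm(m2)$logcpm
  expect_lt(max(abs(d[m2 >= 500])), 1e-3)
  expect_error(log_cpm(m2, factors = c(-1, 1, 1, 1)), "positive")
})

test_that("PCA matches an eigendecomposition oracle and uses a fixed sign rule", {
  x <- matrix(rnorm(100 * 30), 100, 30,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:30)))
  pca <- pca_scores(x, n_components = 10)
  orc <- oracle_pca_scores(x, 10)
  for (j in 1:10) {
    expect_equal(unname(abs(pca$scores[, j])), abs(orc[, j]), tolerance = 1e-8)
    top <- which.max(abs(pca$loadings[, j]))
    expect_gt(pca$loadings[top, j], 0)
  }
  expect_lte(sum(pca$explained_variance), 1 + 1e-12)
  expect_true(all(diff(pca$explained_variance) <= 1e-12))

  # two samples differing along one gene: PC1 explains everything
  y <- matrix(5, 10, 2, dimnames = list(paste0("g", 1:10), c("a", "b")))
  y[1, 2] <- 9
  p2 <- pca_scores(y, n_components = 1)
  expect_equal(p2$explained_variance[1], 1, tolerance = 1e-12)
  expect_error(pca_scores(matrix(1, 5, 5), n_components = 2), "constant")
})

test_that("outlier screening needs the configured number of extreme components", {
  set.seed(7)
  scores <- matrix(rnorm(50 * 20), 50, 20,
                   dimnames = list(paste0("s", 1:50), paste0("PC", 1:20)))
  pca <- structure(list(scores = scores), class = "pcares")
  expect_length(detect_outliers(pca, sd_threshold = 5), 0)

  shifted <- scores
  shifted[1, 1:2] <- shifted[1, 1:2] + 10 * apply(scores[, 1:2], 2, sd)
  pca2 <- structure(list(scores = shifted), class = "pcares")
  expect_identical(detect_outliers(pca2, sd_threshold = 5), "s1")

  one_pc <- scores
  one_pc[1, 1] <- one_pc[1, 1] + 10 * sd(scores[, 1])
  pca3 <- structure(list(scores = one_pc), class = "pcares")
  expect_length(detect_outliers(pca3, sd_threshold = 5), 0)
  expect_length(detect_outliers(pca2, sd_threshold = Inf), 0)
})

test_that("precision weights are positive, finite and track expression", {
  set.seed(8)
  flat <- matrix(rpois(500 * 20, 500), 500, 20,
                 dimnames = list(paste0("g", 1:500), paste0("s", 1:20)))
  w <- voom_weights(flat)
  expect_true(all(is.finite(w)) && all(w > 0))
  expect_lt(sd(w) / mean(w), 0.10)   # near-flat trend for homogeneous genes

  sim <- simulate_bulk_cohort(sim_config(n_genes = 800), seed = 9)
  f <- filter_genes(sim$counts, min_fraction = 0.5)
  wf <- voom_weights(f, tmm_factors(f))
  expect_true(all(is.finite(wf)) && all(wf > 0))
  expect_true(all(wf >= 1e-6) && all(wf <= 1e6))
  # low-count observations get no more weight than high-count ones on average
  lc <- log2(f + 0.5)
  lo <- wf[lc < stats::quantile(lc, 0.2)]
  hi <- wf[lc > stats::quantile(lc, 0.8)]
  expect_lt(mean(lo), mean(hi))
  expect_error(voom_weights(f[1:5, ]), "10 genes")
})
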