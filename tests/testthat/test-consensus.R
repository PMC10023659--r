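# Gaussian latent-factor expression with planted modules, for direct
# construction of co-expression structure without the count generator.
make_module_expr <- function(sizes, n_noise, n_samples, factors = NULL,
                             loading = 1.5, noise_sd = 1, seed = 1,
                             prefix = "g") {
  set.seed(seed)
  n_genes <- sum(sizes) + n_noise
  labels <- c(rep(paste0("P", seq_along(sizes)), sizes), rep("none", n_noise))
  if (is.null(factors)) {
    factors <- matrix(rnorm(length(sizes) * n_samples), length(sizes), n_samples)
  }
  x <- matrix(rnorm(n_genes * n_samples, sd = noise_sd), n_genes, n_samples)
  start <- 1
  for (m in seq_along(sizes)) {
    idx <- start:(start + sizes[m] - 1)
    x[idx, ] <- x[idx, ] + loading * matrix(factors[m, ], sizes[m], n_samples,
                                            byrow = TRUE)
    start <- start + sizes[m]
  }
  dimnames(x) <- list(sprintf("%s%04d", prefix, seq_len(n_genes)),
                      sprintf("s%03d", seq_len(n_samples)))
  list(x = x, labels = stats::setNames(labels, rownames(x)), factors = factors)
}

test_that("signed adjacency maps correlation through the soft power", {
  s <- seq_len(8)
  x <- rbind(g1 = s, g2 = 2 * s + 3, g3 = -s,
             g4 = c(1, -1, 1, -1, 1, -1, 1, -1) + 10)
  a <- signed_adjacency(x, beta_power = 12)
  expect_equal(a["g1", "g2"], 1, tolerance = 1e-12)       # cor +1
  expect_equal(a["g1", "g3"], 0, tolerance = 1e-12)       # cor -1
  expect_equal(unname(diag(a)), rep(1, 4))
  y <- rbind(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1))    # exactly orthogonal
  a2 <- signed_adjacency(y, beta_power = 12)
  expect_equal(a2["a", "b"], 0.5^12, tolerance = 1e-12)
  expect_error(signed_adjacency(rbind(g1 = s, g2 = rep(1, 8))), "g2")
})

test_that("topological overlap matches hand algebra and a brute-force oracle", {
  a2 <- matrix(c(1, 0.4, 0.4, 1), 2, 2)
  expect_equal(topological_overlap(a2)[1, 2], 0.4, tolerance = 1e-12)

  a3 <- matrix(1, 3, 3)
  expect_true(all(abs(topological_overlap(a3) - 1) < 1e-12))

  set.seed(5)
  r <- matrix(runif(400, 0, 0.8), 20, 20)
  a <- (r + t(r)) / 2; diag(a) <- 1
  tom <- topological_overlap(a)
  expect_equal(tom, oracle_tom(a), tolerance = 1e-12)
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  expect_equal(tom, t(tom), tolerance = 1e-12)
})

test_that("consensus TOM is the element-wise minimum after quantile scaling", {
  set.seed(6)
  r <- matrix(runif(225, 0, 0.4), 15, 15)
  tom_a <- (r + t(r)) / 2; diag(tom_a) <- 1
  expect_equal(consensus_tom(tom_a, tom_a), tom_a, tolerance = 1e-12)

  tom_b <- tom_a / 2; diag(tom_b) <- 1
  # off-diagonal quantiles differ by exactly 2x, so scaling restores tom_a
  cons <- consensus_tom(tom_a, tom_b)
  off <- upper.tri(tom_a)
  expect_equal(cons[off], tom_a[off], tolerance = 1e-10)
  expect_error(consensus_tom(tom_a, tom_a[1:10, 1:10]), "differ")
})

test_that("module detection recovers planted structure in two datasets", {
  sizes <- rep(40, 4)
  fx_a <- make_module_expr(sizes, n_noise = 100, n_samples = 80, seed = 7,
                           prefix = "a")
  fx_b <- make_module_expr(sizes, n_noise = 100, n_samples = 40, seed = 8,
                           prefix = "a")   # same gene ids, different samples
  tom_a <- topological_overlap(signed_adjacency(fx_a$x))
  tom_b <- topological_overlap(signed_adjacency(fx_b$x))
  cons <- consensus_tom(tom_a, tom_b)
  asg <- detect_modules(cons, fx_a$x, fx_b$x, min_size = 30)
  expect_equal(length(asg$sizes), 4)
  skip_if_not_installed("mclust")
  expect_gt(mclust::adjustedRandIndex(asg$labels, fx_a$labels), 0.9)
  # background genes do not enter modules
  expect_true(all(asg$labels[fx_a$labels == "none"] == "unassigned"))
})

test_that("modules driven by one latent factor merge; order of genes is irrelevant", {
  set.seed(9)
  shared <- matrix(rnorm(2 * 60), 2, 60)
  shared[2, ] <- shared[1, ]                    # identical factors
  fx_a <- make_module_expr(c(35, 35), 60, 60, factors = shared, seed = 10)
  fx_b <- make_module_expr(c(35, 35), 60, 30, factors = shared[, 1:30] * 0 +
                             matrix(rep(rnorm(30), 2), 2, 30, byrow = TRUE),
                           seed = 11)
  tom_a <- topological_overlap(signed_adjacency(fx_a$x))
  tom_b <- topological_overlap(signed_adjacency(fx_b$x))
  cons <- consensus_tom(tom_a, tom_b)
  asg <- detect_modules(cons, fx_a$x, fx_b$x, min_size = 30)
  expect_equal(length(asg$sizes), 1)            # merged into one module

  # permutation invariance of the partition
  fx <- make_module_expr(c(40, 40), 80, 50, seed = 12)
  tom1 <- topological_overlap(signed_adjacency(fx$x))
  cons1 <- consensus_tom(tom1, tom1)
  asg1 <- detect_modules(cons1, fx$x, fx$x, min_size = 30)
  perm <- sample(nrow(fx$x))
  asg2 <- detect_modules(cons1[perm, perm], fx$x[perm, ], fx$x[perm, ],
                         min_size = 30)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(asg1$labels[rownames(fx$x)],
                                         asg2$labels[rownames(fx$x)]), 1)
})

test_that("eigengenes are unit-variance PC1 with positive mean member correlation", {
  profile <- rnorm(30)
  x <- matrix(rep(profile, each = 10), 10, 30,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:30)))
  labels <- stats::setNames(rep("M1", 10), rownames(x))
  eg <- module_eigengenes(x, labels)
  expect_equal(unname(eg$eigengenes["M1", ]), as.vector(scale(profile)),
               tolerance = 1e-10)
  expect_equal(eg$var_explained[["M1"]], 1, tolerance = 1e-10)

  # flipping all member genes flips the eigengene
  eg_neg <- module_eigengenes(-x, labels)
  expect_equal(eg_neg$eigengenes["M1", ], -eg$eigengenes["M1", ],
               tolerance = 1e-10)

  # PC1 variance fraction matches an eigendecomposition oracle
  fx <- make_module_expr(50, 0, 40, seed = 13)
  labs <- stats::setNames(rep("M1", 50), rownames(fx$x))
  eg2 <- module_eigengenes(fx$x, labs)
  xs <- t(scale(t(fx$x)))
  ev <- eigen(stats::cov(t(xs)), symmetric = TRUE)$values
  expect_equal(eg2$var_explained[["M1"]], ev[1] / sum(ev), tolerance = 1e-8)
  expect_equal(stats::sd(eg2$eigengenes["M1", ]), 1, tolerance = 1e-12)
  expect_gt(mean(stats::cor(eg2$eigengenes["M1", ], t(fx$x))), 0)
})

test_that("eigengene association and convergence classification follow the sign rules", {
  set.seed(14)
  n <- 60
  tab <- data.frame(sample_id = sprintf("s%03d", 1:n),
                    grp = rep(c("ctl", "case"), each = n / 2),
                    stringsAsFactors = FALSE)
  tab$grp <- factor(tab$grp, levels = c("ctl", "case"))
  eg <- matrix(rnorm(2 * n), 2, n, dimnames = list(c("M1", "M2"), tab$sample_id))
  eg[1, tab$grp == "case"] <- eg[1, tab$grp == "case"] + 3
  assoc <- eigengene_association(eg, tab, "grp")
  expect_equal(nrow(assoc), 2)
  expect_lt(assoc$p[assoc$module == "M1"], 1e-6)
  expect_gt(assoc$t[assoc$module == "M1"], 0)
  expect_equal(assoc$q, adjust_bh(assoc$p), tolerance = 1e-12)

  a <- data.frame(module = c("M1", "M2", "M3"), level = "case",
                  t = c(3, 3, 3), p = 0.01)
  b <- data.frame(module = c("M1", "M2", "M3"), level = "drug",
                  t = c(2.5, -2.5, 1.0), p = 0.01)
  conv <- classify_convergence(a, b, t_threshold = 2)
  expect_equal(conv$classification[conv$module == "M1"], "convergent")
  expect_equal(conv$classification[conv$module == "M2"], "divergent")
  expect_equal(conv$classification[conv$module == "M3"], "indeterminate")
})
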