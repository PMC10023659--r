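test_that("signature scores obey the dot-product identities", {
  betas <- data.frame(gene = c("g1", "g2"), beta = c(1, -2), p = c(0.01, 0.01))

  r0 <- matrix(0, 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  sc0 <- signature_scores(r0, betas)
  expect_identical(unname(sc0$score), c(0, 0, 0))

  # residual column equal to the beta vector: score = sum(beta^2)
  rb <- matrix(c(1, -2), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(unname(signature_scores(rb, betas)$score), sum(c(1, -2)^2))

  # (0.5, 0.5) . (1, -2) = -0.5
  r5 <- matrix(c(0.5, 0.5), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(unname(signature_scores(r5, betas)$score), -0.5)

  # only genes below the p threshold enter
  betas2 <- betas; betas2$p[2] <- 0.5
  expect_equal(unname(signature_scores(r5, betas2)$score), 0.5)
  expect_equal(signature_scores(r5, betas2)$n_genes_used, 1)
  betas3 <- betas; betas3$p <- c(0.9, 0.9)
  expect_error(signature_scores(r5, betas3), "no genes pass")
})

test_that("signature scoring is linear in the residual matrix", {
  set.seed(1)
  betas <- data.frame(gene = paste0("g", 1:30), beta = rnorm(30),
                      p = runif(30, 0, 0.04))
  r1 <- matrix(rnorm(30 * 8), 30, 8, dimnames = list(betas$gene, paste0("s", 1:8)))
  r2 <- matrix(rnorm(30 * 8), 30, 8, dimnames = dimnames(r1))
  s_combo <- signature_scores(2 * r1 + 3 * r2, betas)$score
  expect_equal(s_combo,
               2 * signature_scores(r1, betas)$score +
                 3 * signature_scores(r2, betas)$score,
               tolerance = 1e-10)
})

test_that("case scores exceed control scores when betas come from the same contrast", {
  sim <- simulate_bulk_cohort(sim_config(n_genes = 400), seed = 21)
  f <- filter_genes(sim$counts, min_fraction = 0.5)
  res <- residualize(log_cpm(f, tmm_factors(f))$logcpm,
                     design_covariates = c("batch", "sex", "age", "rin"),
                     sample_table = sim$sample_table)
  de <- fit_contrast(res, sim$sample_table, c("diagnosis", "control", "case"))
  sc <- signature_scores(res, de)
  is_case <- sim$sample_table$diagnosis == "case"
  expect_gt(mean(sc$score[is_case]), mean(sc$score[!is_case]))
})

test_that("normality gate reproduces the reference Shapiro-Wilk p", {
  x <- as.numeric(1:50)
  gate <- normality_gate(x)
  expect_equal(gate$shapiro_p, stats::shapiro.test(x)$p.value, tolerance = 1e-12)
  set.seed(2)
  g <- rnorm(100)
  expect_true(normality_gate(g)$parametric_ok)
  expect_error(normality_gate(rep(1, 10)), "constant")
  expect_error(normality_gate(c(1, 2)), "3 <= n")
})

test_that("Kruskal-Wallis H follows the rank formula with its tie conventions", {
  kw <- kruskal_wallis(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(kw$statistic, 2.4, tolerance = 1e-12)
  expect_equal(kw$df, 1)

  tied <- kruskal_wallis(rep(7, 8), rep(c("a", "b"), 4))
  expect_equal(tied$statistic, 0)
  expect_equal(tied$p, 1)

  set.seed(3)
  strong <- kruskal_wallis(c(rnorm(10), rnorm(10, 10)), rep(c("a", "b"), each = 10))
  expect_lt(strong$p, 0.001)
})

test_that("Mann-Whitney switches between exact enumeration and normal approximation", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 0.1, tolerance = 1e-12)   # 2/20 arrangements

  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 1)

  set.seed(4)
  x <- rnorm(30); y <- rnorm(40, 0.3)
  rr <- rank(c(x, y))
  U <- sum(rr[1:30]) - 30 * 31 / 2
  z <- (U - 600 - sign(U - 600) * 0.5) / sqrt(30 * 40 * 71 / 12)
  expect_equal(mann_whitney(x, y)$p, 2 * stats::pnorm(-abs(z)), tolerance = 1e-8)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("Dunn z statistics match a hand-computed fixture", {
  d <- dunn_posthoc(1:9, rep(c("A", "B", "C"), each = 3))
  # mean ranks 2/5/8, no ties: z_AB = -3 / sqrt(7.5 * 2/3)
  expect_equal(d$z[d$group_i == "A" & d$group_j == "B"], -3 / sqrt(5),
               tolerance = 1e-12)
  expect_equal(d$z[d$group_i == "A" & d$group_j == "C"], -6 / sqrt(5),
               tolerance = 1e-12)
  expect_equal(d$p, 2 * stats::pnorm(-abs(d$z)), tolerance = 1e-12)
  expect_equal(d$q, stats::p.adjust(d$p, "BH"), tolerance = 1e-12)

  # identical groups: z = 0, p = 1
  d2 <- dunn_posthoc(c(1, 2, 3, 1, 2, 3, 9, 9, 9),
                     rep(c("A", "B", "C"), each = 3))
  expect_equal(d2$z[d2$group_i == "A" & d2$group_j == "B"], 0, tolerance = 1e-12)
  expect_error(dunn_posthoc(1:4, c("a", "a", "b", "b")), ">= 3 groups")
})

test_that("the group-test battery reports every comparison family", {
  sim <- simulate_bulk_cohort(sim_config(n_genes = 300), seed = 22)
  f <- filter_genes(sim$counts, min_fraction = 0.5)
  res <- residualize(log_cpm(f, tmm_factors(f))$logcpm,
                     design_covariates = "batch", sample_table = sim$sample_table)
  de <- fit_contrast(res, sim$sample_table, c("diagnosis", "control", "case"))
  sc <- signature_scores(res, de)
  gt <- signature_group_tests(sc, sim$sample_table)
  expect_named(gt, c("shapiro", "kw_all", "kw_subgroups", "mwu_case_control", "dunn"))
  expect_equal(nrow(gt$dunn), choose(5, 2))
  expect_lt(gt$kw_all$p, 0.05)
})
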