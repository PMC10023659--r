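make_ref <- function() {
  # 4 cells per label, deterministic counts; 12 genes
  p_exn <- c(100L, 10L, 10L, 5L, 5L, 20L, 80L, 2L, 7L, 30L, 1L, 12L)
  p_inn <- c(10L, 100L, 10L, 5L, 20L, 5L, 2L, 80L, 30L, 7L, 12L, 1L)
  p_ast <- c(10L, 10L, 100L, 20L, 5L, 5L, 7L, 30L, 2L, 80L, 6L, 40L)
  counts <- rbind(
    matrix(rep(p_exn, each = 4), 4, 12),
    matrix(rep(p_inn, each = 4), 4, 12),
    matrix(rep(p_ast, each = 4), 4, 12)
  )
  dimnames(counts) <- list(sprintf("c%02d", 1:12), sprintf("g%d", 1:12))
  list(counts = counts, cell_type = rep(c("ExN", "InN", "Astro"), each = 4))
}

test_that("reference profiles are CPM means with merge and drop applied", {
  ref <- make_ref()
  prof <- build_reference_profiles(ref)
  expect_equal(rownames(prof), c("ExN", "InN", "Astro"))
  # identical cells per type: profile = that cell's CPM vector
  cpm1 <- ref$counts[1, ] / sum(ref$counts[1, ]) * 1e6
  expect_equal(unname(prof["ExN", ]), unname(cpm1), tolerance = 1e-10)

  merged <- build_reference_profiles(ref, merge_map = list(Neu = c("ExN", "InN")))
  expect_setequal(rownames(merged), c("Neu", "Astro"))
  exn_cpm <- ref$counts[1, ] / sum(ref$counts[1, ]) * 1e6
  inn_cpm <- ref$counts[5, ] / sum(ref$counts[5, ]) * 1e6
  expect_equal(unname(merged["Neu", ]), unname((exn_cpm + inn_cpm) / 2),
               tolerance = 1e-10)

  dropped <- build_reference_profiles(ref, drop_list = "Astro")
  expect_false("Astro" %in% rownames(dropped))
  expect_error(build_reference_profiles(ref,
                                        merge_map = list(bad = c("ExN", "Astro")),
                                        drop_list = "Astro"), "dropped")
  expect_error(build_reference_profiles(ref, drop_list = c("InN", "Astro")),
               "fewer than 2")
})

test_that("proportions are exactly recovered from noiseless convex mixtures", {
  ref <- make_ref()
  prof <- build_reference_profiles(ref)
  w <- c(ExN = 0.3, InN = 0.7, Astro = 0)
  bulk <- t(prof) %*% w
  bulk <- cbind(mix = bulk[, 1], pure = t(prof)["g1", ] * 0 + t(prof) %*% c(1, 0, 0))
  colnames(bulk) <- c("mix", "pure")
  est <- estimate_proportions(bulk * 3, prof)   # scale invariance included
  expect_equal(unname(est$proportions["mix", ]), unname(w), tolerance = 1e-6)
  expect_equal(unname(est$proportions["pure", "ExN"]), 1, tolerance = 1e-6)
  expect_equal(unname(rowSums(est$proportions)), c(1, 1), tolerance = 1e-9)
})

test_that("up to 8 independent profiles are recovered from exact mixtures", {
  set.seed(15)
  k <- 8; g <- 200
  prof <- matrix(rgamma(k * g, 2, 0.01), k, g,
                 dimnames = list(paste0("T", 1:k), paste0("g", 1:g)))
  prof <- prof / rowSums(prof) * 1e6
  w <- matrix(rgamma(5 * k, 1), 5, k)
  w <- w / rowSums(w)
  bulk <- t(prof) %*% t(w)
  colnames(bulk) <- paste0("s", 1:5)
  est <- estimate_proportions(bulk, prof)
  expect_lt(max(abs(est$proportions - w)), 1e-6)
})

test_that("overlap-based moment matching corrects a distorted bulk", {
  set.seed(16)
  r <- simulate_reference(sim_config(n_genes = 300), seed = 16, noise = FALSE)
  prof <- t(r$profiles)
  # distort the bulk gene-wise; use true composite as the overlap reference
  distort <- runif(nrow(r$bulk), 0.3, 3)
  bulk_d <- r$bulk * distort
  comp <- r$profiles %*% t(r$truth[1:5, ])   # composites for 5 overlap samples
  est_plain <- estimate_proportions(bulk_d, prof)
  est_mm <- estimate_proportions(bulk_d, prof,
                                 overlap = list(bulk_ids = colnames(r$bulk)[1:5],
                                                ref_composite = comp))
  err_plain <- mean(abs(est_plain$proportions - r$truth))
  err_mm <- mean(abs(est_mm$proportions - r$truth))
  expect_lt(err_mm, err_plain)
})

test_that("proportion group tests report per-type KW and MWU with BH families", {
  r <- simulate_reference(sim_config(n_genes = 300), seed = 17)
  prof <- build_reference_profiles(r$reference)
  est <- estimate_proportions(r$bulk, prof)
  tests <- compare_proportions(est, r$sample_table)
  expect_setequal(unique(tests$test), c("kw_all", "mwu_case_control"))
  expect_equal(sum(tests$test == "mwu_case_control"), 3)
  for (tst in unique(tests$test)) {
    sel <- tests$test == tst
    expect_equal(tests$q[sel], adjust_bh(tests$p[sel]), tolerance = 1e-12)
  }
  # the planted InN decrease has the right direction
  inn <- tests[tests$cell_type == "InN" & tests$test == "mwu_case_control", ]
  expect_equal(inn$direction, -1)

  # constant proportions: degenerate conventions hold
  cp <- matrix(1 / 3, 6, 3, dimnames = list(paste0("s", 1:6), c("A", "B", "C")))
  st <- data.frame(sample_id = rownames(cp),
                   group = rep(c("control", "case"), 3))
  ct <- compare_proportions(cp, st)
  expect_true(all(ct$p[ct$test == "kw_all"] == 1))
})
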