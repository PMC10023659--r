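#' Associate candidate covariates with principal components
#'
#' For each candidate covariate and each PC: continuous covariates are
#' tested by a Pearson correlation test, categorical covariates by one-way
#' ANOVA of PC scores on the levels. Each covariate's summary is its
#' minimum Bonferroni-adjusted p across the tested PCs.
#'
#' @param pca A `pcares` list from [pca_scores()].
#' @param sample_table Metadata data.frame, rows aligned with the score rows.
#' @param candidates Character vector of column names to test.
#' @param n_pcs Number of leading PCs to test (default all available).
#' @return List: `table` (covariate x PC p-value matrix), `min_adj_p`
#'   (named vector of Bonferroni-adjusted minima), `excluded` (constant
#'   covariates dropped with a warning).
#' @export
associate_covariates <- function(pca, sample_table, candidates,
                                 n_pcs = ncol(pca$scores)) {
  stopifnot(nrow(sample_table) == nrow(pca$scores))
  n_pcs <- min(n_pcs, ncol(pca$scores))
  excluded <- character(0)
  usable <- character(0)
  for (cv in candidates) {
    if (!cv %in% colnames(sample_table)) stop("unknown covariate: ", cv)
    x <- sample_table[[cv]]
    n_lv <- length(unique(x[!is.na(x)]))
    if (n_lv < 2L) {
      warning("covariate '", cv, "' is constant; excluded")
      excluded <- c(excluded, cv)
    } else {
      usable <- c(usable, cv)
    }
  }
  tab <- matrix(NA_real_, length(usable), n_pcs,
                dimnames = list(usable, colnames(pca$scores)[seq_len(n_pcs)]))
  for (cv in usable) {
    x <- sample_table[[cv]]
    for (j in seq_len(n_pcs)) {
      s <- pca$scores[, j]
      if (is.numeric(x)) {
        tab[cv, j] <- stats::cor.test(x, s)$p.value
      } else {
        fit <- stats::aov(s ~ factor(x))
        tab[cv, j] <- summary(fit)[[1]][["Pr(>F)"]][1]
      }
    }
  }
  min_adj <- apply(tab, 1, function(p) min(pmin(p * n_pcs, 1)))
  list(table = tab, min_adj_p = min_adj, excluded = excluded)
}

#' Greedy sequential covariate selection against expression PCs
#'
#' Iterates: (1) PCA of the current residual matrix, (2) test all remaining
#' candidates against the top PCs, (3) add the covariate with the smallest
#' Bonferroni-adjusted minimum p if below `alpha` (exact ties broken
#' lexicographically by covariate name), (4) regress it out of the
#' expression matrix. Stops when no candidate is significant, `max_iter` is
#' reached, or the accumulated design becomes rank-deficient (collinear
#' duplicates are therefore selected at most once).
#'
#' @param norm_expr `normexpr` list or genes x samples matrix.
#' @param sample_table Metadata data.frame.
#' @param candidates Candidate covariate column names.
#' @param alpha Significance threshold on the adjusted minimum p.
#' @param max_iter Maximum covariates selected.
#' @param n_pcs PCs tested per iteration (default 20).
#' @param recompute_pcs Recompute the PCA after each regression (default
#'   `TRUE`); with `FALSE` the PCs of the input matrix are reused and only
#'   the candidate set shrinks.
#' @return List of class `covselect`: `selected` (ordered names),
#'   `log` (one data.frame row per iteration), `association` (last
#'   association table).
#' @export
select_covariates_sequential <- function(norm_expr, sample_table, candidates,
                                         alpha = 0.05, max_iter = 10,
                                         n_pcs = 20, recompute_pcs = TRUE) {
  x <- if (inherits(norm_expr, "normexpr")) norm_expr$logcpm else norm_expr
  selected <- character(0)
  log_rows <- list()
  remaining <- candidates
  current <- x
  pca0 <- NULL
  assoc <- NULL
  for (it in seq_len(max_iter)) {
    if (!length(remaining)) break
    if (recompute_pcs || is.null(pca0)) {
      pca0 <- pca_scores(current, n_components = min(n_pcs, ncol(current) - 1L))
    }
    assoc <- associate_covariates(pca0, sample_table, remaining)
    remaining <- setdiff(remaining, assoc$excluded)
    if (!length(assoc$min_adj_p)) break
    p <- assoc$min_adj_p
    best <- names(p)[order(p, names(p))][1]
    log_rows[[it]] <- data.frame(iteration = it, covariate = best,
                                 min_adj_p = p[[best]],
                                 selected = p[[best]] < alpha)
    if (p[[best]] >= alpha) break
    # rank check before committing the new covariate
    design_try <- build_design(sample_table, c(selected, best))
    if (qr(design_try)$rank < ncol(design_try)) {
      log_rows[[it]]$selected <- FALSE
      remaining <- setdiff(remaining, best)
      next
    }
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    current <- residualize(current, design_covariates = best,
                           sample_table = sample_table)$residuals
  }
  structure(list(selected = selected,
                 log = if (length(log_rows)) do.call(rbind, log_rows) else
                   data.frame(iteration = integer(), covariate = character(),
                              min_adj_p = numeric(), selected = logical()),
                 association = assoc),
            class = "covselect")
}

#' Build a design matrix (intercept + covariates)
#'
#' Categorical covariates are expanded to treatment-coded indicators.
#'
#' @param sample_table Metadata data.frame.
#' @param covariates Covariate column names (may be empty).
#' @return A numeric design matrix with `nrow(sample_table)` rows.
#' @export
build_design <- function(sample_table, covariates = character()) {
  if (!length(covariates)) {
    return(matrix(1, nrow(sample_table), 1, dimnames = list(NULL, "(Intercept)")))
  }
  missing <- setdiff(covariates, colnames(sample_table))
  if (length(missing)) stop("unknown covariate(s): ", paste(missing, collapse = ", "))
  sub <- sample_table[, covariates, drop = FALSE]
  if (anyNA(sub)) stop("missing covariate value(s); no imputation is performed")
  sub <- droplevels(sub)
  stats::model.matrix(~ ., data = sub)
}

#' Covariate-corrected residual expression
#'
#' Per-gene (weighted) least squares of expression on the design
#' (intercept + covariates); returns the residual matrix. With per-gene
#' observation weights the fit is done gene by gene; unweighted fits use a
#' single projection. The weighted cross-product of each gene's residuals
#' with every design column is ~0 (checked in tests to 1e-8).
#'
#' @param norm_expr `normexpr` list or genes x samples matrix.
#' @param weights Optional genes x samples positive weight matrix.
#' @param design_covariates Covariate column names to regress out.
#' @param sample_table Metadata supplying the covariates.
#' @param design Alternatively, a ready-made design matrix (overrides
#'   `design_covariates`).
#' @return List of class `residmat`: `residuals` (genes x samples),
#'   `design_covariates`, `weighted` flag.
#' @export
residualize <- function(norm_expr, weights = NULL,
                        design_covariates = character(),
                        sample_table = NULL, design = NULL) {
  y <- if (inherits(norm_expr, "normexpr")) norm_expr$logcpm else norm_expr
  if (is.null(design)) {
    if (length(design_covariates) && is.null(sample_table)) {
      stop("sample_table required when design_covariates are named")
    }
    design <- build_design(if (is.null(sample_table))
      data.frame(row.names = seq_len(ncol(y))) else sample_table,
      design_covariates)
  }
  if (nrow(design) != ncol(y)) stop("design rows must match samples")
  if (qr(design)$rank < ncol(design)) stop("design is rank-deficient")
  if (is.null(weights)) {
    qr_d <- qr(design)
    resid <- t(qr.resid(qr_d, t(y)))
  } else {
    stopifnot(all(dim(weights) == dim(y)), all(weights > 0))
    resid <- y
    for (g in seq_len(nrow(y))) {
      fit <- stats::lm.wfit(design, y[g, ], weights[g, ])
      resid[g, ] <- fit$residuals
    }
  }
  dimnames(resid) <- dimnames(y)
  structure(list(residuals = resid,
                 design_covariates = design_covariates,
                 weighted = !is.null(weights)),
            class = "residmat")
}
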