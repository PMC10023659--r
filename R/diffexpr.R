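#' Per-gene two-group contrast test
#'
#' Per-gene (weighted) least squares of expression on a two-level group
#' indicator. `beta` is the coefficient of the second level (case /
#' treatment) versus the first (control / reference), i.e. a log2 fold
#' change when the input is logCPM residuals. With `moderation = TRUE`
#' residual variances are shrunk toward a common prior by an
#' empirical-Bayes method-of-moments fit of a scaled inverse-chi-square
#' prior (limma's squeezeVar), with the t degrees of freedom augmented by
#' the prior df. Zero-residual-variance genes get `p = 0` if `beta != 0`
#' (flagged in the `degenerate` column) and `p = 1` if `beta == 0`.
#'
#' @param expr Genes x samples matrix (typically logCPM residuals) or a
#'   `residmat` list.
#' @param sample_table Metadata with the contrast column.
#' @param contrast Length-3 character vector: column name, reference level,
#'   test level. `beta` is test minus reference.
#' @param weights Optional genes x samples positive weight matrix.
#' @param moderation Shrink residual variances (default `TRUE`).
#' @return A data.frame (one row per gene): `gene`, `beta`, `se`, `t`,
#'   `df`, `p`, `q` (BH), `mean_expression`, `degenerate`.
#' @export
fit_contrast <- function(expr, sample_table, contrast, weights = NULL,
                         moderation = TRUE) {
  y <- if (inherits(expr, "residmat")) expr$residuals else expr
  stopifnot(length(contrast) == 3)
  col <- contrast[1]
  if (!col %in% colnames(sample_table)) stop("unknown contrast column: ", col)
  if (nrow(sample_table) != ncol(y)) {
    stop("sample_table rows must match expression columns")
  }
  grp <- as.character(sample_table[[col]])
  keep <- grp %in% contrast[2:3]
  if (sum(grp == contrast[2]) < 2 || sum(grp == contrast[3]) < 2) {
    stop("each contrast level needs >= 2 samples")
  }
  y <- y[, keep, drop = FALSE]
  g <- as.numeric(grp[keep] == contrast[3])
  w <- if (is.null(weights)) NULL else weights[, keep, drop = FALSE]
  n <- length(g)
  df <- n - 2

  if (is.null(w)) w <- matrix(1, nrow(y), n)
  # closed-form per-gene WLS for design [1, g], vectorized over genes
  sw <- rowSums(w)
  swx <- w %*% g
  swx2 <- w %*% (g^2)
  swy <- rowSums(w * y)
  swxy <- (w * y) %*% g
  det <- sw * swx2 - swx^2
  beta <- as.vector((sw * swxy - swx * swy) / det)
  alpha <- as.vector((swx2 * swy - swx * swxy) / det)
  fitted <- outer(alpha, rep(1, n)) + outer(beta, g)
  rss <- rowSums(w * (y - fitted)^2)
  s2 <- rss / df
  var_beta_unit <- as.vector(sw / det)   # times sigma^2

  if (moderation) {
    sq <- limma::squeezeVar(s2, df)
    s2_post <- sq$var.post
    df_total <- df + sq$df.prior
  } else {
    s2_post <- s2
    df_total <- rep(df, length(s2))
  }
  se <- sqrt(s2_post * var_beta_unit)
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df_total)

  degenerate <- s2 < 1e-12 & !moderation
  if (any(degenerate)) {
    p[degenerate] <- ifelse(abs(beta[degenerate]) > 1e-12, 0, 1)
    tstat[degenerate] <- ifelse(abs(beta[degenerate]) > 1e-12,
                                sign(beta[degenerate]) * Inf, 0)
  }
  data.frame(
    gene = rownames(y),
    beta = beta,
    se = se,
    t = tstat,
    df = if (length(df_total) == 1) rep(df_total, nrow(y)) else df_total,
    p = p,
    q = adjust_bh(p),
    mean_expression = rowMeans(y),
    degenerate = degenerate,
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j`, monotone non-decreasing in p.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return q-values aligned with the input.
#' @export
adjust_bh <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Subgroup contrasts against controls
#'
#' One [fit_contrast()] per toxicology subgroup level found in the
#' metadata, each against the control level, with per-contrast BH.
#'
#' @param expr Residual expression matrix or `residmat`.
#' @param sample_table Metadata with `diagnosis` and `tox_group`.
#' @param weights Optional weight matrix.
#' @param moderation Passed through to [fit_contrast()].
#' @return Named list of DE data.frames, one per subgroup.
#' @export
subgroup_contrasts <- function(expr, sample_table, weights = NULL,
                               moderation = TRUE) {
  levels_present <- setdiff(unique(as.character(
    sample_table$tox_group[sample_table$diagnosis == "case"])), NA)
  out <- list()
  tab <- sample_table
  tab$subgrp <- ifelse(tab$diagnosis == "control", "control",
                       as.character(tab$tox_group))
  for (lv in levels_present) {
    out[[lv]] <- fit_contrast(expr, tab, c("subgrp", "control", lv),
                              weights = weights, moderation = moderation)
  }
  out
}

#' Cross-dataset t-statistic concordance
#'
#' Matches genes strictly via the one-to-one orthology map and correlates
#' the per-gene t-statistics of the two DE results.
#'
#' @param de_a,de_b DE data.frames from [fit_contrast()].
#' @param orthology Data.frame with `gene_a`, `gene_b`.
#' @return List: `pearson_r`, `spearman_rho`, `n_matched`.
#' @export
cross_concordance <- function(de_a, de_b, orthology) {
  ia <- match(orthology$gene_a, de_a$gene)
  ib <- match(orthology$gene_b, de_b$gene)
  ok <- !is.na(ia) & !is.na(ib)
  if (sum(ok) < 3) stop("fewer than 3 ortholog-matched genes")
  ta <- de_a$t[ia[ok]]
  tb <- de_b$t[ib[ok]]
  list(
    pearson_r = stats::cor(ta, tb, method = "pearson"),
    spearman_rho = stats::cor(ta, tb, method = "spearman"),
    n_matched = sum(ok)
  )
}
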