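#' Per-sample disease expression signature scores
#'
#' The aggregated differential-expression score: each sample's
#' covariate-corrected expression (logCPM residuals) is projected, via dot
#' product, onto the case-control log fold changes (betas) over all genes
#' with nominal `p <` `p_threshold`:
#' `score_s = sum_g residual[g, s] * beta_g`. A higher score indicates
#' expression deviating from the mean in the direction of cases.
#'
#' @param residuals Genes x samples residual matrix or `residmat` list.
#' @param betas Either a DE data.frame from [fit_contrast()] (columns
#'   `gene`, `beta`, `p`) or any external table with those columns.
#' @param p_threshold Nominal p cutoff for gene inclusion (default 0.05).
#' @return List of class `sigscores`: `score` (named per-sample vector),
#'   `n_genes_used`, `genes_used`.
#' @export
signature_scores <- function(residuals, betas, p_threshold = 0.05) {
  r <- if (inherits(residuals, "residmat")) residuals$residuals else residuals
  stopifnot(all(c("gene", "beta", "p") %in% colnames(betas)))
  pass <- betas$gene[betas$p < p_threshold]
  pass <- intersect(pass, rownames(r))
  if (!length(pass)) {
    stop("no genes pass p < ", p_threshold, " (0 of ", nrow(betas),
         "); cannot compute signature scores")
  }
  b <- betas$beta[match(pass, betas$gene)]
  score <- as.vector(b %*% r[pass, , drop = FALSE])
  structure(list(score = stats::setNames(score, colnames(r)),
                 n_genes_used = length(pass),
                 genes_used = pass),
            class = "sigscores")
}

#' Leave-one-out signature scores
#'
#' Clean-inference variant: for each sample, the case-control betas are
#' refit with that sample excluded before projection, removing the
#' circularity of scoring samples on betas estimated from themselves.
#'
#' @param residuals Genes x samples residual matrix or `residmat`.
#' @param sample_table Metadata with the contrast column.
#' @param contrast As in [fit_contrast()].
#' @param p_threshold Nominal p cutoff, applied per refit.
#' @param moderation Passed to [fit_contrast()].
#' @return A `sigscores` list (`n_genes_used` is the median across refits).
#' @export
signature_scores_loo <- function(residuals, sample_table, contrast,
                                 p_threshold = 0.05, moderation = TRUE) {
  r <- if (inherits(residuals, "residmat")) residuals$residuals else residuals
  n <- ncol(r)
  score <- numeric(n)
  used <- integer(n)
  for (i in seq_len(n)) {
    de <- fit_contrast(r[, -i, drop = FALSE], sample_table[-i, , drop = FALSE],
                       contrast, moderation = moderation)
    pass <- de$gene[de$p < p_threshold]
    if (!length(pass)) stop("no genes pass p < ", p_threshold,
                            " when excluding sample ", colnames(r)[i])
    b <- de$beta[match(pass, de$gene)]
    score[i] <- sum(b * r[pass, i])
    used[i] <- length(pass)
  }
  structure(list(score = stats::setNames(score, colnames(r)),
                 n_genes_used = stats::median(used),
                 genes_used = NULL),
            class = "sigscores")
}

#' Shapiro-Wilk normality gate
#'
#' Downstream group comparisons switch to non-parametric tests when the
#' Shapiro-Wilk p is below `alpha`.
#'
#' @param values Numeric vector, 3 <= n <= 5000.
#' @param alpha Gate threshold (default 0.05).
#' @return List: `parametric_ok` (logical), `shapiro_p`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(values) == 0) stop("constant values: normality test undefined")
  p <- stats::shapiro.test(values)$p.value
  list(parametric_ok = p >= alpha, shapiro_p = p)
}

#' Kruskal-Wallis test across groups
#'
#' H statistic with tie correction, p from chi-square with k-1 df. The
#' all-tied degenerate case returns `H = 0, p = 1` by convention.
#'
#' @param scores Numeric vector.
#' @param groups Grouping vector (same length).
#' @return One-row data.frame: `test`, `groups`, `statistic`, `df`, `p`.
#' @export
kruskal_wallis <- function(scores, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (length(scores) < 3) stop("need total n >= 3")
  if (length(unique(scores)) == 1L) {
    return(data.frame(test = "kruskal",
                      groups = paste(levels(groups), collapse = "|"),
                      statistic = 0, df = nlevels(groups) - 1L, p = 1,
                      stringsAsFactors = FALSE))
  }
  kt <- stats::kruskal.test(scores, groups)
  data.frame(test = "kruskal",
             groups = paste(levels(groups), collapse = "|"),
             statistic = unname(kt$statistic), df = unname(kt$parameter),
             p = kt$p.value, stringsAsFactors = FALSE)
}

#' Mann-Whitney U test between two groups
#'
#' Exact enumeration p when both groups have n <= `exact_below` and there
#' are no ties; otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param x,y Numeric vectors.
#' @param exact_below Exact-enumeration size limit per group (default 20).
#' @return One-row data.frame: `test`, `statistic` (U for x), `p`,
#'   `direction` (sign of median difference x - y).
#' @export
mann_whitney <- function(x, y, exact_below = 20) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= exact_below && length(y) <= exact_below && !ties
  wt <- stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  data.frame(test = "mwu", statistic = unname(wt$statistic), p = wt$p.value,
             direction = sign(stats::median(x) - stats::median(y)),
             stringsAsFactors = FALSE)
}

#' Dunn post hoc pairwise tests after Kruskal-Wallis
#'
#' Rank-based pairwise z statistics with tie correction:
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j))` with
#' `T = sum(t^3 - t) / (12 (N - 1))` over tie groups; two-sided normal p,
#' adjusted across all pairs (BH by default).
#'
#' @param scores Numeric vector.
#' @param groups Grouping vector with >= 3 levels present.
#' @param adjust Multiplicity adjustment across pairs (`p.adjust` method).
#' @return Data.frame, one row per pair: `group_i`, `group_j`, `z`, `p`,
#'   `q`.
#' @export
dunn_posthoc <- function(scores, groups, adjust = "BH") {
  groups <- factor(groups)
  if (nlevels(groups) < 3) stop("Dunn post hoc needs >= 3 groups")
  if (any(table(groups) == 0)) stop("empty group")
  N <- length(scores)
  r <- rank(scores)
  tie_tab <- table(scores)
  T_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  mean_rank <- tapply(r, groups, mean)
  n_g <- table(groups)
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    denom <- sqrt((N * (N + 1) / 12 - T_corr) * (1 / n_g[[i]] + 1 / n_g[[j]]))
    z[k] <- if (denom == 0) 0 else (mean_rank[[i]] - mean_rank[[j]]) / denom
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group_i = pairs[1, ], group_j = pairs[2, ], z = z, p = p,
             q = stats::p.adjust(p, method = adjust),
             stringsAsFactors = FALSE)
}

#' Non-parametric group-comparison report for signature scores
#'
#' Reproduces the study's test battery: Shapiro-Wilk gate, Kruskal-Wallis
#' across all groups (controls + case subgroups), Kruskal-Wallis within
#' case subgroups only, Mann-Whitney U between cases and controls, and
#' Dunn post hoc tests across all groups.
#'
#' @param scores A `sigscores` list or named numeric vector.
#' @param sample_table Metadata with `diagnosis` and `tox_group`.
#' @return List: `shapiro`, `kw_all`, `kw_subgroups`, `mwu_case_control`,
#'   `dunn` (data.frames as returned by the individual tests).
#' @export
signature_group_tests <- function(scores, sample_table) {
  s <- if (inherits(scores, "sigscores")) scores$score else scores
  stopifnot(!is.null(names(s)))
  tab <- sample_table[match(names(s), sample_table$sample_id), ]
  grp <- ifelse(tab$diagnosis == "control", "control",
                as.character(tab$tox_group))
  is_case <- tab$diagnosis == "case"
  gate <- normality_gate(s)
  list(
    shapiro = gate,
    kw_all = kruskal_wallis(s, grp),
    kw_subgroups = kruskal_wallis(s[is_case], grp[is_case]),
    mwu_case_control = mann_whitney(s[is_case], s[!is_case]),
    dunn = dunn_posthoc(s, grp)
  )
}
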