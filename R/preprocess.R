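#' Filter genes by CPM threshold
#'
#' Keeps genes with CPM above `cpm_threshold` (CPM computed on raw library
#' sizes, no pseudocount) in at least the required number of samples. The
#' two dataset presets used in practice are expressed through the same
#' operation: "CPM > 1 in >= 50% of samples" via `min_fraction = 0.5`, and
#' "CPM > 1 in >= 3 samples" via `min_samples = 3`.
#'
#' @param counts Integer matrix, genes x samples.
#' @param cpm_threshold CPM cutoff (exclusive).
#' @param min_fraction Minimum fraction of samples exceeding the cutoff.
#' @param min_samples Minimum number of samples exceeding the cutoff.
#'   Exactly one of `min_fraction` / `min_samples` must be given.
#' @return The filtered count matrix (same samples).
#' @export
filter_genes <- function(counts, cpm_threshold = 1, min_fraction = NULL,
                         min_samples = NULL) {
  if (is.null(min_fraction) == is.null(min_samples)) {
    stop("give exactly one of min_fraction or min_samples")
  }
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample(s) with zero library size")
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  need <- if (!is.null(min_fraction)) ceiling(min_fraction * ncol(counts)) else min_samples
  keep <- rowSums(cpm > cpm_threshold) >= need
  if (!any(keep)) {
    stop("all genes removed at CPM > ", cpm_threshold,
         "; lower the threshold or the required sample count")
  }
  counts[keep, , drop = FALSE]
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values scale factors (Robinson & Oshlack): per sample,
#' a doubly-trimmed, precision-weighted mean of gene-wise log2 expression
#' ratios against a reference sample (chosen automatically as the sample
#' whose 75th expression percentile is closest to the mean of those
#' percentiles). Factors are rescaled to geometric mean 1. Computation is
#' delegated to edgeR's TMM implementation.
#'
#' @param counts Integer matrix, genes x samples (>= 2 samples).
#' @param trim_m Trim fraction on log-ratios (each tail).
#' @param trim_a Trim fraction on average log expression (each tail).
#' @return Named numeric vector of per-sample factors.
#' @export
tmm_factors <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  if (ncol(counts) < 2) stop("TMM needs >= 2 samples")
  if (any(colSums(counts) == 0)) stop("sample(s) with zero library size")
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = trim_m, sumTrim = trim_a)
  if (any(!is.finite(f)) || any(f <= 0)) {
    stop("TMM failed: a sample shares no expressed genes with the reference")
  }
  stats::setNames(f, colnames(counts))
}

#' log2 counts-per-million with normalized library sizes
#'
#' `logcpm[g, s] = log2((count + prior) / (lib * factor + 2 * prior) * 1e6)`.
#'
#' @param counts Integer matrix, genes x samples.
#' @param factors Per-sample TMM factors (default all 1).
#' @param prior_count Pseudocount (default 0.5).
#' @return List of class `normexpr`: `logcpm` matrix, `tmm_factors`,
#'   `library_sizes`, `prior_count`.
#' @export
log_cpm <- function(counts, factors = NULL, prior_count = 0.5) {
  lib <- colSums(counts)
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  if (any(factors <= 0)) stop("factors must be positive")
  eff <- lib * factors
  logcpm <- log2(sweep(sweep(counts, 2, prior_count, "+"),
                       2, eff + 2 * prior_count, "/") * 1e6)
  structure(list(logcpm = logcpm, tmm_factors = factors,
                 library_sizes = lib, prior_count = prior_count),
            class = "normexpr")
}

#' PCA of logCPM expression
#'
#' Gene-centered (no unit-variance scaling) singular value decomposition of
#' the samples x genes matrix. Each component is oriented so its
#' largest-magnitude gene loading is positive, giving a deterministic sign.
#'
#' @param norm_expr A `normexpr` list (or a plain genes x samples matrix).
#' @param n_components Number of components to return (truncated with a
#'   warning if it exceeds the available rank).
#' @return List of class `pcares`: `scores` (samples x K), `loadings`
#'   (genes x K), `explained_variance` (length K fractions).
#' @export
pca_scores <- function(norm_expr, n_components = 20) {
  x <- if (inherits(norm_expr, "normexpr")) norm_expr$logcpm else norm_expr
  max_k <- min(ncol(x) - 1L, nrow(x))
  if (n_components > max_k) {
    warning("n_components truncated from ", n_components, " to ", max_k)
    n_components <- max_k
  }
  xc <- x - rowMeans(x)
  if (all(abs(xc) < 1e-12)) stop("constant expression matrix: PCA undefined")
  pc <- stats::prcomp(t(xc), center = FALSE, scale. = FALSE)
  k <- n_components
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = ev[seq_len(k)]),
            class = "pcares")
}

#' Flag outlier samples from PC scores
#'
#' Standardizes each of the first `top_k` components across samples and
#' flags samples whose |z| exceeds `sd_threshold` in at least `min_pcs`
#' components. Single pass: scores are not recomputed after removal.
#'
#' @param pca A `pcares` list from [pca_scores()].
#' @param sd_threshold SD cutoff (default 5).
#' @param min_pcs Minimum number of offending components (default 2).
#' @param top_k Components examined (default 20).
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
detect_outliers <- function(pca, sd_threshold = 5, min_pcs = 2, top_k = 20) {
  k <- min(top_k, ncol(pca$scores))
  z <- scale(pca$scores[, seq_len(k), drop = FALSE])
  hits <- rowSums(abs(z) > sd_threshold, na.rm = TRUE)
  rownames(pca$scores)[hits >= min_pcs]
}

#' Per-observation precision weights (mean-variance trend)
#'
#' Estimates the voom mean-variance trend: per-gene linear model on logCPM,
#' lowess of sqrt(residual SD) on average log-count, inverse fourth-power
#' weights predicted from each observation's fitted log-count. Delegated to
#' limma's voom with TMM-normalized library sizes; weights are clipped to
#' `[1e-6, 1e6]`.
#'
#' @param counts Integer matrix, genes x samples (>= 10 genes).
#' @param factors Per-sample TMM factors.
#' @param design Design matrix (defaults to intercept only).
#' @param span Lowess span for the trend.
#' @return Weight matrix, genes x samples, strictly positive and finite.
#' @export
voom_weights <- function(counts, factors = NULL, design = NULL, span = 0.5) {
  if (nrow(counts) < 10) stop("voom trend unestimable with < 10 genes")
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  if (is.null(design)) design <- matrix(1, ncol(counts), 1)
  v <- limma::voom(counts, design = design,
                   lib.size = colSums(counts) * factors, span = span)
  w <- pmin(pmax(v$weights, 1e-6), 1e6)
  dimnames(w) <- dimnames(counts)
  w
}
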