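# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive each quantity from its published definition
# (loops, enumeration, closed forms), not from the code paths they test.

# TMM factors: step-by-step trimmed, precision-weighted mean of gene-wise
# log ratios against the auto-selected reference sample.
oracle_tmm <- function(counts, logratioTrim = 0.3, sumTrim = 0.05) {
  lib <- colSums(counts)
  q75 <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(q75 - mean(q75)))
  f <- vapply(seq_len(ncol(counts)), function(i) {
    obs <- as.numeric(counts[, i]); refc <- as.numeric(counts[, ref])
    no <- lib[i]; nr <- lib[ref]
    logR <- log2((obs / no) / (refc / nr))
    absE <- (log2(obs / no) + log2(refc / nr)) / 2
    v <- (no - obs) / no / obs + (nr - refc) / nr / refc
    fin <- is.finite(logR) & is.finite(absE) & (absE > -1e10)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * logratioTrim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * sumTrim) + 1; hiS <- n + 1 - loS
    keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
      (rank(absE) >= loS & rank(absE) <= hiS)
    fk <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
    if (!is.finite(fk)) fk <- 0
    2^fk
  }, numeric(1))
  f / exp(mean(log(f)))
}

# BH step-up from the definition: q_(i) = min_{j >= i} p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(vapply(i:m, function(j) p[o[j]] * m / j, numeric(1)), 1)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Topological overlap by triple loop.
oracle_tom <- function(a) {
  n <- nrow(a)
  ad <- a; diag(ad) <- 0
  k <- rowSums(ad)
  tom <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { tom[i, j] <- 1; next }
    s <- 0
    for (u in seq_len(n)) if (u != i && u != j) s <- s + ad[i, u] * ad[u, j]
    tom[i, j] <- (s + ad[i, j]) / (min(k[i], k[j]) + 1 - ad[i, j])
  }
  tom
}

# Two-sided Fisher p by enumeration over the hypergeometric support, with
# the same relative-epsilon tie rule as the classic summation convention.
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + c_           # genes in set
  nn <- b + d           # genes not in set
  k <- a + b            # list size
  support <- max(0, k - nn):min(k, m)
  dens <- stats::dhyper(support, m, nn, k)
  sum(dens[dens <= stats::dhyper(a, m, nn, k) * (1 + 1e-7)])
}

# Weighted least-squares residuals from the closed-form hat matrix.
oracle_residualize <- function(y, design, weights = NULL) {
  out <- y
  for (g in seq_len(nrow(y))) {
    w <- if (is.null(weights)) rep(1, ncol(y)) else weights[g, ]
    xtw <- t(design * w)
    beta <- solve(xtw %*% design, xtw %*% y[g, ])
    out[g, ] <- y[g, ] - as.vector(design %*% beta)
  }
  out
}

# PCA scores via eigendecomposition of the sample covariance of the
# gene-centered matrix.
oracle_pca_scores <- function(x, k) {
  xc <- x - rowMeans(x)
  cv <- crossprod(xc) / (ncol(x) - 1)   # samples x samples
  # scores from eigenvectors of the Gram matrix
  eg <- eigen(crossprod(xc), symmetric = TRUE)
  scores <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(eg$values[seq_len(k)]), k)
  scores
}

# Pooled-variance two-sample t (unequal sizes) from the textbook formula.
oracle_two_sample_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  (mean(y) - mean(x)) / sqrt(sp2 * (1 / nx + 1 / ny))
}

# Small NB count fixture with dimnames.
make_counts <- function(n_genes, n_samples, mu = 200, size = 5, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rnbinom(n_genes * n_samples, mu = mu, size = size),
              n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  storage.mode(m) <- "integer"
  m
}
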