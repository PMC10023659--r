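#' Signed co-expression adjacency
#'
#' `a_ij = ((1 + cor(x_i, x_j)) / 2)^beta` with Pearson correlation across
#' samples; diagonal 1. The signed transform keeps anticorrelated genes
#' apart (cor -1 -> 0) rather than folding them together.
#'
#' @param expr Genes x samples matrix (residualized expression).
#' @param beta_power Soft-thresholding power (default 12).
#' @return Symmetric genes x genes adjacency in [0, 1].
#' @export
signed_adjacency <- function(expr, beta_power = 12) {
  if (ncol(expr) < 3) stop("need >= 3 samples for co-expression")
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    stop("constant gene(s): ", paste(rownames(expr)[sds == 0], collapse = ", "))
  }
  a <- ((1 + stats::cor(t(expr))) / 2)^beta_power
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `tom_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k` the row sums excluding the diagonal; `tom_ii = 1`. Shared-neighbor
#' sums exclude i and j themselves.
#'
#' @param adjacency Symmetric adjacency in [0, 1] with unit diagonal.
#' @return Symmetric TOM in [0, 1].
#' @export
topological_overlap <- function(adjacency) {
  a <- adjacency
  diag(a) <- 0
  k <- rowSums(a)
  shared <- a %*% a            # sum_u a_iu a_uj, u != i, j handled below
  # remove u = i and u = j contributions (zero because diag(a) = 0)
  num <- shared + a
  kmin <- outer(k, k, pmin)
  tom <- num / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Consensus TOM of two datasets
#'
#' Scales the second TOM multiplicatively so its `scale_quantile` quantile
#' of off-diagonal entries matches the first's, then takes the
#' element-wise minimum, clipped to [0, 1].
#'
#' @param tom_a,tom_b TOM matrices on the same (ortholog-matched, same
#'   order) gene universe.
#' @param scale_quantile Quantile used for scale calibration (default 0.95).
#' @return Consensus TOM matrix.
#' @export
consensus_tom <- function(tom_a, tom_b, scale_quantile = 0.95) {
  if (!identical(dim(tom_a), dim(tom_b))) stop("gene universes differ")
  if (!is.null(rownames(tom_a)) && !is.null(rownames(tom_b)) &&
      !identical(rownames(tom_a), rownames(tom_b))) {
    stop("gene order differs between the two TOMs")
  }
  off <- upper.tri(tom_a)
  qa <- stats::quantile(tom_a[off], scale_quantile)
  qb <- stats::quantile(tom_b[off], scale_quantile)
  scaled_b <- if (qb > 0) tom_b * (qa / qb) else tom_b
  cons <- pmin(tom_a, scaled_b)
  cons[cons < 0] <- 0
  cons[cons > 1] <- 1
  cons
}

# Simplified dynamic cut, approximating a moderate deep-split. The
# average-linkage merge tree is traversed bottom-up (merges in height
# order). A subtree is claimed as a module the first time it (i) reaches
# min_size genes and (ii) is cohesive against the network: mean internal
# similarity > `cohesion` x mean similarity to all other genes. A claimed
# module keeps growing through later merges as long as the joining genes
# are strongly attached (mean similarity to the module >= `join_frac` x
# the module's internal mean); the first loose joiner freezes it, and a
# merge of two claimed modules freezes both. Genes never claimed are left
# unlabeled (0). This handles modules that assemble at different heights,
# which a single global cut height cannot.
cut_tree_simplified <- function(dmat, min_size = 30, cohesion = 2,
                                join_frac = 0.5) {
  n <- nrow(dmat)
  if (n < min_size) return(rep(0L, n))
  sim <- 1 - dmat
  diag(sim) <- 0
  rs <- rowSums(sim)
  hc <- stats::hclust(stats::as.dist(dmat), method = "average")
  claimed <- integer(n)
  next_id <- 0L
  frozen <- logical(0)
  # per tree node: member indices, internal similarity sum (both triangles),
  # and status: "plain" (no module inside), a module id, or NA (dead)
  members <- vector("list", n - 1L)
  wsum <- numeric(n - 1L)
  status <- vector("list", n - 1L)
  node_of <- function(j) {
    if (j < 0) list(m = -j, w = 0, s = "plain")
    else list(m = members[[j]], w = wsum[j], s = status[[j]])
  }
  for (k in seq_len(n - 1L)) {
    a <- node_of(hc$merge[k, 1])
    b <- node_of(hc$merge[k, 2])
    cross <- sum(sim[a$m, b$m])
    mem <- c(a$m, b$m)
    w <- a$w + b$w + 2 * cross
    members[[k]] <- mem
    wsum[k] <- w
    sa <- a$s; sb <- b$s
    if (is.na(sa[1]) || is.na(sb[1]) ||
        (sa[1] != "plain" && sb[1] != "plain")) {
      # dead subtree, or two modules meeting: freeze any module involved
      for (s in c(sa, sb)) if (!is.na(s) && s != "plain") frozen[as.integer(s)] <- TRUE
      status[[k]] <- NA_character_
      next
    }
    if (sa[1] == "plain" && sb[1] == "plain") {
      s <- length(mem)
      if (s >= min_size && s < n) {
        within_mean <- w / (s * (s - 1))
        out_mean <- (sum(rs[mem]) - w) / (s * (n - s))
        if (within_mean > cohesion * out_mean) {
          next_id <- next_id + 1L
          frozen[next_id] <- FALSE
          claimed[mem] <- next_id
          status[[k]] <- as.character(next_id)
          next
        }
      }
      status[[k]] <- "plain"
      next
    }
    # one module + plain joiners: grow if the joiners attach strongly
    mod <- if (sa[1] != "plain") a else b
    oth <- if (sa[1] != "plain") b else a
    id <- as.integer(mod$s)
    if (frozen[id]) { status[[k]] <- NA_character_; next }
    s_mod <- length(mod$m)
    join_mean <- cross / (s_mod * length(oth$m))
    mod_mean <- mod$w / (s_mod * (s_mod - 1))
    if (join_mean >= join_frac * mod_mean) {
      claimed[oth$m] <- id
      status[[k]] <- as.character(id)
    } else {
      frozen[id] <- TRUE
      status[[k]] <- NA_character_
    }
  }
  claimed
}

#' Detect consensus co-expression modules
#'
#' Average-linkage hierarchical clustering on `1 - consensus_tom`, cut by a
#' simplified two-level procedure (99th-percentile merge height, oversized
#' clusters re-cut once). Clusters below `min_size` become "unassigned".
#' Module pairs whose eigengenes correlate above `1 - merge_cut` in BOTH
#' datasets are merged iteratively; genes whose signed kME falls below
#' `min_kme` in either dataset are dropped to "unassigned". Surviving
#' modules are relabeled "M1", "M2", ... by decreasing size.
#'
#' @param cons_tom Consensus TOM matrix.
#' @param expr_a,expr_b The two residual expression matrices (same gene
#'   order as `cons_tom`; datasets may have different samples).
#' @param min_size Minimum module size (default 30).
#' @param merge_cut Eigengene-dissimilarity merge threshold (default 0.25).
#' @param min_kme Minimum signed kME to stay in a module (default 0.3).
#' @param kme_rule `"both"` (default) requires min_kme in both datasets;
#'   `"either"` requires it in at least one.
#' @return List of class `modassign`: `labels` (named gene -> module),
#'   `kme_a`, `kme_b` (gene x module matrices), `sizes`.
#' @export
detect_modules <- function(cons_tom, expr_a, expr_b, min_size = 30,
                           merge_cut = 0.25, min_kme = 0.3,
                           kme_rule = c("both", "either")) {
  kme_rule <- match.arg(kme_rule)
  genes <- rownames(cons_tom)
  stopifnot(identical(genes, rownames(expr_a)),
            identical(genes, rownames(expr_b)))
  raw <- cut_tree_simplified(1 - cons_tom, min_size = min_size)
  labels <- ifelse(raw > 0L & stats::ave(raw, raw, FUN = length) >= min_size,
                   paste0("C", raw), "unassigned")
  names(labels) <- genes
  if (all(labels == "unassigned")) {
    warning("no cluster reaches min_size = ", min_size, "; all unassigned")
    return(structure(list(labels = labels, kme_a = NULL, kme_b = NULL,
                          sizes = integer(0)), class = "modassign"))
  }

  # iterative merge: closest eigengene pair over both datasets
  repeat {
    mods <- setdiff(unique(labels), "unassigned")
    if (length(mods) < 2) break
    eg_a <- module_eigengenes(expr_a, labels)$eigengenes
    eg_b <- module_eigengenes(expr_b, labels)$eigengenes
    cor_a <- stats::cor(t(eg_a[mods, , drop = FALSE]))
    cor_b <- stats::cor(t(eg_b[mods, , drop = FALSE]))
    both <- pmin(cor_a, cor_b)
    diag(both) <- -Inf
    best <- which(both == max(both), arr.ind = TRUE)[1, ]
    if (both[best[1], best[2]] <= 1 - merge_cut) break
    from <- mods[best[2]]; into <- mods[best[1]]
    labels[labels == from] <- into
  }

  # kME filter against the merged modules' eigengenes
  mods <- setdiff(unique(labels), "unassigned")
  eg_a <- module_eigengenes(expr_a, labels)$eigengenes
  eg_b <- module_eigengenes(expr_b, labels)$eigengenes
  kme_a <- stats::cor(t(expr_a), t(eg_a[mods, , drop = FALSE]))
  kme_b <- stats::cor(t(expr_b), t(eg_b[mods, , drop = FALSE]))
  for (m in mods) {
    member <- labels == m
    low <- if (kme_rule == "both") {
      kme_a[member, m] < min_kme | kme_b[member, m] < min_kme
    } else {
      kme_a[member, m] < min_kme & kme_b[member, m] < min_kme
    }
    labels[member][low] <- "unassigned"
  }
  labels[labels %in% names(which(table(labels[labels != "unassigned"]) < min_size))] <- "unassigned"

  # relabel by decreasing size
  sizes <- sort(table(labels[labels != "unassigned"]), decreasing = TRUE)
  new_names <- stats::setNames(paste0("M", seq_along(sizes)), names(sizes))
  labels <- ifelse(labels == "unassigned", "unassigned", new_names[labels])
  names(labels) <- genes
  sizes <- sort(table(labels[labels != "unassigned"]), decreasing = TRUE)

  mods <- names(sizes)
  eg_a <- module_eigengenes(expr_a, labels)$eigengenes
  eg_b <- module_eigengenes(expr_b, labels)$eigengenes
  kme_a <- stats::cor(t(expr_a), t(eg_a[mods, , drop = FALSE]))
  kme_b <- stats::cor(t(expr_b), t(eg_b[mods, , drop = FALSE]))
  structure(list(labels = labels, kme_a = kme_a, kme_b = kme_b,
                 sizes = as.integer(sizes)), class = "modassign")
}

#' Module eigengenes
#'
#' Eigengene = first principal component of the module's gene-standardized
#' expression (samples x genes), scaled to unit variance and oriented so
#' the mean correlation with the module's genes is non-negative.
#' Single-gene modules return that gene standardized.
#'
#' @param expr Genes x samples matrix.
#' @param assignment Named gene -> module label vector (or `modassign`).
#' @return List of class `eigenset`: `eigengenes` (module x samples),
#'   `var_explained` (named fractions).
#' @export
module_eigengenes <- function(expr, assignment) {
  labels <- if (inherits(assignment, "modassign")) assignment$labels else assignment
  mods <- setdiff(unique(labels), c("unassigned", "none"))
  if (!length(mods)) stop("no modules in assignment")
  eg <- matrix(NA_real_, length(mods), ncol(expr),
               dimnames = list(mods, colnames(expr)))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (m in mods) {
    gm <- names(labels)[labels == m]
    x <- expr[gm, , drop = FALSE]
    xs <- t(scale(t(x)))          # standardize each gene across samples
    if (nrow(xs) == 1L) {
      e <- as.vector(xs)
      ve[m] <- 1
    } else {
      sv <- svd(t(xs), nu = 1, nv = 0)
      e <- sv$u[, 1]
      ve[m] <- sv$d[1]^2 / sum(sv$d^2)
    }
    e <- as.vector(scale(e))
    if (mean(stats::cor(e, t(x))) < 0) e <- -e
    eg[m, ] <- e
  }
  structure(list(eigengenes = eg, var_explained = ve), class = "eigenset")
}

#' Eigengene-condition association
#'
#' Per module and per non-reference condition level: ordinary least
#' squares of the eigengene on the level indicator (level samples vs
#' reference samples), two-sided t test on the coefficient, BH across
#' modules within each level. `|t|` is capped at 1e6 for noiseless fits.
#'
#' @param eigengenes `eigenset` list or module x samples matrix.
#' @param sample_table Metadata aligned to the eigengene columns.
#' @param condition Column name of the condition factor; its first level
#'   is the reference.
#' @return Data.frame: `module`, `level`, `beta`, `t`, `p`, `q`.
#' @export
eigengene_association <- function(eigengenes, sample_table, condition) {
  eg <- if (inherits(eigengenes, "eigenset")) eigengenes$eigengenes else eigengenes
  cond <- factor(sample_table[[condition]])
  if (nlevels(cond) < 2) stop("condition needs >= 2 levels")
  ref <- levels(cond)[1]
  out <- list()
  for (lv in levels(cond)[-1]) {
    keep <- cond %in% c(ref, lv)
    if (sum(cond == lv) < 2 || sum(cond == ref) < 2) {
      stop("level '", lv, "' or reference has < 2 samples")
    }
    g <- as.numeric(cond[keep] == lv)
    rows <- lapply(rownames(eg), function(m) {
      y <- eg[m, keep]
      fit <- stats::lm(y ~ g)
      co <- summary(fit)$coefficients
      if (nrow(co) < 2) {
        data.frame(module = m, level = lv, beta = 0, t = 0, p = 1)
      } else {
        tval <- co["g", "t value"]
        tval <- max(min(tval, 1e6), -1e6)
        data.frame(module = m, level = lv, beta = co["g", "Estimate"],
                   t = tval, p = co["g", "Pr(>|t|)"])
      }
    })
    block <- do.call(rbind, rows)
    block$q <- adjust_bh(block$p)
    out[[lv]] <- block
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify module convergence between two condition associations
#'
#' For each module and each (condition_a level, condition_b level) pair:
#' convergent if the two t statistics share a sign and both `|t| >=
#' t_threshold`; divergent if the signs differ and both `|t| >=
#' t_threshold`; otherwise indeterminate.
#'
#' @param assoc_a,assoc_b Association tables from
#'   [eigengene_association()] over the same module set.
#' @param t_threshold Magnitude threshold (default 2.0, about two-sided
#'   p < 0.05 at moderate sample sizes).
#' @return Data.frame: `module`, `condition_a`, `condition_b`, `t_a`,
#'   `t_b`, `classification`.
#' @export
classify_convergence <- function(assoc_a, assoc_b, t_threshold = 2.0) {
  mods <- sort(unique(assoc_a$module))
  if (!setequal(mods, unique(assoc_b$module))) {
    stop("module sets differ between the two association tables")
  }
  rows <- list()
  for (la in unique(assoc_a$level)) {
    for (lb in unique(assoc_b$level)) {
      ta <- assoc_a$t[match(paste(mods, la), paste(assoc_a$module, assoc_a$level))]
      tb <- assoc_b$t[match(paste(mods, lb), paste(assoc_b$module, assoc_b$level))]
      strong <- abs(ta) >= t_threshold & abs(tb) >= t_threshold
      cls <- ifelse(!strong, "indeterminate",
                    ifelse(sign(ta) == sign(tb), "convergent", "divergent"))
      rows[[paste(la, lb)]] <- data.frame(
        module = mods, condition_a = la, condition_b = lb,
        t_a = ta, t_b = tb, classification = cls, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Two-dataset consensus module workflow
#'
#' Convenience wrapper: signed adjacency and TOM per dataset on the
#' ortholog-matched gene universe, consensus TOM, module detection.
#'
#' @param expr_a,expr_b Residual expression matrices.
#' @param orthology Orthology map (gene_a, gene_b); dataset B genes are
#'   re-indexed to dataset A identifiers.
#' @param beta_power,min_size,merge_cut,min_kme,scale_quantile Parameters
#'   passed through to the component operations.
#' @return List: `assignment` (`modassign`), `expr_a`, `expr_b` (matched
#'   matrices on A identifiers).
#' @export
consensus_modules <- function(expr_a, expr_b, orthology, beta_power = 12,
                              min_size = 30, merge_cut = 0.25, min_kme = 0.3,
                              scale_quantile = 0.95) {
  ok <- orthology$gene_a %in% rownames(expr_a) &
    orthology$gene_b %in% rownames(expr_b)
  map <- orthology[ok, , drop = FALSE]
  if (nrow(map) < min_size) stop("too few ortholog-matched genes: ", nrow(map))
  ea <- expr_a[map$gene_a, , drop = FALSE]
  eb <- expr_b[map$gene_b, , drop = FALSE]
  rownames(eb) <- map$gene_a
  tom_a <- topological_overlap(signed_adjacency(ea, beta_power))
  tom_b <- topological_overlap(signed_adjacency(eb, beta_power))
  cons <- consensus_tom(tom_a, tom_b, scale_quantile)
  assignment <- detect_modules(cons, ea, eb, min_size = min_size,
                               merge_cut = merge_cut, min_kme = min_kme)
  list(assignment = assignment, expr_a = ea, expr_b = eb)
}
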