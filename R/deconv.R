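#' Build cell-type reference profiles
#'
#' Applies the configured label merges and drops, then computes each
#' type's profile as the CPM-normalized mean over its cells. Mirrors the
#' usual reference curation for brain single-nucleus data (e.g. combining
#' vascular subtypes, removing stray clusters).
#'
#' @param reference List with `counts` (cells x genes) and `cell_type`
#'   (per-cell labels).
#' @param merge_map Named list: new label -> character vector of labels to
#'   combine.
#' @param drop_list Labels to remove entirely.
#' @return Cell-type x gene profile matrix (rows CPM-scaled means).
#' @export
build_reference_profiles <- function(reference, merge_map = list(),
                                     drop_list = character()) {
  labels <- as.character(reference$cell_type)
  counts <- reference$counts
  stopifnot(nrow(counts) == length(labels))
  for (new in names(merge_map)) {
    old <- merge_map[[new]]
    if (any(old %in% drop_list)) {
      stop("merge target '", new, "' mixes dropped type(s): ",
           paste(intersect(old, drop_list), collapse = ", "))
    }
    labels[labels %in% old] <- new
  }
  keep <- !(labels %in% drop_list)
  labels <- labels[keep]
  counts <- counts[keep, , drop = FALSE]
  types <- unique(labels)
  if (length(types) < 2) stop("fewer than 2 cell types after merge/drop")
  # CPM per cell, then mean within type
  lib <- rowSums(counts)
  if (any(lib == 0)) stop("cell(s) with zero counts")
  cpm <- counts / lib * 1e6
  profiles <- t(vapply(types, function(tp) colMeans(cpm[labels == tp, , drop = FALSE]),
                       numeric(ncol(counts))))
  rownames(profiles) <- types
  profiles
}

#' Estimate cell-type proportions from bulk expression
#'
#' Per sample, non-negative least squares of the bulk CPM vector on the
#' reference profile matrix (all shared genes, no marker pre-selection),
#' renormalized to the unit simplex. When `overlap` is supplied (samples
#' measured in both bulk and reference, used to improve the model), a
#' gene-wise linear moment matching first rescales bulk expression to the
#' reference-composite distribution estimated on the overlap samples.
#'
#' @param bulk Genes x samples matrix (counts or CPM; scale-invariant).
#' @param profiles Cell-type x gene profile matrix from
#'   [build_reference_profiles()].
#' @param overlap Optional list with `bulk_ids` (sample ids present in
#'   `bulk`) and `ref_composite` (genes x overlap-samples matrix of
#'   reference-derived composite expression for the same individuals).
#' @return List of class `propest`: `proportions` (samples x types, rows
#'   on the simplex), `residual_norm` (per-sample NNLS residual).
#' @export
estimate_proportions <- function(bulk, profiles, overlap = NULL) {
  shared <- intersect(rownames(bulk), colnames(profiles))
  if (length(shared) < 10) stop("fewer than 10 shared genes between bulk and reference")
  if (nrow(profiles) < 2) stop("need >= 2 cell types")
  lib <- colSums(bulk)
  if (any(lib == 0)) stop("all-zero bulk sample(s): ",
                          paste(colnames(bulk)[lib == 0], collapse = ", "))
  b <- sweep(bulk[shared, , drop = FALSE], 2, lib, "/") * 1e6
  p <- t(profiles[, shared, drop = FALSE])   # genes x types

  if (!is.null(overlap)) {
    ids <- intersect(overlap$bulk_ids, colnames(b))
    if (length(ids) < 2) stop("need >= 2 overlap samples for moment matching")
    rc <- overlap$ref_composite[shared, , drop = FALSE]
    bo <- b[, ids, drop = FALSE]
    mu_b <- rowMeans(bo); sd_b <- apply(bo, 1, stats::sd)
    mu_r <- rowMeans(rc); sd_r <- apply(rc, 1, stats::sd)
    scale_g <- ifelse(sd_b > 1e-12, sd_r / sd_b, 1)
    shift_g <- mu_r - scale_g * mu_b
    b <- b * scale_g + shift_g
    b[b < 0] <- 0
  }

  n <- ncol(b)
  k <- nrow(profiles)
  props <- matrix(0, n, k, dimnames = list(colnames(b), rownames(profiles)))
  rnorm_ <- numeric(n)
  for (s in seq_len(n)) {
    fit <- pracma::lsqnonneg(p, b[, s])
    x <- fit$x
    if (sum(x) <= 0) stop("degenerate NNLS fit for sample ", colnames(b)[s])
    props[s, ] <- x / sum(x)
    rnorm_[s] <- sqrt(sum(fit$resid.norm))
  }
  structure(list(proportions = props,
                 residual_norm = stats::setNames(rnorm_, colnames(b))),
            class = "propest")
}

#' Group comparisons of estimated proportions
#'
#' Per cell type: Kruskal-Wallis across all groups (controls + case
#' subgroups), Kruskal-Wallis within case subgroups only, and
#' Mann-Whitney U between cases and controls; BH across cell types within
#' each test family.
#'
#' @param props `propest` list or samples x types matrix.
#' @param sample_table Metadata with `sample_id` plus either `group`
#'   (control/case) or `diagnosis`/`tox_group` columns.
#' @return Data.frame: `cell_type`, `test`, `statistic`, `p`, `q`,
#'   `direction` (MWU rows: sign of case minus control median).
#' @export
compare_proportions <- function(props, sample_table) {
  m <- if (inherits(props, "propest")) props$proportions else props
  tab <- sample_table[match(rownames(m), sample_table$sample_id), ]
  if ("diagnosis" %in% colnames(tab)) {
    grp_all <- ifelse(tab$diagnosis == "control", "control",
                      as.character(tab$tox_group))
    is_case <- tab$diagnosis == "case"
  } else {
    grp_all <- as.character(tab$group)
    is_case <- grp_all != "control"
  }
  fam <- list()
  for (ct in colnames(m)) {
    v <- m[, ct]
    kw_all <- kruskal_wallis(v, grp_all)
    mwu <- mann_whitney(v[is_case], v[!is_case])
    rows <- data.frame(
      cell_type = ct,
      test = c("kw_all", "mwu_case_control"),
      statistic = c(kw_all$statistic, mwu$statistic),
      p = c(kw_all$p, mwu$p),
      direction = c(NA, mwu$direction),
      stringsAsFactors = FALSE
    )
    if (length(unique(grp_all[is_case])) >= 2) {
      kw_sub <- kruskal_wallis(v[is_case], grp_all[is_case])
      rows <- rbind(rows, data.frame(cell_type = ct, test = "kw_subgroups",
                                     statistic = kw_sub$statistic,
                                     p = kw_sub$p, direction = NA))
    }
    fam[[ct]] <- rows
  }
  res <- do.call(rbind, fam)
  res$q <- NA_real_
  for (tst in unique(res$test)) {
    sel <- res$test == tst
    res$q[sel] <- adjust_bh(res$p[sel])
  }
  rownames(res) <- NULL
  res
}
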