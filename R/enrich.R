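#' Fisher's exact enrichment of a gene list in a gene set
#'
#' Builds the 2x2 table over `background` (a = in list and set, b = in
#' list only, c = in set only, d = neither) and computes the classic
#' two-sided Fisher p by summing hypergeometric probabilities no larger
#' than the observed table's. The reported odds ratio is the sample OR
#' `(a d) / (b c)` with conventions: `b c = 0` and `a d > 0` gives `Inf`;
#' `a d = 0` gives 0.
#'
#' @param gene_list Character vector (subset of `background`).
#' @param gene_set Character vector; intersected with `background` first.
#' @param background Character vector of all eligible genes.
#' @return One-row data.frame: `a`, `b`, `c`, `d`, `odds_ratio`, `p`,
#'   `n_hits`.
#' @export
fisher_enrichment <- function(gene_list, gene_set, background) {
  if (!length(background)) stop("empty background")
  background <- unique(background)
  gene_list <- intersect(unique(gene_list), background)
  gene_set <- intersect(unique(gene_set), background)
  a <- length(intersect(gene_list, gene_set))
  b <- length(gene_list) - a
  c_ <- length(gene_set) - a
  d <- length(background) - a - b - c_
  p <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
  or <- if (a * d == 0) {
    0
  } else if (b * c_ == 0) {
    Inf
  } else {
    (a * d) / (b * c_)
  }
  data.frame(a = a, b = b, c = c_, d = d, odds_ratio = or, p = p,
             n_hits = a, stringsAsFactors = FALSE)
}

#' Enrichment of gene lists against a gene-set collection
#'
#' One Fisher test per (list, set) pair. Sets whose overlap with a list is
#' below `min_hits` (default: excluding terms with <= 3 hits) are removed
#' before BH adjustment, which is applied within each gene list across the
#' surviving sets.
#'
#' @param gene_lists Named list of character vectors (e.g. module gene
#'   sets or DE gene lists).
#' @param collection Named list of gene sets (e.g. from
#'   [read_gene_sets()]).
#' @param background Character vector of all eligible genes.
#' @param min_hits Minimum overlap to keep a (list, set) test (default 4).
#' @return Data.frame: `gene_list`, `gene_set`, `a`..`d`, `odds_ratio`,
#'   `p`, `q`, `n_hits`. Empty (with a warning) if nothing survives.
#' @export
enrich_collection <- function(gene_lists, collection, background,
                              min_hits = 4) {
  rows <- list()
  for (ln in names(gene_lists)) {
    for (sn in names(collection)) {
      r <- fisher_enrichment(gene_lists[[ln]], collection[[sn]], background)
      if (r$n_hits < min_hits) next
      r$gene_list <- ln
      r$gene_set <- sn
      rows[[paste(ln, sn)]] <- r
    }
  }
  if (!length(rows)) {
    warning("no (list, set) pair reaches min_hits = ", min_hits)
    return(data.frame(gene_list = character(), gene_set = character(),
                      a = integer(), b = integer(), c = integer(),
                      d = integer(), odds_ratio = numeric(), p = numeric(),
                      q = numeric(), n_hits = integer()))
  }
  res <- do.call(rbind, rows)
  res$q <- NA_real_
  for (ln in unique(res$gene_list)) {
    sel <- res$gene_list == ln
    res$q[sel] <- adjust_bh(res$p[sel])
  }
  rownames(res) <- NULL
  res[, c("gene_list", "gene_set", "a", "b", "c", "d", "odds_ratio",
          "p", "q", "n_hits")]
}

#' Overlap of module genes with GWAS-prioritized genes
#'
#' Same machinery as [fisher_enrichment()], reported per module against a
#' single prioritized gene list (e.g. fine-mapped risk genes).
#'
#' @param module_genes Named list: module -> character vector of genes.
#' @param prioritized_genes Character vector of prioritized gene ids.
#' @param background Character vector of all eligible genes.
#' @return Data.frame, one row per module, with BH `q` across modules.
#' @export
gwas_overlap <- function(module_genes, prioritized_genes, background) {
  if (!length(prioritized_genes)) stop("empty prioritized gene list")
  rows <- lapply(names(module_genes), function(m) {
    r <- fisher_enrichment(module_genes[[m]], prioritized_genes, background)
    r$module <- m
    r
  })
  res <- do.call(rbind, rows)
  res$q <- adjust_bh(res$p)
  res[, c("module", "a", "b", "c", "d", "odds_ratio", "p", "q", "n_hits")]
}
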