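#' Default simulation configuration
#'
#' Builds the configuration list consumed by the cohort generators. The
#' defaults emulate a toxicology-stratified postmortem case-control study:
#' 113 controls and schizophrenia cases split by postmortem toxicology into
#' APD-negative (23), atypical-positive (28), typical-positive (27) and
#' mixed (10) subgroups, with the planted disease effect scaled per subgroup
#' (atypical 1.5 > mixed 1.2 > negative 1.0 > typical 0.8). The paired
#' drug-treatment dataset defaults to placebo/clozapine/low-dose and
#' high-dose haloperidol groups of 7/9/10/7 animals.
#'
#' @param n_genes Number of genes.
#' @param group_sizes Named integer vector of samples per group; names are
#'   `control` plus the toxicology subgroups.
#' @param n_de_genes Number of genes carrying a planted diagnosis effect.
#' @param base_lfc Planted case-control log2 fold change on DE genes.
#' @param subgroup_multipliers Named multipliers applied to `base_lfc` per
#'   case subgroup.
#' @param nb_dispersion Negative-binomial dispersion (1/size).
#' @param library_size_range Range of per-sample library sizes; sizes are
#'   drawn log-uniformly.
#' @param covariate_effect_sizes Named SDs (log2 units per SD of covariate)
#'   of per-gene covariate coefficients.
#' @param n_modules Number of planted co-expression modules.
#' @param module_size_range Range of module sizes (genes).
#' @param module_condition_effects For [simulate_bulk_cohort()], a numeric
#'   vector (length `n_modules`) of latent-factor mean shifts in cases; for
#'   [simulate_paired_species()], a two-column matrix (`effect_a`,
#'   `effect_b`) of signed shifts per dataset so convergent (same sign) and
#'   divergent (opposite sign) modules can be planted.
#' @param module_cor Target within-module correlation strength in (0, 1).
#' @param n_outliers Number of planted outlier samples (large displacement
#'   on two latent directions).
#' @param outlier_sd Size of the planted outlier displacement, in units of
#'   the latent factor SD.
#' @param treatment_group_sizes Named sizes for the drug-treatment dataset.
#' @param celltypes Cell-type labels for the deconvolution reference.
#' @param base_proportions Mean cell-type proportions (simplex) of controls.
#' @param case_proportion_shift Additive shift of case proportions
#'   (re-normalized to the simplex).
#' @param cells_per_type Cells per type in the single-nucleus reference.
#' @param n_marker_genes Type-exclusive marker genes per cell type.
#' @param deconv_group_sizes Bulk samples per group for the mixing study.
#' @param proportion_noise_sd SD of per-sample logit-scale jitter around the
#'   group mean proportions.
#' @param seed Default seed recorded in the config.
#' @return A named list; entries can be overridden via `...`-style
#'   modification before passing to the generators.
#' @export
sim_config <- function(n_genes = 2000,
                       group_sizes = c(control = 113, neg = 23, atypical = 28,
                                       typical = 27, mixed = 10),
                       n_de_genes = 200,
                       base_lfc = 1,
                       subgroup_multipliers = c(neg = 1.0, atypical = 1.5,
                                                typical = 0.8, mixed = 1.2),
                       nb_dispersion = 0.15,
                       library_size_range = c(10e6, 30e6),
                       covariate_effect_sizes = c(sex = 0.1, age = 0.1,
                                                  rin = 0.15, pmi = 0.05,
                                                  ph = 0.05, batch = 0.15),
                       n_modules = 0,
                       module_size_range = c(40, 60),
                       module_condition_effects = NULL,
                       module_cor = 0.6,
                       n_outliers = 0,
                       outlier_sd = 10,
                       treatment_group_sizes = c(placebo = 7, CLZ = 9,
                                                 HAL.lo = 10, HAL.hi = 7),
                       celltypes = c("ExN", "InN", "Astro"),
                       base_proportions = c(ExN = 0.55, InN = 0.20, Astro = 0.25),
                       case_proportion_shift = c(ExN = 0.05, InN = -0.05, Astro = 0),
                       cells_per_type = 50,
                       n_marker_genes = 25,
                       deconv_group_sizes = c(control = 40, case = 40),
                       proportion_noise_sd = 0.15,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (any(cfg$group_sizes < 2)) stop("all group sizes must be >= 2")
  if (cfg$n_de_genes > cfg$n_genes) stop("n_de_genes exceeds n_genes")
  if (any(cfg$subgroup_multipliers <= 0)) stop("subgroup multipliers must be > 0")
  if (abs(sum(cfg$base_proportions) - 1) > 1e-8 || any(cfg$base_proportions < 0)) {
    stop("base_proportions must lie on the unit simplex")
  }
  cfg
}

# Derived sub-seed: keeps each sub-generator on its own reproducible stream
# while staying inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 9973) %% 2147483647L)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

# Sample-level metadata for the case-control cohort, with covariate
# distributions loosely matching a postmortem brain bank.
simulate_sample_table <- function(config, seed) {
  set.seed(derive_seed(seed, 1L))
  groups <- rep(names(config$group_sizes), config$group_sizes)
  n <- length(groups)
  data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    diagnosis = ifelse(groups == "control", "control", "case"),
    tox_group = ifelse(groups == "control", "none", groups),
    sex = sample(c("F", "M"), n, replace = TRUE),
    age = round(rtrunc_norm(n, 48, 14, 18, 90), 1),
    rin = round(rtrunc_norm(n, 7.4, 0.9, 4, 10), 1),
    pmi = round(rtrunc_norm(n, 35, 15, 5, 90), 1),
    ph = round(rtrunc_norm(n, 6.4, 0.25, 5.8, 7.0), 2),
    batch = sample(paste0("B", 1:3), n, replace = TRUE),
    effective_mapping_rate = round(stats::rbeta(n, 90, 10), 4),
    intergenic_rate = round(stats::rbeta(n, 5, 45), 4),
    stringsAsFactors = FALSE
  )
}

# Planted module structure: disjoint gene blocks sharing a latent factor
# whose mean differs between condition groups. Returns per-gene labels and
# loadings plus the per-sample latent factors (n_modules x n_samples).
simulate_module_structure <- function(config, group_of_sample, effects, seed) {
  n_genes <- config$n_genes
  n_modules <- config$n_modules
  set.seed(derive_seed(seed, 2L))
  size_seq <- seq(config$module_size_range[1], config$module_size_range[2])
  sizes <- size_seq[sample.int(length(size_seq), n_modules, replace = TRUE)]
  if (sum(sizes) > n_genes) stop("module sizes exceed n_genes")
  labels <- rep("none", n_genes)
  idx <- sample.int(n_genes, sum(sizes))
  start <- 1L
  for (m in seq_len(n_modules)) {
    labels[idx[start:(start + sizes[m] - 1L)]] <- paste0("P", m)
    start <- start + sizes[m]
  }
  n_samples <- length(group_of_sample)
  factors <- matrix(0, n_modules, n_samples)
  for (m in seq_len(n_modules)) {
    shift <- effects[[m]][group_of_sample]
    shift[is.na(shift)] <- 0
    factors[m, ] <- stats::rnorm(n_samples) + shift
  }
  # loading magnitude sets within-module correlation ~ l^2/(l^2 + noise)
  loadings <- stats::runif(n_genes, 0.9, 1.1) *
    sqrt(config$module_cor / (1 - config$module_cor))
  loadings[labels == "none"] <- 0
  list(labels = labels, loadings = loadings, factors = factors, sizes = sizes)
}

# Core count generator shared by the bulk and paired-species simulators.
# log2 mean model: baseline + covariates + planted lfc + module factor,
# scaled by library size; counts ~ NB(mu, 1/dispersion).
generate_counts <- function(config, meta, group_of_sample, gene_prefix,
                            module_struct, lfc_by_sample, seed,
                            covariate_cols) {
  n_genes <- config$n_genes
  n <- nrow(meta)
  set.seed(derive_seed(seed, 3L))
  base_log2_cpm <- stats::rnorm(n_genes, 4, 1.8)
  lib <- exp(stats::runif(n, log(config$library_size_range[1]),
                          log(config$library_size_range[2])))
  lib <- round(lib)

  log2mu <- matrix(base_log2_cpm, n_genes, n)
  es <- config$covariate_effect_sizes
  for (cv in covariate_cols) {
    if (!cv %in% names(meta)) next
    x <- meta[[cv]]
    size <- if (cv %in% names(es)) es[[cv]] else 0
    if (size == 0) next
    if (is.numeric(x)) {
      xs <- as.numeric(scale(x))
      coef <- stats::rnorm(n_genes, 0, size)
      log2mu <- log2mu + outer(coef, xs)
    } else {
      x <- factor(x)
      for (lv in levels(x)[-1L]) {
        coef <- stats::rnorm(n_genes, 0, size)
        log2mu <- log2mu + outer(coef, as.numeric(x == lv))
      }
    }
  }
  if (!is.null(lfc_by_sample)) log2mu <- log2mu + lfc_by_sample
  if (!is.null(module_struct)) {
    for (m in seq_along(module_struct$sizes)) {
      in_m <- module_struct$labels == paste0("P", m)
      log2mu[in_m, ] <- log2mu[in_m, ] +
        outer(module_struct$loadings[in_m], module_struct$factors[m, ])
    }
  }
  # planted outliers: displaced along the first two PC directions of the
  # noise-free mean structure, so they are extreme on >= 2 empirical PCs
  # (a displacement along a single arbitrary direction would surface on
  # only one component)
  outlier_ids <- character(0)
  if (config$n_outliers > 0) {
    set.seed(derive_seed(seed, 4L))
    out_idx <- sample.int(n, config$n_outliers)
    outlier_ids <- meta$sample_id[out_idx]
    pc <- stats::prcomp(t(log2mu), center = TRUE, scale. = FALSE, rank. = 2)
    floor_sd <- 0.05 * stats::sd(log2mu)
    for (d in 1:2) {
      s_d <- max(pc$sdev[d], floor_sd)
      log2mu[, out_idx] <- log2mu[, out_idx] + config$outlier_sd * s_d *
        matrix(pc$rotation[, d], n_genes, length(out_idx))
    }
  }
  rel <- 2^log2mu
  rel <- sweep(rel, 2, colSums(rel), "/")
  mu <- sweep(rel, 2, lib, "*")
  set.seed(derive_seed(seed, 5L))
  counts <- matrix(
    stats::rnbinom(n_genes * n, mu = as.vector(mu), size = 1 / config$nb_dispersion),
    n_genes, n
  )
  rownames(counts) <- sprintf("%s%04d", gene_prefix, seq_len(n_genes))
  colnames(counts) <- meta$sample_id
  list(counts = counts, library_sizes = lib, outlier_ids = outlier_ids)
}

#' Simulate a toxicology-stratified bulk case-control cohort
#'
#' Generates negative-binomial counts with gene-wise means scaled by
#' log-uniform library sizes, log-scale covariate effects (sex, age, RIN,
#' PMI, pH, batch), a planted diagnosis effect of `base_lfc` times the
#' subgroup multiplier on the DE genes, and optional planted co-expression
#' modules and outlier samples. Deterministic given `seed`.
#'
#' @param config List from [sim_config()].
#' @param seed Integer seed; overrides `config$seed`.
#' @return A list with `counts` (genes x samples integer matrix),
#'   `sample_table` (validated metadata data.frame) and `truth` (per-gene
#'   true lfc, DE mask, module labels, module effects, outlier ids).
#' @export
simulate_bulk_cohort <- function(config = sim_config(), seed = config$seed) {
  if (config$n_de_genes > 0 && config$base_lfc == 0 &&
      !is.null(config$nonzero_lfc_required) && config$nonzero_lfc_required) {
    stop("degenerate config: DE genes requested with zero base_lfc")
  }
  meta <- simulate_sample_table(config, seed)
  groups <- ifelse(meta$diagnosis == "control", "control",
                   as.character(meta$tox_group))

  set.seed(derive_seed(seed, 6L))
  de_mask <- rep(FALSE, config$n_genes)
  true_lfc <- rep(0, config$n_genes)
  if (config$n_de_genes > 0) {
    de_idx <- sample.int(config$n_genes, config$n_de_genes)
    de_mask[de_idx] <- TRUE
    true_lfc[de_idx] <- sample(c(-1, 1), config$n_de_genes, replace = TRUE) *
      config$base_lfc
  }
  mult <- c(control = 0, config$subgroup_multipliers)
  lfc_by_sample <- outer(true_lfc, mult[groups])

  module_struct <- NULL
  if (config$n_modules > 0) {
    eff <- config$module_condition_effects
    if (is.null(eff)) eff <- rep(0, config$n_modules)
    eff_list <- lapply(seq_len(config$n_modules), function(m) {
      e <- c(control = 0, stats::setNames(rep(eff[m], length(config$subgroup_multipliers)),
                                          names(config$subgroup_multipliers)))
      e
    })
    module_struct <- simulate_module_structure(config, groups, eff_list, seed)
  }

  gen <- generate_counts(config, meta, groups, "gA", module_struct,
                         lfc_by_sample, seed,
                         c("sex", "age", "rin", "pmi", "ph", "batch"))
  truth <- list(
    true_lfc = stats::setNames(true_lfc, rownames(gen$counts)),
    de_mask = stats::setNames(de_mask, rownames(gen$counts)),
    module_labels = if (is.null(module_struct)) NULL else
      stats::setNames(module_struct$labels, rownames(gen$counts)),
    module_effects = config$module_condition_effects,
    library_sizes = gen$library_sizes,
    outlier_ids = gen$outlier_ids
  )
  list(counts = validate_counts(gen$counts),
       sample_table = validate_metadata(meta),
       truth = truth)
}

#' Simulate a paired two-species design with shared module structure
#'
#' Dataset A is the case-control cohort of [simulate_bulk_cohort()];
#' dataset B is a drug-treatment cohort (default groups
#' placebo/CLZ/HAL.lo/HAL.hi of 7/9/10/7) sharing the planted module
#' structure on ortholog-matched genes. Per-module condition effects are
#' signed separately per dataset (`module_condition_effects` two-column
#' matrix), so convergent (same sign) and divergent (opposite sign) modules
#' can be planted.
#'
#' @param config List from [sim_config()]; `n_modules` must be >= 1 and
#'   `module_condition_effects` a matrix with columns `effect_a`,
#'   `effect_b`.
#' @param seed Integer seed.
#' @return List with `a` and `b` (each `counts` + `sample_table`),
#'   `orthology` (data.frame gene_a/gene_b), and `truth` (module labels on
#'   both gene universes, per-module effect signs per dataset).
#' @export
simulate_paired_species <- function(config = sim_config(n_genes = 600,
                                                        n_modules = 5),
                                    seed = config$seed) {
  if (config$n_modules < 1) stop("paired-species simulation needs n_modules >= 1")
  eff <- config$module_condition_effects
  if (is.null(eff)) {
    eff <- cbind(effect_a = rep(1, config$n_modules),
                 effect_b = rep(1, config$n_modules))
  }
  eff <- as.matrix(eff)
  if (nrow(eff) != config$n_modules || ncol(eff) != 2) {
    stop("module_condition_effects must be n_modules x 2 (effect_a, effect_b)")
  }

  # dataset A: case-control cohort
  meta_a <- simulate_sample_table(config, seed)
  groups_a <- ifelse(meta_a$diagnosis == "control", "control",
                     as.character(meta_a$tox_group))
  eff_list_a <- lapply(seq_len(config$n_modules), function(m) {
    c(control = 0,
      stats::setNames(rep(eff[m, 1], length(config$subgroup_multipliers)),
                      names(config$subgroup_multipliers)))
  })
  module_struct_a <- simulate_module_structure(config, groups_a, eff_list_a, seed)

  set.seed(derive_seed(seed, 6L))
  de_mask <- rep(FALSE, config$n_genes)
  true_lfc <- rep(0, config$n_genes)
  if (config$n_de_genes > 0) {
    de_idx <- sample.int(config$n_genes, min(config$n_de_genes, config$n_genes))
    de_mask[de_idx] <- TRUE
    true_lfc[de_idx] <- sample(c(-1, 1), length(de_idx), replace = TRUE) *
      config$base_lfc
  }
  mult <- c(control = 0, config$subgroup_multipliers)
  lfc_by_sample_a <- outer(true_lfc, mult[groups_a])

  gen_a <- generate_counts(config, meta_a, groups_a, "gA", module_struct_a,
                           lfc_by_sample_a, seed,
                           c("sex", "age", "rin", "pmi", "ph", "batch"))

  # dataset B: treatment cohort, same module gene blocks (ortholog-matched
  # by position), treatment effect applied to all non-placebo groups
  set.seed(derive_seed(seed, 7L))
  groups_b <- rep(names(config$treatment_group_sizes),
                  config$treatment_group_sizes)
  nb <- length(groups_b)
  meta_b <- data.frame(
    sample_id = sprintf("M%02d", seq_len(nb)),
    treatment = factor(groups_b, levels = names(config$treatment_group_sizes)),
    sex = sample(c("F", "M"), nb, replace = TRUE),
    age = round(rtrunc_norm(nb, 6.3, 1.3, 4, 10), 1),
    rin = round(rtrunc_norm(nb, 7.3, 0.6, 5, 10), 1),
    batch = sample(paste0("RB", 1:2), nb, replace = TRUE),
    effective_mapping_rate = round(stats::rbeta(nb, 90, 10), 4),
    intergenic_rate = round(stats::rbeta(nb, 5, 45), 4),
    stringsAsFactors = FALSE
  )
  eff_list_b <- lapply(seq_len(config$n_modules), function(m) {
    e <- stats::setNames(rep(eff[m, 2], length(config$treatment_group_sizes)),
                         names(config$treatment_group_sizes))
    e["placebo"] <- 0
    e
  })
  cfg_b <- config
  cfg_b$n_outliers <- 0
  module_struct_b <- simulate_module_structure(cfg_b, groups_b, eff_list_b,
                                               derive_seed(seed, 8L))
  # same gene blocks as A so orthologs share module membership
  module_struct_b$labels <- module_struct_a$labels
  module_struct_b$loadings <- module_struct_a$loadings
  module_struct_b$sizes <- module_struct_a$sizes

  gen_b <- generate_counts(cfg_b, meta_b, groups_b, "gB", module_struct_b,
                           NULL, derive_seed(seed, 9L),
                           c("sex", "age", "rin", "batch"))

  orthology <- data.frame(gene_a = rownames(gen_a$counts),
                          gene_b = rownames(gen_b$counts),
                          stringsAsFactors = FALSE)
  truth <- list(
    module_labels_a = stats::setNames(module_struct_a$labels, rownames(gen_a$counts)),
    module_labels_b = stats::setNames(module_struct_b$labels, rownames(gen_b$counts)),
    module_effects = eff,
    true_lfc = stats::setNames(true_lfc, rownames(gen_a$counts)),
    de_mask = stats::setNames(de_mask, rownames(gen_a$counts)),
    outlier_ids = gen_a$outlier_ids
  )
  list(
    a = list(counts = validate_counts(gen_a$counts),
             sample_table = validate_metadata(meta_a)),
    b = list(counts = validate_counts(gen_b$counts),
             sample_table = meta_b),
    orthology = orthology,
    truth = truth
  )
}

#' Simulate a single-nucleus reference and mixed bulk samples
#'
#' Per-type mean profiles share a common baseline with type-exclusive
#' marker genes (strong expression in one type only). Reference cells and
#' bulk samples are NB draws; each bulk sample's mean is a convex
#' combination of the type CPM profiles with known weights. With
#' `noise = FALSE` the bulk matrix is the exact weighted sum (no sampling),
#' supporting exact-recovery checks.
#'
#' @param config List from [sim_config()].
#' @param seed Integer seed.
#' @param noise If `FALSE`, bulk columns are exact convex mixtures of the
#'   type profiles (scaled to library size) instead of NB draws.
#' @return List with `reference` (list: `counts` cells x genes,
#'   `cell_type` labels), `bulk` (genes x samples matrix), `sample_table`
#'   (sample_id + group) and `truth` (samples x types true proportions).
#' @export
simulate_reference <- function(config = sim_config(n_genes = 500),
                               seed = config$seed, noise = TRUE) {
  types <- config$celltypes
  k <- length(types)
  if (k < 2) stop("need >= 2 cell types")
  if (config$cells_per_type < 20) stop("need >= 20 cells per type")
  n_genes <- config$n_genes
  set.seed(derive_seed(seed, 11L))

  base <- 2^stats::rnorm(n_genes, 3, 1.2)
  profiles <- matrix(rep(base, k), n_genes, k)
  marker_idx <- sample.int(n_genes, k * config$n_marker_genes)
  for (j in seq_len(k)) {
    mk <- marker_idx[((j - 1) * config$n_marker_genes + 1):(j * config$n_marker_genes)]
    profiles[mk, ] <- profiles[mk, ] * 0.05
    profiles[mk, j] <- base[mk] * 30
  }
  profiles <- sweep(profiles, 2, colSums(profiles), "/") * 1e6  # CPM scale
  gene_ids <- sprintf("gA%04d", seq_len(n_genes))
  rownames(profiles) <- gene_ids
  colnames(profiles) <- types

  # reference cells: NB around each type profile at modest depth
  n_cells <- k * config$cells_per_type
  cell_type <- rep(types, each = config$cells_per_type)
  cell_depth <- 20000
  ref_counts <- matrix(0L, n_cells, n_genes,
                       dimnames = list(sprintf("C%04d", seq_len(n_cells)), gene_ids))
  set.seed(derive_seed(seed, 12L))
  for (i in seq_len(n_cells)) {
    mu <- profiles[, cell_type[i]] / 1e6 * cell_depth
    ref_counts[i, ] <- stats::rnbinom(n_genes, mu = mu, size = 1 / 0.3)
  }

  # bulk mixtures: group-mean proportions with logit-scale jitter
  gsz <- config$deconv_group_sizes
  group <- rep(names(gsz), gsz)
  n_bulk <- length(group)
  props <- matrix(0, n_bulk, k, dimnames = list(sprintf("BK%03d", seq_len(n_bulk)), types))
  set.seed(derive_seed(seed, 13L))
  for (i in seq_len(n_bulk)) {
    mean_p <- config$base_proportions
    if (group[i] == "case") {
      mean_p <- mean_p + config$case_proportion_shift[types]
      mean_p <- pmax(mean_p, 1e-3)
      mean_p <- mean_p / sum(mean_p)
    }
    z <- log(mean_p) + stats::rnorm(k, 0, config$proportion_noise_sd)
    p <- exp(z) / sum(exp(z))
    props[i, ] <- p
  }
  lib <- round(exp(stats::runif(n_bulk, log(config$library_size_range[1]),
                                log(config$library_size_range[2]))))
  mix_cpm <- profiles %*% t(props)           # genes x samples, CPM scale
  mu_bulk <- sweep(mix_cpm / 1e6, 2, lib, "*")
  set.seed(derive_seed(seed, 14L))
  if (noise) {
    bulk <- matrix(stats::rnbinom(length(mu_bulk), mu = as.vector(mu_bulk),
                                  size = 1 / 0.05),
                   n_genes, n_bulk)
  } else {
    bulk <- mu_bulk
  }
  dimnames(bulk) <- list(gene_ids, rownames(props))
  list(
    reference = list(counts = ref_counts, cell_type = cell_type),
    profiles = profiles,
    bulk = bulk,
    sample_table = data.frame(sample_id = rownames(props), group = group,
                              stringsAsFactors = FALSE),
    truth = props
  )
}
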