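#' Default pipeline configuration
#'
#' Parameter blocks for every stage of the full analysis graph, with the
#' synthetic paired-cohort bundle as the default input. Stages communicate
#' only via files under `out_dir`, so a run can be resumed at any stage.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed governing all randomness.
#' @param mode `"fixed"` (predetermined covariate designs) or
#'   `"data-driven"` (sequential covariate selection).
#' @param loo_scores Use leave-one-out signature scoring.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(out_dir = "sigconfound_run", seed = 1L,
                                    mode = c("fixed", "data-driven"),
                                    loo_scores = FALSE) {
  mode <- match.arg(mode)
  sim <- sim_config(n_genes = 600, n_modules = 5,
                    module_condition_effects = cbind(
                      effect_a = c(0.8, 0.8, -0.8, 0.8, -0.8),
                      effect_b = c(4, -4, -4, 4, 4)))
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    mode = mode,
    loo_scores = loo_scores,
    sim = sim,
    preprocess = list(
      cpm_threshold = 1,
      min_fraction_a = 0.5,    # human preset: CPM > 1 in >= 50% of samples
      min_samples_b = 3,       # macaque preset: CPM > 1 in >= 3 samples
      prior_count = 0.5,
      n_pcs = 20,
      outlier_sd_a = 5, outlier_sd_b = 3, outlier_min_pcs = 2
    ),
    residualize = list(
      covariates_de_a = c("batch", "sex", "age", "effective_mapping_rate",
                          "intergenic_rate", "rin", "pmi", "ph"),
      covariates_de_b = c("batch", "sex", "effective_mapping_rate",
                          "intergenic_rate", "rin"),
      covariates_net_a = c("batch", "effective_mapping_rate",
                           "intergenic_rate", "rin", "pmi", "ph"),
      covariates_net_b = c("batch", "effective_mapping_rate",
                           "intergenic_rate", "rin"),
      alpha = 0.05
    ),
    de = list(moderation = TRUE, p_threshold = 0.05),
    modules = list(beta_power = 12, min_size = 30, merge_cut = 0.25,
                   min_kme = 0.3, scale_quantile = 0.95, t_threshold = 2.0),
    enrich = list(min_hits = 4),
    deconv = list(merge_map = list(), drop_list = character())
  )
}

.pipeline_stages <- c("simulate", "preprocess", "residualize", "de",
                      "signature", "modules", "enrich", "deconvolve")

read_stage_meta <- function(dir, name) {
  validate_metadata(utils::read.table(file.path(dir, name), header = TRUE,
                                      sep = "\t", stringsAsFactors = FALSE))
}

stage_simulate <- function(cfg) {
  dir <- cfg$out_dir
  pair <- simulate_paired_species(cfg$sim, seed = cfg$seed)
  ref <- simulate_reference(cfg$sim, seed = derive_seed(cfg$seed, 21L))
  write_tsv(pair$a$counts, file.path(dir, "counts_a.tsv"), id_col = "gene")
  write_tsv(pair$b$counts, file.path(dir, "counts_b.tsv"), id_col = "gene")
  utils::write.table(pair$a$sample_table, file.path(dir, "meta_a.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pair$b$sample_table, file.path(dir, "meta_b.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pair$orthology, file.path(dir, "orthology.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  planted <- split(names(pair$truth$module_labels_a),
                   pair$truth$module_labels_a)
  planted <- planted[names(planted) != "none"]
  write_gene_sets(planted, file.path(dir, "planted_modules.gmt"))
  write_tsv(data.frame(gene = names(pair$truth$true_lfc),
                       true_lfc = pair$truth$true_lfc,
                       module = pair$truth$module_labels_a),
            file.path(dir, "truth_genes_a.tsv"))
  ref_counts <- t(ref$reference$counts)   # genes x cells for the TSV
  write_tsv(ref_counts, file.path(dir, "reference_counts.tsv"), id_col = "gene")
  utils::write.table(data.frame(cell_id = rownames(ref$reference$counts),
                                cell_type = ref$reference$cell_type),
                     file.path(dir, "reference_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_tsv(ref$bulk, file.path(dir, "bulk_mix.tsv"), id_col = "gene")
  utils::write.table(ref$sample_table, file.path(dir, "bulk_mix_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_tsv(ref$truth, file.path(dir, "truth_proportions.tsv"),
            id_col = "sample_id")
  list(n_genes_a = nrow(pair$a$counts), n_samples_a = ncol(pair$a$counts),
       n_genes_b = nrow(pair$b$counts), n_samples_b = ncol(pair$b$counts),
       n_orthologs = nrow(pair$orthology),
       n_bulk_mix = ncol(ref$bulk))
}

preprocess_one <- function(cfg, dir, tag, min_fraction = NULL,
                           min_samples = NULL, outlier_sd = 5) {
  counts <- read_counts(file.path(dir, sprintf("counts_%s.tsv", tag)))
  pp <- cfg$preprocess
  filt <- filter_genes(counts, pp$cpm_threshold, min_fraction = min_fraction,
                       min_samples = min_samples)
  fac <- tmm_factors(filt)
  ne <- log_cpm(filt, fac, prior_count = pp$prior_count)
  pca <- pca_scores(ne, n_components = min(pp$n_pcs, ncol(filt) - 1L))
  out <- detect_outliers(pca, sd_threshold = outlier_sd,
                         min_pcs = pp$outlier_min_pcs, top_k = pp$n_pcs)
  keep <- setdiff(colnames(filt), out)
  filt <- filt[, keep, drop = FALSE]
  if (length(out)) {     # refit normalization on the retained samples
    fac <- tmm_factors(filt)
    ne <- log_cpm(filt, fac, prior_count = pp$prior_count)
  }
  write_tsv(filt, file.path(dir, sprintf("filtered_counts_%s.tsv", tag)),
            id_col = "gene")
  write_tsv(data.frame(sample_id = names(fac), tmm_factor = fac),
            file.path(dir, sprintf("tmm_factors_%s.tsv", tag)))
  write_tsv(ne$logcpm, file.path(dir, sprintf("logcpm_%s.tsv", tag)),
            id_col = "gene")
  write_tsv(pca$scores, file.path(dir, sprintf("pca_scores_%s.tsv", tag)),
            id_col = "sample_id")
  write_tsv(data.frame(sample_id = if (length(out)) out else "none",
                       flagged = length(out) > 0),
            file.path(dir, sprintf("outliers_%s.tsv", tag)))
  list(genes_kept = nrow(filt), samples_kept = ncol(filt),
       outliers = length(out))
}

stage_preprocess <- function(cfg) {
  dir <- cfg$out_dir
  pp <- cfg$preprocess
  list(
    a = preprocess_one(cfg, dir, "a", min_fraction = pp$min_fraction_a,
                       outlier_sd = pp$outlier_sd_a),
    b = preprocess_one(cfg, dir, "b", min_samples = pp$min_samples_b,
                       outlier_sd = pp$outlier_sd_b)
  )
}

residualize_one <- function(cfg, dir, tag, covariates_de, covariates_net) {
  logcpm <- read_tsv_matrix(file.path(dir, sprintf("logcpm_%s.tsv", tag)),
                            id_col = "gene")
  meta <- utils::read.table(file.path(dir, sprintf("meta_%s.tsv", tag)),
                            header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  meta <- meta[match(colnames(logcpm), meta$sample_id), ]
  if (cfg$mode == "data-driven") {
    sel <- select_covariates_sequential(logcpm, meta,
                                        candidates = covariates_de,
                                        alpha = cfg$residualize$alpha)
    covariates_de <- sel$selected
    utils::write.table(sel$log, file.path(dir, sprintf("covariate_selection_%s.tsv", tag)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res_de <- residualize(logcpm, design_covariates = covariates_de,
                        sample_table = meta)
  res_net <- residualize(logcpm, design_covariates = covariates_net,
                         sample_table = meta)
  write_tsv(res_de$residuals, file.path(dir, sprintf("residuals_de_%s.tsv", tag)),
            id_col = "gene")
  write_tsv(res_net$residuals, file.path(dir, sprintf("residuals_net_%s.tsv", tag)),
            id_col = "gene")
  list(covariates_de = covariates_de, genes = nrow(res_de$residuals))
}

stage_residualize <- function(cfg) {
  dir <- cfg$out_dir
  rc <- cfg$residualize
  list(
    a = residualize_one(cfg, dir, "a", rc$covariates_de_a, rc$covariates_net_a),
    b = residualize_one(cfg, dir, "b", rc$covariates_de_b, rc$covariates_net_b)
  )
}

stage_de <- function(cfg) {
  dir <- cfg$out_dir
  res_a <- read_tsv_matrix(file.path(dir, "residuals_de_a.tsv"), id_col = "gene")
  meta_a <- read_stage_meta(dir, "meta_a.tsv")
  meta_a <- meta_a[match(colnames(res_a), meta_a$sample_id), ]
  de_a <- fit_contrast(res_a, meta_a, c("diagnosis", "control", "case"),
                       moderation = cfg$de$moderation)
  write_tsv(de_a, file.path(dir, "de_case_control_a.tsv"))
  sub <- subgroup_contrasts(res_a, meta_a, moderation = cfg$de$moderation)
  for (lv in names(sub)) {
    write_tsv(sub[[lv]], file.path(dir, sprintf("de_subgroup_%s_a.tsv", lv)))
  }
  res_b <- read_tsv_matrix(file.path(dir, "residuals_de_b.tsv"), id_col = "gene")
  meta_b <- utils::read.table(file.path(dir, "meta_b.tsv"), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
  meta_b <- meta_b[match(colnames(res_b), meta_b$sample_id), ]
  treatments <- setdiff(unique(meta_b$treatment), "placebo")
  n_sig_b <- integer(0)
  for (tr in treatments) {
    de_b <- fit_contrast(res_b, meta_b, c("treatment", "placebo", tr),
                         moderation = cfg$de$moderation)
    write_tsv(de_b, file.path(dir, sprintf("de_treatment_%s_b.tsv", tr)))
    n_sig_b[tr] <- sum(de_b$q < 0.05)
  }
  list(n_sig_a = sum(de_a$q < 0.05), n_sig_subgroups =
         vapply(sub, function(d) sum(d$q < 0.05), integer(1)),
       n_sig_b = n_sig_b)
}

stage_signature <- function(cfg) {
  dir <- cfg$out_dir
  res_a <- read_tsv_matrix(file.path(dir, "residuals_de_a.tsv"), id_col = "gene")
  meta_a <- read_stage_meta(dir, "meta_a.tsv")
  meta_a <- meta_a[match(colnames(res_a), meta_a$sample_id), ]
  de_a <- utils::read.table(file.path(dir, "de_case_control_a.tsv"),
                            header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  scores <- if (isTRUE(cfg$loo_scores)) {
    signature_scores_loo(res_a, meta_a, c("diagnosis", "control", "case"),
                         p_threshold = cfg$de$p_threshold,
                         moderation = cfg$de$moderation)
  } else {
    signature_scores(res_a, de_a, p_threshold = cfg$de$p_threshold)
  }
  write_tsv(data.frame(sample_id = names(scores$score), score = scores$score,
                       n_genes_used = scores$n_genes_used),
            file.path(dir, "signature_scores.tsv"))
  tests <- signature_group_tests(scores, meta_a)
  report <- rbind(
    data.frame(test = "shapiro", groups = "all", statistic = NA,
               p = tests$shapiro$shapiro_p, stringsAsFactors = FALSE),
    tests$kw_all[, c("test", "groups", "statistic", "p")],
    cbind(tests$kw_subgroups[, c("test", "statistic", "p")],
          groups = "case-subgroups")[, c("test", "groups", "statistic", "p")],
    data.frame(test = "mwu_case_control", groups = "case|control",
               statistic = tests$mwu_case_control$statistic,
               p = tests$mwu_case_control$p),
    data.frame(test = "dunn", groups = paste(tests$dunn$group_i,
                                             tests$dunn$group_j, sep = "|"),
               statistic = tests$dunn$z, p = tests$dunn$p)
  )
  write_tsv(report, file.path(dir, "signature_group_tests.tsv"))
  list(n_genes_used = scores$n_genes_used,
       kw_all_p = tests$kw_all$p, kw_subgroups_p = tests$kw_subgroups$p)
}

stage_modules <- function(cfg) {
  dir <- cfg$out_dir
  orth_path <- file.path(dir, "orthology.tsv")
  if (!file.exists(orth_path)) {
    message("orthology map missing: consensus-module stage skipped")
    return(list(skipped = TRUE, reason = "missing orthology"))
  }
  orth <- read_orthology(orth_path)
  res_a <- read_tsv_matrix(file.path(dir, "residuals_net_a.tsv"), id_col = "gene")
  res_b <- read_tsv_matrix(file.path(dir, "residuals_net_b.tsv"), id_col = "gene")
  mp <- cfg$modules
  cm <- consensus_modules(res_a, res_b, orth, beta_power = mp$beta_power,
                          min_size = mp$min_size, merge_cut = mp$merge_cut,
                          min_kme = mp$min_kme,
                          scale_quantile = mp$scale_quantile)
  labels <- cm$assignment$labels
  write_tsv(data.frame(gene = names(labels), module = labels),
            file.path(dir, "module_assignment.tsv"))
  if (!length(cm$assignment$sizes)) {
    return(list(n_modules = 0))
  }
  meta_a <- read_stage_meta(dir, "meta_a.tsv")
  meta_a <- meta_a[match(colnames(cm$expr_a), meta_a$sample_id), ]
  meta_b <- utils::read.table(file.path(dir, "meta_b.tsv"), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
  meta_b <- meta_b[match(colnames(cm$expr_b), meta_b$sample_id), ]
  meta_b$treatment <- factor(meta_b$treatment,
                             levels = c("placebo",
                                        setdiff(unique(meta_b$treatment),
                                                "placebo")))
  eg_a <- module_eigengenes(cm$expr_a, cm$assignment)
  eg_b <- module_eigengenes(cm$expr_b, cm$assignment)
  write_tsv(eg_a$eigengenes, file.path(dir, "eigengenes_a.tsv"), id_col = "module")
  write_tsv(eg_b$eigengenes, file.path(dir, "eigengenes_b.tsv"), id_col = "module")
  assoc_a <- eigengene_association(eg_a, meta_a, "diagnosis")
  assoc_b <- eigengene_association(eg_b, meta_b, "treatment")
  write_tsv(assoc_a, file.path(dir, "eigengene_assoc_a.tsv"))
  write_tsv(assoc_b, file.path(dir, "eigengene_assoc_b.tsv"))
  conv <- classify_convergence(assoc_a, assoc_b, t_threshold = mp$t_threshold)
  write_tsv(conv, file.path(dir, "convergence.tsv"))
  list(n_modules = length(cm$assignment$sizes),
       module_sizes = cm$assignment$sizes,
       n_convergent = sum(conv$classification == "convergent"),
       n_divergent = sum(conv$classification == "divergent"))
}

stage_enrich <- function(cfg) {
  dir <- cfg$out_dir
  assign_path <- file.path(dir, "module_assignment.tsv")
  if (!file.exists(assign_path)) {
    message("module assignment missing: enrichment stage skipped")
    return(list(skipped = TRUE))
  }
  assign_tab <- utils::read.table(assign_path, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
  collection <- read_gene_sets(file.path(dir, "planted_modules.gmt"))
  background <- assign_tab$gene
  module_lists <- split(assign_tab$gene, assign_tab$module)
  module_lists <- module_lists[names(module_lists) != "unassigned"]
  if (!length(module_lists)) return(list(n_tests = 0))
  res <- enrich_collection(module_lists, collection, background,
                           min_hits = cfg$enrich$min_hits)
  write_tsv(res, file.path(dir, "module_enrichment.tsv"))
  list(n_tests = nrow(res), n_sig = sum(res$q < 0.05))
}

stage_deconvolve <- function(cfg) {
  dir <- cfg$out_dir
  ref_counts <- read_tsv_matrix(file.path(dir, "reference_counts.tsv"),
                                id_col = "gene")
  labels <- utils::read.table(file.path(dir, "reference_labels.tsv"),
                              header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  bulk <- read_tsv_matrix(file.path(dir, "bulk_mix.tsv"), id_col = "gene")
  meta <- utils::read.table(file.path(dir, "bulk_mix_meta.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  profiles <- build_reference_profiles(
    list(counts = t(ref_counts), cell_type = labels$cell_type),
    merge_map = cfg$deconv$merge_map, drop_list = cfg$deconv$drop_list)
  est <- estimate_proportions(bulk, profiles)
  write_tsv(est$proportions, file.path(dir, "proportions.tsv"),
            id_col = "sample_id")
  tests <- compare_proportions(est, meta)
  write_tsv(tests, file.path(dir, "proportion_tests.tsv"))
  list(n_types = ncol(est$proportions),
       mwu_p = stats::setNames(tests$p[tests$test == "mwu_case_control"],
                               tests$cell_type[tests$test == "mwu_case_control"]))
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> preprocess -> residualize -> DE -> signature ->
#' consensus modules -> enrichment -> deconvolution, writing every
#' intermediate as TSV under `config$out_dir` and a JSON run manifest
#' recording the config, seed, per-stage dimensions, and MD5 digests of
#' all outputs. Outputs are pure functions of (config, seed): a rerun
#' yields a byte-identical manifest.
#'
#' @param config List from [default_pipeline_config()].
#' @param from Optional stage name to resume from (earlier outputs must
#'   exist in `out_dir`).
#' @return The manifest list (invisibly written to `manifest.json`).
#' @export
run_all <- function(config = default_pipeline_config(), from = NULL) {
  dir <- config$out_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stages <- .pipeline_stages
  if (!is.null(from)) {
    if (!from %in% stages) stop("unknown stage: ", from)
    stages <- stages[seq(match(from, stages), length(stages))]
  }
  records <- list()
  for (st in stages) {
    fn <- switch(st,
                 simulate = stage_simulate,
                 preprocess = stage_preprocess,
                 residualize = stage_residualize,
                 de = stage_de,
                 signature = stage_signature,
                 modules = stage_modules,
                 enrich = stage_enrich,
                 deconvolve = stage_deconvolve)
    records[[st]] <- tryCatch(fn(config), error = function(e) {
      stop("pipeline stage '", st, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  outputs <- sort(setdiff(list.files(dir, full.names = TRUE),
                          file.path(dir, "manifest.json")))
  manifest <- build_manifest(config, config$seed, inputs = outputs,
                             stages = records)
  names(manifest$input_digests) <- basename(names(manifest$input_digests))
  write_manifest(manifest, file.path(dir, "manifest.json"))
  invisible(manifest)
}
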