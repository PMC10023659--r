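# Shared runners for the simulation-based checks: full scoring path on the
# default cohort, and the paired-species module-recovery path.

run_signature_cohort <- function(seed, cfg = sim_config()) {
  sim <- simulate_bulk_cohort(cfg, seed = seed)
  f <- filter_genes(sim$counts, min_fraction = 0.5)
  ne <- log_cpm(f, tmm_factors(f))
  res <- residualize(ne$logcpm,
                     design_covariates = c("batch", "sex", "age", "rin",
                                           "pmi", "ph"),
                     sample_table = sim$sample_table)
  de <- fit_contrast(res, sim$sample_table, c("diagnosis", "control", "case"))
  sc <- signature_scores(res, de)
  grp <- ifelse(sim$sample_table$diagnosis == "control", "control",
                as.character(sim$sample_table$tox_group))
  list(sim = sim, de = de, scores = sc, group = grp,
       tests = signature_group_tests(sc, sim$sample_table))
}

# Low-noise paired-cohort condition for module recovery: 5 planted 50-gene
# modules, nuisance covariate effects off, treatment effects sized for
# clearly significant eigengene associations.
module_recovery_config <- function() {
  sim_config(n_genes = 600, n_modules = 5, module_size_range = c(50, 50),
             covariate_effect_sizes = c(sex = 0, age = 0, rin = 0, pmi = 0,
                                        ph = 0, batch = 0),
             module_condition_effects = cbind(
               effect_a = c(0.8, 0.8, -0.8, 0.8, -0.8),
               effect_b = c(4, -4, -4, 4, 4)))
}

run_module_recovery <- function(seed, cfg = module_recovery_config()) {
  pair <- simulate_paired_species(cfg, seed = seed)
  fa <- filter_genes(pair$a$counts, min_fraction = 0.5)
  res_a <- residualize(log_cpm(fa, tmm_factors(fa))$logcpm,
                       design_covariates = c("batch", "rin"),
                       sample_table = pair$a$sample_table)$residuals
  fb <- filter_genes(pair$b$counts, min_samples = 3)
  res_b <- residualize(log_cpm(fb, tmm_factors(fb))$logcpm,
                       design_covariates = c("batch", "rin"),
                       sample_table = pair$b$sample_table)$residuals
  cm <- consensus_modules(res_a, res_b, pair$orthology)
  lab <- cm$assignment$labels
  truth <- pair$truth$module_labels_a[names(lab)]

  meta_a <- pair$a$sample_table[match(colnames(cm$expr_a),
                                      pair$a$sample_table$sample_id), ]
  meta_b <- pair$b$sample_table[match(colnames(cm$expr_b),
                                      pair$b$sample_table$sample_id), ]
  meta_b$treatment <- factor(meta_b$treatment,
                             levels = c("placebo", "CLZ", "HAL.lo", "HAL.hi"))
  assoc_a <- eigengene_association(module_eigengenes(cm$expr_a, cm$assignment),
                                   meta_a, "diagnosis")
  assoc_b <- eigengene_association(module_eigengenes(cm$expr_b, cm$assignment),
                                   meta_b, "treatment")
  conv <- classify_convergence(assoc_a, assoc_b)

  correct <- 0; total <- 0
  for (m in unique(conv$module)) {
    planted <- names(sort(table(truth[lab == m]), decreasing = TRUE))[1]
    if (planted == "none") next
    k <- as.integer(sub("P", "", planted))
    eff <- cfg$module_condition_effects[k, ]
    expected <- if (sign(eff[1]) == sign(eff[2])) "convergent" else "divergent"
    got <- conv$classification[conv$module == m]
    total <- total + length(got)
    correct <- correct + sum(got == expected)
  }
  list(labels = lab, truth = truth,
       n_modules = length(cm$assignment$sizes),
       classification_accuracy = if (total) correct / total else NA_real_,
       convergence = conv)
}
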