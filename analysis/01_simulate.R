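#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study.
#
# Blood counts: four genotypes (WT0, CM1, CP2, TH3), 15 animals each over
# five experiments, lognormal noise (batch sd 0.1, residual sd 0.2 on the
# natural-log scale).  The planted interaction terms use the published
# point estimates for each cell type as ground truth, so stage 2 has a
# known target to recover.  Expression: two genotypes x two treatments,
# 4 replicates, 5000 genes with 10% activated / 10% repressed and half of
# each KIX-sensitive.

library(hematrio)

out <- "scratch/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20261001L

baselines <- c(platelets = log(1000),   # K/uL
               b_cells = log(2.0),      # K/uL
               cd4_t = log(1.2),        # K/uL
               cd8_t = log(0.8),        # K/uL
               hematocrit = log(45),    # %
               neutrophils = log(1.5),  # K/uL
               monocytes = log(0.3))    # K/uL
planted_E <- c(platelets = 0.41, b_cells = -1.35, cd4_t = -1.08,
               cd8_t = -1.13, hematocrit = -0.11, neutrophils = 0,
               monocytes = 0.16)

blood <- simulate_blood_counts(blood_sim_config(
  n_per_group = 15, n_experiments = 5,
  baseline_log_mean = baselines,
  delta_cm1 = -0.05, delta_cp2 = -0.05,
  true_E = planted_E,
  batch_sd = 0.1, residual_sd = 0.2, seed = seed))
write_counts_csv(blood, file.path(out, "blood_counts.csv"))
utils::write.table(
  data.frame(phenotype = names(planted_E), true_E = planted_E),
  file.path(out, "planted_interactions.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)

expr <- simulate_expression(expr_sim_config(
  n_genes = 5000, n_replicates = 4,
  frac_activated = 0.1, frac_repressed = 0.1,
  activation_log2fc = 2, repression_log2fc = -2,
  frac_kix_sensitive = 0.5, noise_sd = 0.3, seed = seed + 1L))
write_gct(expr, file.path(out, "expression.gct"))
write_sample_annotation(expr, file.path(out, "samples.tsv"))
utils::write.table(expr$truth, file.path(out, "expression_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("wrote %d animals x %d phenotypes and %d genes x %d arrays under %s\n",
            nrow(blood), length(baselines), nrow(expr$values),
            ncol(expr$values), out))
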