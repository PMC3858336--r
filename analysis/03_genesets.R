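#!/usr/bin/env Rscript
# Stage 3: c-Myb response gene sets and their KIX sensitivity.
#
# Replicate-averaged log2 signals; presence filter at 3.4 in both WT
# conditions; activated = induced at least twofold by c-Myb treatment,
# repressed = reduced at least 50%; KIX-sensitive = response blunted at
# least 1.5-fold in the KIX mutant.  Recovery is scored against the
# simulator's planted truth, and a direction-concordance comparison
# against the truth labels stands in for the cross-dataset ChIP overlap.

library(hematrio)

vals <- read_gct("scratch/data/expression.gct")
samples <- utils::read.delim("scratch/data/samples.tsv",
                             colClasses = c(replicate = "integer"))
truth <- utils::read.delim("scratch/data/expression_truth.tsv")
expr <- expr_matrix(vals, samples, truth)

params <- filter_params()  # floor 3.4, 2-fold, 50%, 1.5-fold
means <- average_replicates(expr)
present <- presence_filter(means, c("WT.ctrl", "WT.myb"),
                           params$presence_floor)
sets <- classify_myb_response(means, "WT.ctrl", "WT.myb", params,
                              genes = present)
gsr <- kix_sensitivity(sets, means, "WT.myb", "KIX.myb", params)

dir.create("results", showWarnings = FALSE)
write_gmt(list(myb_activated = gsr$activated,
               myb_repressed = gsr$repressed,
               kix_sensitive_activated = gsr$kix_sensitive_activated,
               kix_sensitive_repressed = gsr$kix_sensitive_repressed),
          "results/myb_gene_sets.gmt")

cat(sprintf("present in both WT conditions: %d of %d genes\n",
            length(present), nrow(vals)))
cat(sprintf("activated >= %.0f-fold: %d | KIX-sensitive: %d (%.0f%%)\n",
            params$induce_ratio, length(gsr$activated),
            length(gsr$kix_sensitive_activated),
            100 * gsr$frac_sensitive_activated))
cat(sprintf("repressed <= %.0f%%: %d | KIX-sensitive: %d (%.0f%%)\n",
            100 * params$repress_ratio, length(gsr$repressed),
            length(gsr$kix_sensitive_repressed),
            100 * gsr$frac_sensitive_repressed))

act_truth <- truth$gene_id[truth$class == "activated"]
rep_truth <- truth$gene_id[truth$class == "repressed"]
cat(sprintf("planted-truth recovery: %.1f%% activated, %.1f%% repressed\n",
            100 * mean(act_truth %in% gsr$activated),
            100 * mean(rep_truth %in% gsr$repressed)))

called <- data.frame(
  gene_id = c(gsr$activated, gsr$repressed),
  direction = c(rep("up", length(gsr$activated)),
                rep("down", length(gsr$repressed))))
planted <- data.frame(
  gene_id = c(act_truth, rep_truth),
  direction = c(rep("up", length(act_truth)),
                rep("down", length(rep_truth))))
conc <- direction_concordance(called, planted)
utils::write.table(conc$table, "results/direction_concordance.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("direction concordance vs planted truth: %d shared, %d same direction\n",
            conc$n_overlap, conc$n_same_direction))
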