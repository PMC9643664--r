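#!/usr/bin/env Rscript
# Validation stage: simulate three independent cohorts sharing the discovery
# ground truth (fresh batch effects, no controls), assign every case with the
# trained classifier, score an up/down risk signature, and quantify survival
# differences (KM/log-rank, Cox PH, C-index, nested LRT).

library(fibrotype)
source("analysis/00_config.R")

classifier <- read_classifier_json(file.path(RESULTS_DIR, "04_classifier.json"))

# the discovery truth is regenerated from its seed; validation cohorts share
# it but draw fresh samples and batch effects
truth <- simulate_multi_cohort(discovery_config())$truth
sim_val <- simulate_multi_cohort(validation_config(), truth = truth)

worst <- which.max(truth$true_hazard)
sams_sig <- list(up = truth$signature_genes[[worst]]$up,
                 down = truth$signature_genes[[worst]]$down)

rc <- run_config(sim_val$cohorts, rep("validation", 3),
                 out_dir = file.path(DATA_DIR, "validation"), seed = SEED)
val <- suppressWarnings(run_validation(rc, classifier, sams_signature = sams_sig))

truth_lab <- sim_val$truth$latent_cluster[names(val$labels)]
acc <- if (requireNamespace("mclust", quietly = TRUE)) {
  m <- match_cluster_labels(reference = truth_lab, labels = val$labels)
  m$agreement / length(truth_lab)
} else NA_real_

surv <- val$survival
summary_tab <- data.frame(
  quantity = c("validation_n", "accuracy_vs_truth_pct",
               "logrank_p_clusters", "hr_high_vs_low", "c_index",
               "hr_adjusted", "lrt_p", "sams_hr", "method_agreement_pct"),
  value = c(length(val$labels), 100 * acc,
            surv$km_cluster$p, unname(surv$cox_risk$hr[1]),
            surv$cox_risk$c_index,
            unname(surv$cox_risk_adjusted$hr[1]), surv$lrt_risk$p,
            unname(surv$cox_sams$hr[1]), val$agreement))
write.table(summary_tab, file.path(RESULTS_DIR, "05_validation_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Validation summary:\n")
print(summary_tab, row.names = FALSE)
cat("\nCox model, classifier risk groups (high vs low):\n")
print(surv$cox_risk)
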