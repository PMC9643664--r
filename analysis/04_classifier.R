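#!/usr/bin/env Rscript
# Compare clinical traits across the discovered clusters and train the
# compact greedy gene-expression cluster classifier on the clustered cases.

library(fibrotype)
source("analysis/00_config.R")

cases <- read_expression_tsv(file.path(DATA_DIR, "conorm_cases.tsv"))
pheno <- read.csv(file.path(DATA_DIR, "pheno_cases.csv"), stringsAsFactors = FALSE)
sol <- read.delim(file.path(DATA_DIR, "solution.tsv"), stringsAsFactors = FALSE)
labels <- ifelse(sol$label == "UNCLUSTERED", NA_integer_, as.integer(sol$label))
names(labels) <- sol$sample_id

pheno$gap_index <- with(pheno, gap_index(sex, age, fvc_pct, dlco_pct))
traits <- compare_traits(pheno, labels,
                         traits = c("age", "sex", "ancestry", "fvc_pct",
                                    "dlco_pct", "fev1_pct", "smoking_ever",
                                    "muc5b", "gap_index"))
write.table(traits, file.path(RESULTS_DIR, "04_trait_comparison.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Trait comparison across clusters:\n")
print(traits, row.names = FALSE)

candidates <- derive_candidate_genes(cases, labels, alpha_fdr = 0.01, min_effect = 0.5)
classifier <- greedy_train(cases, labels, candidates, seed = SEED)
classifier$low_risk_cluster <- pick_low_risk_cluster(
  labels, pheno$time[match(names(labels), pheno$sample_id)],
  pheno$event[match(names(labels), pheno$sample_id)])
write_classifier_json(classifier, file.path(RESULTS_DIR, "04_classifier.json"))

cat(sprintf("\nClassifier: %d genes, training accuracy %.1f%%, low-risk cluster %d\n",
            length(classifier$selected_genes),
            100 * classifier$training_accuracy, classifier$low_risk_cluster))
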