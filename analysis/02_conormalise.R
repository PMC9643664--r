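#!/usr/bin/env Rscript
# Pool the discovery cohorts on their common genes and co-normalise them with
# batch effects estimated from healthy controls only; report how well the
# cohorts mix in principal-component space before and after.

library(fibrotype)
source("analysis/00_config.R")

ddir <- file.path(DATA_DIR, "discovery")
ids <- sub("^expr_(.*)\\.tsv$", "\\1", list.files(ddir, pattern = "^expr_.*\\.tsv$"))
pheno <- read.csv(file.path(ddir, "pheno.csv"), stringsAsFactors = FALSE)
cohorts <- lapply(ids, function(id) {
  expr <- read_expression_tsv(file.path(ddir, sprintf("expr_%s.tsv", id)))
  cohort_data(expr, pheno[pheno$cohort_id == id, ], id)
})

pooled <- intersect_and_pool(cohorts)
params <- fit_control_combat(pooled$expression, pooled$annotations)
adjusted <- apply_conormalization(pooled$expression, pooled$annotations, params)

ann <- pooled$annotations
is_case <- ann$disease_status == "case"
mixing <- c(pre = batch_mixing_score(pooled$expression[params$genes, is_case],
                                     ann$cohort_id[is_case]),
            post = batch_mixing_score(adjusted[, is_case], ann$cohort_id[is_case]))

# controls are removed from all further analysis
write_expression_tsv(adjusted[, is_case], file.path(DATA_DIR, "conorm_cases.tsv"))
write_pheno_csv(ann[is_case, ], file.path(DATA_DIR, "pheno_cases.csv"))
write.table(data.frame(stage = names(mixing), batch_separation = mixing),
            file.path(RESULTS_DIR, "02_batch_mixing.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("Pooled %d cohorts on %d common genes (%d cases, %d controls).\n",
            length(cohorts), length(params$genes), sum(is_case), sum(!is_case)))
cat(sprintf("Batch separation in PC1-2 (0 = mixed, 1 = separated): pre %.3f -> post %.3f\n",
            mixing["pre"], mixing["post"]))
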