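# Shared settings for the analysis scripts. Run the scripts in order from the
# repository root:
#   Rscript analysis/01_simulate.R
#   Rscript analysis/02_conormalise.R
#   ...
# Bulky intermediates (expression matrices) live under scratch/analysis/ and
# are regenerated on demand; small summary tables are written to results/.

SEED <- 2026L
DATA_DIR <- "scratch/analysis"
RESULTS_DIR <- "results"

dir.create(DATA_DIR, showWarnings = FALSE, recursive = TRUE)
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

# Three discovery cohorts with healthy controls, emulating a pooled blood
# transcriptome study of idiopathic pulmonary fibrosis (cases 70/93/57,
# controls 45/30/20), with three latent case subgroups of which subgroup 2
# carries a much lower mortality hazard.
discovery_config <- function() {
  sim_config(
    n_cohorts = 3,
    n_cases = c(70, 93, 57), n_controls = c(45, 30, 20),
    n_genes_total = 1500, common_fraction = 0.85,
    K = 3, cluster_proportions = c(0.33, 0.48, 0.19),
    n_signature_genes = 150, effect_size = 1.5,
    batch_additive_sd = 2, batch_scale_shape = 5,
    hazard_per_cluster = c(0.25, 0.08, 0.30), censoring_rate = 0.10,
    seed = SEED)
}

validation_config <- function() {
  sim_config(
    n_cohorts = 3,
    n_cases = c(74, 45, 75), n_controls = c(0, 0, 0),
    n_genes_total = 1500, common_fraction = 1,
    K = 3, cluster_proportions = c(0.33, 0.48, 0.19),
    n_signature_genes = 150, effect_size = 1.5,
    batch_additive_sd = 2, batch_scale_shape = 5,
    hazard_per_cluster = c(0.25, 0.08, 0.30), censoring_rate = 0.10,
    cohort_prefix = "val", seed = SEED + 1L)
}
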