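# fibrotype

Endotype discovery from multi-cohort blood transcriptomes in idiopathic
pulmonary fibrosis (IPF).

IPF runs a highly variable clinical course, which suggests the disease is a
mixture of endotypes — subtypes driven by distinct pathophysiological
mechanisms. Single public cohorts are too small to find them, so this
package implements the full pipeline for pooling several blood
gene-expression cohorts and mining them for clinically distinct case
subgroups, aimed at researchers working with multi-cohort transcriptomic
studies of IPF or similar heterogeneous diseases:

1. **Controls-anchored co-normalisation** — cohorts are pooled on their
   common genes and batch effects are removed with the ComBat
   location/scale model estimated from *healthy controls only*: per gene
   `g` and batch `b`, empirical-Bayes-shrunk effects `γ*_bg` (additive) and
   `δ²*_bg` (multiplicative) adjust every sample as
   `y = σ_g·((x−α_g)/σ_g − γ*_bg)/√δ²*_bg + α_g`. Cases never influence the
   fit, so case biology survives the adjustment.
2. **Consensus clustering with an optimality map** — k-means and PAM over a
   grid of cluster numbers k and most-variable-gene subset sizes, scored by
   five validity indices (silhouette, Dunn, Calinski-Harabasz,
   connectivity, gap statistic); the z-score-aggregated map picks
   (k, gene count), and samples where the two algorithms disagree after
   optimal (Hungarian) label matching are called UNCLUSTERED.
3. **A compact greedy gene classifier** — per-cluster up/down gene
   signatures grown by greedy forward search on cross-validated balanced
   accuracy; a sample's score for cluster c is mean z-scored expression
   over c's up genes minus its down genes. Because scoring z-scores within
   each dataset, the classifier transfers to cohorts on other platforms
   without co-normalisation.
4. **Risk scoring and survival statistics** — up/down-signature risk scores
   with a median split (SAMS-style), cluster-to-risk dichotomisation, and a
   statistics layer with trait routing (χ²/Fisher, ANOVA/Kruskal-Wallis,
   log-rank), the GAP index, Cox proportional hazards with Harrell's
   C-index, nested likelihood-ratio tests, and hypergeometric
   over-representation.
5. **A synthetic multi-cohort generator** with known ground truth (latent
   subgroups, signature genes, batch effects, hazards), so every stage —
   and the pipeline end to end — is testable without any data download.

## Worked example

Simulate a three-cohort discovery study (planted K = 3 subgroups, one with
a much lower mortality hazard) and run the discovery pipeline:

```r
library(fibrotype)

cfg <- sim_config(n_cohorts = 3, n_cases = c(45, 45, 45), n_controls = c(15, 15, 15),
                  n_genes_total = 500, n_signature_genes = 60, effect_size = 2,
                  hazard_per_cluster = c(0.35, 0.08, 0.45), seed = 2024)
sim <- simulate_multi_cohort(cfg)

rc <- run_config(sim$cohorts, rep("discovery", 3), out_dir = tempfile("disc"), seed = 11,
                 cluster = list(k_values = 2:4, gene_counts = c(100, 250), gap_B = 10))
disc <- run_discovery(rc)

round(disc$mixing, 3)
#>   pre  post
#> 0.998 0.038
disc$map
#> <optimality_map> chosen k = 3 at 100 genes
#>      100    250
#> 2  0.041 -0.711
#> 3  1.066  0.568
#> 4 -0.377 -0.587
disc$solution
#> <cluster_solution> k = 3 (100 genes): sizes 27/51/57; unclustered 0 (0.0%)
disc$classifier
#> <cluster_classifier> k = 3, 4 genes; training accuracy 100.0%; low-risk cluster: 3

d <- disc$annotations
km_logrank(d$time, d$event, disc$solution$labels[d$sample_id])
#> <km_logrank> n = 135; log-rank chisq = 32.11 (df 2), p = 1.07e-07
#>   median survival: 1 = 1.93; 2 = 1.92; 3 = 6.46
```

Reading the output: before co-normalisation the three cohorts are almost
fully separated in PC space (mixing score 0.998); afterwards they overlap
(0.038). The optimality map picks k = 3 at 100 genes — the planted number of
subgroups — with no unclustered samples; a 4-gene classifier reassigns all
training cases, and the cluster with the lowest crude event rate (here
cluster 3, median survival 6.5 years vs ≈ 1.9) is recorded as the low-risk
group for downstream risk dichotomisation. `run_validation()` then applies
the classifier and an up/down risk signature to fresh cohorts and fits the
corresponding Cox models.

The `analysis/` directory holds the same workflow as numbered narrative
scripts (`01_simulate.R` … `05_validation.R`, run from the repository root);
their summary tables land in `results/`.

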