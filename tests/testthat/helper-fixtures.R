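# Shared fixtures, all generated in code.

# Two-batch control fixture: batch 2 equals batch 1 plus a constant offset on
# every gene; cases carry the same batch offset plus a planted case-vs-control
# contrast on the first `n_signal` genes. Per-gene noise SDs vary so that
# standardised-scale quantities (offset / sigma_g) differ across genes.
make_offset_fixture <- function(n_genes = 400, n_ctrl = 50, n_case = 30,
                                offset = 2, signal = 1.5, n_signal = 25,
                                seed = 42) {
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  mu <- stats::rnorm(n_genes, 8, 2)
  noise_sd <- stats::runif(n_genes, 0.5, 1.5)
  mk <- function(bid, off) {
    n <- n_case + n_ctrl
    ids <- sprintf("%s_S%03d", bid, seq_len(n))
    x <- matrix(mu, n_genes, n, dimnames = list(genes, ids)) + off +
      matrix(stats::rnorm(n_genes * n, sd = noise_sd), n_genes, n)
    x[seq_len(n_signal), seq_len(n_case)] <-
      x[seq_len(n_signal), seq_len(n_case)] + signal
    ann <- data.frame(sample_id = ids, cohort_id = bid,
                      disease_status = c(rep("case", n_case), rep("control", n_ctrl)),
                      stringsAsFactors = FALSE)
    cohort_data(x, ann, bid)
  }
  list(cohorts = list(mk("b1", 0), mk("b2", offset)),
       mu = mu, noise_sd = noise_sd, offset = offset, signal = signal,
       signal_genes = genes[seq_len(n_signal)])
}

# Minimal hand-built validity grid carrying two assignments, for consensus tests.
fake_grid <- function(km, pam, k, gene_count = 10) {
  structure(list(
    cells = data.frame(algorithm = c("kmeans", "pam"), k = k,
                       gene_count = gene_count, silhouette = 0.5, dunn = 1,
                       calinski_harabasz = 1, neg_connectivity = 0,
                       gap_statistic = 0, gap_se = 0.1, failed = FALSE),
    assignments = stats::setNames(list(km, pam),
                                  sprintf(c("kmeans:%d:%d", "pam:%d:%d"), k, gene_count)),
    sample_ids = names(km) %||% paste0("s", seq_along(km)),
    k_values = k, gene_counts = gene_count, params = list()
  ), class = "validity_grid")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# All permutations of 1..k (k small), for brute-force matching oracles.
all_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in all_perms(k - 1)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1)
    }
  }
  out
}

# Brute-force maximum-agreement matching of labels onto a reference.
brute_match_agreement <- function(reference, labels) {
  k <- max(reference, labels)
  best <- -Inf
  for (p in all_perms(k)) {
    best <- max(best, sum(unlist(p)[labels] == reference))
  }
  as.integer(best)
}

# Lazily computed shared discovery pipeline fixture (kept small).
.fixtures <- new.env(parent = emptyenv())

shared_discovery <- function() {
  if (!is.null(.fixtures$disc)) return(.fixtures$disc)
  cfg <- sim_config(n_cohorts = 3, n_cases = c(45, 45, 45), n_controls = c(15, 15, 15),
                    n_genes_total = 500, n_signature_genes = 60, effect_size = 2,
                    hazard_per_cluster = c(0.35, 0.08, 0.45), seed = 2024)
  sim <- simulate_multi_cohort(cfg)
  rc <- run_config(sim$cohorts, rep("discovery", 3),
                   out_dir = file.path(tempdir(), "disc_fixture"), seed = 11,
                   cluster = list(k_values = 2:4, gene_counts = c(100, 250),
                                  gap_B = 10))
  disc <- suppressWarnings(run_discovery(rc))
  .fixtures$disc <- list(sim = sim, config = rc, disc = disc)
  .fixtures$disc
}
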