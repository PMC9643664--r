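toy_cohort <- function(id, genes, n = 4) {
  ids <- sprintf("%s_s%d", id, seq_len(n))
  x <- matrix(seq_len(length(genes) * n) + 0.5, length(genes), n,
              dimnames = list(genes, ids))
  ann <- data.frame(sample_id = ids, cohort_id = id,
                    disease_status = rep(c("case", "control"), length.out = n))
  cohort_data(x, ann, id)
}

test_that("pooling restricts to the sorted gene intersection", {
  cohorts <- list(toy_cohort("a", c("A", "B", "C")),
                  toy_cohort("b", c("B", "C", "D")),
                  toy_cohort("c", c("C", "E", "B")))
  pooled <- intersect_and_pool(cohorts)
  expect_identical(rownames(pooled$expression), c("B", "C"))
  expect_identical(ncol(pooled$expression), 12L)
  expect_identical(pooled$annotations$cohort_id, rep(c("a", "b", "c"), each = 4))

  full <- intersect_and_pool(list(toy_cohort("a", c("A", "B")),
                                  toy_cohort("b", c("A", "B"))))
  expect_identical(rownames(full$expression), c("A", "B"))

  expect_error(intersect_and_pool(list(toy_cohort("a", "A"), toy_cohort("b", "B"))),
               "empty gene intersection.*a.*b")
  expect_error(intersect_and_pool(list(toy_cohort("a", "A"), toy_cohort("a", "A"))),
               "duplicate sample")
})

test_that("a single batch yields identity adjustment (gamma 0, delta2 1)", {
  set.seed(1)
  genes <- sprintf("G%03d", 1:100)
  ids <- sprintf("s%02d", 1:40)
  x <- matrix(rnorm(100 * 40, 8, 2), 100, 40, dimnames = list(genes, ids))
  ann <- data.frame(sample_id = ids, cohort_id = "only",
                    disease_status = rep(c("control", "case"), 20))
  p <- fit_control_combat(x, ann)
  expect_lt(max(abs(p$gamma_star)), 1e-6)
  expect_lt(max(abs(p$delta2_star - 1)), 1e-6)
  adj <- apply_conormalization(x, ann, p)
  expect_lt(max(abs(adj - x)), 1e-6)
})

test_that("a constant between-batch offset is recovered and removed", {
  fx <- make_offset_fixture(n_ctrl = 150, n_case = 150)
  pooled <- intersect_and_pool(fx$cohorts)
  p <- fit_control_combat(pooled$expression, pooled$annotations)

  # EB estimates track the truth offset (standardised scale) across genes
  d_gamma <- p$gamma_star["b2", ] - p$gamma_star["b1", ]
  expect_gte(cor(d_gamma, fx$offset / p$sigma), 0.95)
  expect_lt(abs(stats::median(d_gamma * p$sigma) - fx$offset), 0.1)

  # oracle: the raw (no-EB) per-gene control means recover the offset directly
  ann <- pooled$annotations
  ctrl <- ann$disease_status == "control"
  raw_diff <- rowMeans(pooled$expression[, ctrl & ann$cohort_id == "b2"]) -
    rowMeans(pooled$expression[, ctrl & ann$cohort_id == "b1"])
  expect_equal(unname((p$gamma_hat["b2", ] - p$gamma_hat["b1", ]) * p$sigma),
               unname(raw_diff), tolerance = 1e-10)

  adj <- apply_conormalization(pooled$expression, ann, p)
  post_ctrl <- abs(rowMeans(adj[, ctrl & ann$cohort_id == "b2"]) -
                     rowMeans(adj[, ctrl & ann$cohort_id == "b1"]))
  expect_lt(stats::median(post_ctrl), 0.1)

  # cases also carried the offset: their batch-mean gap shrinks too
  cs <- ann$disease_status == "case"
  post_case <- abs(rowMeans(adj[, cs & ann$cohort_id == "b2"]) -
                     rowMeans(adj[, cs & ann$cohort_id == "b1"]))
  expect_lt(stats::median(post_case), 0.15)

  # while the planted case-vs-control contrast survives within 10%
  contrast <- rowMeans(adj[fx$signal_genes, cs]) - rowMeans(adj[fx$signal_genes, ctrl])
  expect_lt(abs(mean(contrast) - fx$signal) / fx$signal, 0.10)
})

test_that("a null batch split shows no spurious location effect", {
  set.seed(10)
  genes <- sprintf("G%03d", 1:300)
  ids <- sprintf("s%03d", 1:80)
  x <- matrix(rnorm(300 * 80, 6, 1.5), 300, 80, dimnames = list(genes, ids))
  ann <- data.frame(sample_id = ids,
                    cohort_id = sample(rep(c("p", "q"), 40)),
                    disease_status = "control")
  p <- fit_control_combat(x, ann)
  expect_lt(abs(stats::median(p$gamma_star["q", ] - p$gamma_star["p", ])), 0.05)
})

test_that("case samples never influence the fitted parameters", {
  fx <- make_offset_fixture(n_genes = 150)
  pooled <- intersect_and_pool(fx$cohorts)
  p1 <- fit_control_combat(pooled$expression, pooled$annotations)
  tampered <- pooled$expression
  cs <- pooled$annotations$disease_status == "case"
  tampered[, cs] <- tampered[, cs] + matrix(rnorm(sum(cs) * nrow(tampered), 0, 5),
                                            nrow(tampered), sum(cs))
  p2 <- fit_control_combat(tampered, pooled$annotations)
  expect_identical(p1, p2)
})

test_that("fit+apply commutes with gene permutation and contracts on reapplication", {
  fx <- make_offset_fixture(n_genes = 120, seed = 77)
  pooled <- intersect_and_pool(fx$cohorts)
  ann <- pooled$annotations
  p <- fit_control_combat(pooled$expression, ann)
  adj <- apply_conormalization(pooled$expression, ann, p)

  perm <- sample(nrow(pooled$expression))
  pperm <- fit_control_combat(pooled$expression[perm, ], ann)
  adj_perm <- apply_conormalization(pooled$expression[perm, ], ann, pperm)
  expect_equal(adj_perm, adj[rownames(adj_perm), ], tolerance = 1e-12)

  # empirical-Bayes shrinkage deliberately leaves a small residual batch
  # effect, so refit+reapply is a contraction (each pass removes most of
  # what remains), not an exact fixed point
  p2 <- fit_control_combat(adj, ann)
  adj2 <- apply_conormalization(adj, ann, p2)
  first_pass <- max(abs(adj - pooled$expression))
  second_pass <- max(abs(adj2 - adj))
  expect_lt(second_pass, 0.1 * first_pass)
})

test_that("errors: too few controls, unknown batch, degenerate genes dropped", {
  fx <- make_offset_fixture(n_genes = 60, n_ctrl = 2)
  pooled <- intersect_and_pool(fx$cohorts)
  expect_error(fit_control_combat(pooled$expression, pooled$annotations),
               "fewer than 3 controls")

  fx2 <- make_offset_fixture(n_genes = 60)
  pooled2 <- intersect_and_pool(fx2$cohorts)
  flat <- pooled2$expression
  flat["G0005", pooled2$annotations$disease_status == "control"] <- 1  # constant in controls
  expect_warning(p <- fit_control_combat(flat, pooled2$annotations),
                 "near-zero control variance")
  expect_identical(p$dropped_genes, "G0005")
  expect_false("G0005" %in% rownames(apply_conormalization(flat, pooled2$annotations, p)))

  bad_ann <- pooled2$annotations
  bad_ann$cohort_id[1] <- "mystery"
  p2 <- fit_control_combat(pooled2$expression, pooled2$annotations)
  expect_error(apply_conormalization(pooled2$expression, bad_ann, p2),
               "without fitted parameters")
})

test_that("batch mixing score is 0 for identical batches and drops after adjustment", {
  set.seed(2)
  x <- matrix(rnorm(50 * 10), 50, 10,
              dimnames = list(sprintf("g%d", 1:50), sprintf("s%d", 1:10)))
  dup <- cbind(x, x)
  colnames(dup) <- sprintf("s%d", 1:20)
  expect_lt(batch_mixing_score(dup, rep(c("a", "b"), each = 10)), 1e-9)

  fx <- make_offset_fixture()
  pooled <- intersect_and_pool(fx$cohorts)
  p <- fit_control_combat(pooled$expression, pooled$annotations)
  adj <- apply_conormalization(pooled$expression, pooled$annotations, p)
  batch <- pooled$annotations$cohort_id
  pre <- batch_mixing_score(pooled$expression[p$genes, ], batch)
  post <- batch_mixing_score(adj, batch)
  expect_lt(post, pre)

  expect_error(batch_mixing_score(x, rep("a", 10)), "at least 2 batches")
  expect_error(batch_mixing_score(dup[, 1:12], c(rep("a", 10), "b", "b")),
               "3 samples per batch")
})
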