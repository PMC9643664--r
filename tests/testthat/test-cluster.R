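test_that("variable-gene selection ranks by variance with id tie-breaks", {
  x <- rbind(a5 = c(0, 4, 0, 4), b  = c(0, 3, 0, 3), c  = c(0, 2, 0, 2),
             d  = c(0, 1, 0, 1), e  = c(1, 1, 1, 1))
  colnames(x) <- paste0("s", 1:4)
  expect_identical(select_variable_genes(x, 2), c("a5", "b"))
  expect_identical(select_variable_genes(x, 99), c("a5", "b", "c", "d", "e"))
  tie <- rbind(z = c(0, 1), y = c(0, 1), x = c(5, 5))
  colnames(tie) <- c("s1", "s2")
  expect_identical(select_variable_genes(tie, 2), c("y", "z"))
  expect_error(select_variable_genes(x, 1), "n must be")
})

test_that("validity indices match hand computation on the 1-D 4-point fixture", {
  X <- matrix(c(0, 0.2, 10, 10.2), 4, 1)
  labels <- c(1, 1, 2, 2)
  m <- cluster_validity_measures(X, labels, neighbours = 2)
  # silhouette by hand: outer points (0, 10.2) have a = 0.2, b = 10.1;
  # inner points (0.2, 10) have a = 0.2, b = 9.9
  sil_hand <- (( 10.1 - 0.2) / 10.1 + (9.9 - 0.2) / 9.9) / 2
  expect_equal(unname(m["silhouette"]), sil_hand, tolerance = 1e-6)
  expect_equal(unname(m["silhouette"]), 0.98, tolerance = 1e-4)
  expect_equal(unname(m["dunn"]), 9.8 / 0.2, tolerance = 1e-6)
  # Calinski-Harabasz: B = 4 * 5^2, W = 4 * 0.01 -> (100/1)/(0.04/2)
  expect_equal(unname(m["calinski_harabasz"]), 100 / 0.02, tolerance = 1e-6)
  # all nearest neighbours are intra-cluster at L = 1
  m1 <- cluster_validity_measures(X, labels, neighbours = 1)
  expect_equal(unname(m1["neg_connectivity"]), 0)
})

test_that("the grid recovers the obvious 2-cluster split and is deterministic", {
  x <- rbind(g1 = c(0, 0.2, 10, 10.2), g2 = c(0, 0.2, 10, 10.2))
  colnames(x) <- paste0("s", 1:4)
  g <- run_grid(x, k_values = 2, gene_counts = 2, gap_B = 5, seed = 1)
  expect_true(all(!g$cells$failed))
  for (alg in c("kmeans", "pam")) {
    lab <- g$assignments[[paste0(alg, ":2:2")]]
    expect_identical(unname(lab[1]), unname(lab[2]))
    expect_identical(unname(lab[3]), unname(lab[4]))
    expect_false(lab[1] == lab[3])
  }
  # z-scoring preserves the silhouette/Dunn ratios of the raw fixture
  sil_hand <- ((10.1 - 0.2) / 10.1 + (9.9 - 0.2) / 9.9) / 2
  expect_equal(g$cells$silhouette, rep(sil_hand, 2), tolerance = 1e-6)
  expect_equal(g$cells$dunn, rep(49, 2), tolerance = 1e-6)

  g2 <- run_grid(x, k_values = 2, gene_counts = 2, gap_B = 5, seed = 1)
  expect_identical(g$cells, g2$cells)
  expect_identical(g$assignments, g2$assignments)
})

test_that("duplicating every sample leaves the partition structure intact", {
  set.seed(3)
  x <- matrix(rnorm(40 * 30), 40, 30, dimnames = list(sprintf("g%d", 1:40), NULL))
  x[, 1:15] <- x[, 1:15] + 6  # well-separated clusters: duplication barely moves a(i)
  colnames(x) <- sprintf("s%d", 1:30)
  dup <- cbind(x, x)
  colnames(dup) <- sprintf("s%d", 1:60)
  g1 <- run_grid(x, k_values = 2, gene_counts = 40, gap_B = 3, seed = 9)
  g2 <- run_grid(dup, k_values = 2, gene_counts = 40, gap_B = 3, seed = 9)
  l1 <- g1$assignments[["kmeans:2:40"]]
  l2 <- g2$assignments[["kmeans:2:40"]]
  m <- match_cluster_labels(rep(unname(l1), 2), unname(l2))
  expect_equal(m$agreement, 60)
  expect_equal(g1$cells$silhouette[1], g2$cells$silhouette[1], tolerance = 0.02)
})

test_that("optimality map aggregates z-scores and breaks ties toward small k", {
  # hand-set 2x2 grid, one algorithm dominating cell: k=3 / 100 genes
  cells <- expand.grid(algorithm = c("kmeans", "pam"), k = c(2, 3),
                       gene_count = c(100, 200), stringsAsFactors = FALSE)
  cells$silhouette <- ifelse(cells$k == 3 & cells$gene_count == 100, 0.9, 0.2)
  cells$dunn <- ifelse(cells$k == 3 & cells$gene_count == 100, 3, 1)
  cells$calinski_harabasz <- ifelse(cells$k == 3 & cells$gene_count == 100, 50, 10)
  cells$neg_connectivity <- ifelse(cells$k == 3 & cells$gene_count == 100, -1, -9)
  cells$gap_statistic <- ifelse(cells$k == 3 & cells$gene_count == 100, 1, 0.1)
  cells$gap_se <- 0.05
  cells$failed <- FALSE
  grid <- structure(list(cells = cells, assignments = list(),
                         sample_ids = character(0), k_values = c(2, 3),
                         gene_counts = c(100, 200), params = list()),
                    class = "validity_grid")
  map <- build_optimality_map(grid)
  expect_identical(c(map$chosen_k, map$chosen_gene_count), c(3, 100))

  # arithmetic oracle: recompute the aggregate for one cell by hand
  meas <- c("silhouette", "dunn", "calinski_harabasz", "neg_connectivity", "gap_statistic")
  z <- sapply(meas, function(m) (cells[[m]] - mean(cells[[m]])) / stats::sd(cells[[m]]))
  byhand <- tapply(rowMeans(z), list(cells$k, cells$gene_count), mean)
  expect_equal(unname(map$matrix), unname(byhand), tolerance = 1e-12)

  # exact ties break toward smaller k, then smaller gene count
  cells2 <- cells
  for (m in meas) cells2[[m]] <- 1
  grid2 <- grid; grid2$cells <- cells2
  map2 <- build_optimality_map(grid2)
  expect_identical(c(map2$chosen_k, map2$chosen_gene_count), c(2, 100))
})

test_that("hungarian matching equals exhaustive permutation search", {
  set.seed(42)
  for (k in 2:5) {
    for (rep in 1:10) {
      cost <- matrix(runif(k * k), k, k)
      assign <- hungarian_min(cost)
      best <- min(vapply(all_perms(k), function(p)
        sum(cost[cbind(seq_len(k), unlist(p))]), 0))
      expect_equal(sum(cost[cbind(seq_len(k), assign)]), best, tolerance = 1e-12)
    }
    ref <- sample(seq_len(k), 40, replace = TRUE)
    lab <- sample(seq_len(k), 40, replace = TRUE)
    m <- match_cluster_labels(ref, lab)
    expect_identical(m$agreement, brute_match_agreement(ref, lab))
  }
})

test_that("consensus assignment is permutation-invariant and flags disagreement", {
  km <- c(1, 1, 2, 2); names(km) <- paste0("s", 1:4)
  pam <- c(2, 2, 1, 1); names(pam) <- names(km)
  sol <- consensus_assign(fake_grid(km, pam, 2, 10), 2, 10)
  expect_identical(unname(sol$labels), c(1, 1, 2, 2))
  expect_identical(sol$unclustered_fraction, 0)

  km10 <- rep(1:2, each = 5); names(km10) <- paste0("s", 1:10)
  pam10 <- km10; pam10[10] <- 1  # one disagreement after identity matching
  pam10 <- (pam10 %% 2) + 1      # permute labels: matching must undo this
  sol10 <- consensus_assign(fake_grid(km10, pam10, 2, 10), 2, 10)
  expect_identical(sum(is.na(sol10$labels)), 1L)
  expect_identical(unname(which(is.na(sol10$labels))), 10L)
  expect_equal(sol10$unclustered_fraction, 0.1)

  # relabelling either input leaves the solution identical
  perm <- c(2, 1)
  km_p <- perm[km10]; names(km_p) <- names(km10)
  sol_p <- consensus_assign(fake_grid(km10, km_p, 2, 10), 2, 10)
  expect_identical(sum(is.na(sol_p$labels)), 0L)
})

test_that("clusters planted in multi-cohort data are found after co-normalisation", {
  skip_if_not_installed("mclust")
  fx <- shared_discovery()
  sol <- fx$disc$solution
  expect_identical(sol$k, 3L)
  truth <- fx$sim$truth$latent_cluster[names(sol$labels)]
  ok <- !is.na(sol$labels)
  ari <- mclust::adjustedRandIndex(sol$labels[ok], truth[ok])
  expect_gte(ari, 0.8)
})
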