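# Small labelled expression fixture: K clusters, a few clean signal genes.
make_labelled_fixture <- function(n_per = 40, n_signal_per = 2, n_noise = 200,
                                  shift = 2, seed = 11, K = 3) {
  set.seed(seed)
  n <- n_per * K
  labels <- rep(seq_len(K), each = n_per)
  genes <- c(sprintf("SIG%02d", seq_len(K * n_signal_per)),
             sprintf("N%03d", seq_len(n_noise)))
  x <- matrix(rnorm(length(genes) * n, 7, 1), length(genes), n,
              dimnames = list(genes, sprintf("s%03d", seq_len(n))))
  truth_sig <- list()
  for (k in seq_len(K)) {
    gk <- sprintf("SIG%02d", ((k - 1) * n_signal_per + 1):(k * n_signal_per))
    up <- gk[seq_len(ceiling(n_signal_per / 2))]
    dn <- setdiff(gk, up)
    x[up, labels == k] <- x[up, labels == k] + shift
    if (length(dn)) x[dn, labels == k] <- x[dn, labels == k] - shift
    truth_sig[[as.character(k)]] <- list(up = up, down = dn)
  }
  names(labels) <- colnames(x)
  list(x = x, labels = labels, signature = truth_sig,
       signal_genes = grep("^SIG", genes, value = TRUE))
}

test_that("planted differential genes are recovered with correct direction", {
  fx <- make_labelled_fixture(n_per = 50, n_signal_per = 10, n_noise = 300)
  cand <- derive_candidate_genes(fx$x, fx$labels, alpha_fdr = 0.01, min_effect = 0.5)
  recovered <- unique(cand$table$gene[grepl("^SIG", cand$table$gene)])
  expect_gte(length(recovered) / length(fx$signal_genes), 0.9)
  # direction agrees with the planted truth for nearly all recovered genes
  hits <- cand$table[grepl("^SIG", cand$table$gene), ]
  correct <- mapply(function(g, cl, dir) {
    s <- fx$signature[[as.character(cl)]]
    (dir == "up" && g %in% s$up) || (dir == "down" && g %in% s$down) ||
      !(g %in% c(s$up, s$down))  # a gene may also separate *other* clusters
  }, hits$gene, hits$cluster, hits$direction)
  own <- mapply(function(g, cl) {
    s <- fx$signature[[as.character(cl)]]
    g %in% c(s$up, s$down)
  }, hits$gene, hits$cluster)
  expect_gte(mean(correct[own]), 0.95)
})

test_that("permuted labels give candidate counts at the type-I level", {
  fx <- make_labelled_fixture(n_per = 30, n_signal_per = 2, n_noise = 300, seed = 5)
  set.seed(99)
  counts <- vapply(1:20, function(i) {
    perm <- sample(fx$labels)
    names(perm) <- names(fx$labels)
    n <- tryCatch(nrow(suppressWarnings(
      derive_candidate_genes(fx$x, perm, alpha_fdr = 0.01, min_effect = 0.1))$table),
      error = function(e) 0L)
    as.integer(n)
  }, 1L)
  expect_lte(mean(counts), 0.01 * nrow(fx$x) * 3)
})

test_that("a null gene is called at no more than the nominal rate", {
  set.seed(314)
  hits <- 0L
  for (i in 1:100) {
    x <- matrix(rnorm(60), 1, 60, dimnames = list("g1", sprintf("s%d", 1:60)))
    labels <- stats::setNames(rep(1:2, each = 30), colnames(x))
    hits <- hits + tryCatch(
      nrow(derive_candidate_genes(x, labels, alpha_fdr = 0.01, min_effect = 0.5)$table) > 0,
      error = function(e) FALSE)
  }
  # false-call probability per simulation is ~0.01; P(X >= 6 | Binom(100, .01)) < 1e-5
  expect_lte(hits, 5L)
})

test_that("greedy training nails perfectly separated clusters", {
  fx <- make_labelled_fixture(n_per = 20, n_signal_per = 1, n_noise = 50,
                              shift = 10, seed = 2)
  cand <- derive_candidate_genes(fx$x, fx$labels, alpha_fdr = 0.01, min_effect = 1)
  clf <- greedy_train(fx$x, fx$labels, cand, max_genes = 10, seed = 3)
  expect_true(all(clf$selected_genes %in% fx$signal_genes))
  expect_identical(clf$training_accuracy, 1)
})

test_that("training on realistic signal stays accurate, precise and unoverfit", {
  fx <- make_labelled_fixture(n_per = 67, n_signal_per = 2, n_noise = 200,
                              shift = 2, seed = 11)
  cand <- derive_candidate_genes(fx$x, fx$labels)
  clf <- greedy_train(fx$x, fx$labels, cand, seed = 11)
  expect_gte(clf$training_accuracy, 0.9)
  expect_gte(mean(clf$selected_genes %in% fx$signal_genes), 0.8)

  # score rule cross-check: recompute score_c independently for 5 samples
  z <- t(scale(t(fx$x[unique(unlist(lapply(clf$signature, unlist))), , drop = FALSE])))
  for (s in c(1, 30, 80, 120, 200)) {
    sc <- vapply(clf$signature, function(sg) {
      up <- if (length(sg$up)) mean(z[sg$up, s]) else 0
      dn <- if (length(sg$down)) mean(z[sg$down, s]) else 0
      up - dn
    }, 0)
    pred <- as.integer(names(sc)[which.max(sc)])
    expect_identical(unname(classify_samples(clf, fx$x)[s]), pred)
  }

  # overfitting guard across seeds
  for (sd_ in 1:5) {
    clf_s <- greedy_train(fx$x, fx$labels, cand, seed = sd_)
    expect_lte(clf_s$cv_accuracy, clf_s$training_accuracy + 0.1)
  }
})

test_that("classification is self-consistent and affine-invariant", {
  fx <- make_labelled_fixture(seed = 8)
  cand <- derive_candidate_genes(fx$x, fx$labels)
  clf <- greedy_train(fx$x, fx$labels, cand, seed = 8)
  lab <- classify_samples(clf, fx$x)
  expect_identical(mean(lab == fx$labels), clf$training_accuracy)
  # monotone affine transform of the whole dataset changes nothing
  lab2 <- classify_samples(clf, 3.7 * fx$x + 12)
  expect_identical(lab, lab2)
})

test_that("classification refuses when too few classifier genes are present", {
  fx <- make_labelled_fixture(seed = 8)
  cand <- derive_candidate_genes(fx$x, fx$labels)
  clf <- greedy_train(fx$x, fx$labels, cand, seed = 8)
  n_sel <- length(clf$selected_genes)
  skip_if(n_sel < 3)
  keep <- setdiff(rownames(fx$x), clf$selected_genes[1:ceiling(0.5 * n_sel)])
  expect_error(classify_samples(clf, fx$x[keep, ]), "classifier genes present")
  keep1 <- setdiff(rownames(fx$x), clf$selected_genes[1])
  if ((n_sel - 1) / n_sel >= 0.8)
    expect_warning(classify_samples(clf, fx$x[keep1, ]), "missing from the dataset")
})

test_that("cv_folds larger than the smallest cluster is refused", {
  fx <- make_labelled_fixture(n_per = 6, n_signal_per = 2, n_noise = 30, shift = 8)
  cand <- derive_candidate_genes(fx$x, fx$labels, min_effect = 1)
  expect_error(greedy_train(fx$x, fx$labels, cand, cv_folds = 10),
               "smallest cluster")
})

test_that("risk scoring reproduces hand arithmetic and handles one-sided signatures", {
  z <- rbind(up1 = c(1, 0.5, -0.5, -1), dn1 = c(-1, -0.5, 0.5, 1))
  colnames(z) <- paste0("s", 1:4)
  res <- sams_score("up1", "dn1", z, standardise = FALSE)
  expect_equal(res$combined_score, c(2, 1, -1, -2))
  expect_identical(res$risk, c("high", "high", "low", "low"))

  one <- sams_score("up1", character(0), z, standardise = FALSE)
  expect_equal(one$combined_score, unname(z["up1", ]))

  # missing signature genes are dropped with a warning, scores use the rest
  expect_warning(part <- sams_score(c("up1", "ghost"), "dn1", z, standardise = FALSE),
                 "absent")
  expect_equal(part$combined_score, res$combined_score)
  expect_error(sams_score("ghost", "phantom", z), "no signature genes")
})

test_that("z-scored risk scoring ranks samples by planted signature burden", {
  set.seed(6)
  x <- matrix(rnorm(30 * 40, 8, 1), 30, 40,
              dimnames = list(sprintf("g%d", 1:30), sprintf("s%d", 1:40)))
  hot <- 1:10  # first ten samples overexpress the up genes
  x[1:5, hot] <- x[1:5, hot] + 3
  res <- sams_score(sprintf("g%d", 1:5), sprintf("g%d", 6:10), x)
  expect_true(all(res$risk[hot] == "high"))
})

test_that("method agreement is exact on toy vectors", {
  expect_identical(method_agreement(c("H", "H", "L"), c("H", "H", "L")), 100)
  expect_identical(method_agreement(c("H", "H", "L", "L", "H"),
                                    c("H", "L", "L", "L", "H")), 80)
  a <- stats::setNames(c("H", "L"), c("s1", "s2"))
  b <- stats::setNames(c("L", "H"), c("s3", "s4"))
  expect_error(method_agreement(a, b), "share no samples")
})

test_that("the low-risk cluster is the one with the best observed survival", {
  set.seed(4)
  labels <- stats::setNames(rep(1:3, each = 100), sprintf("s%d", 1:300))
  haz <- c(0.4, 0.08, 0.5)[labels]
  time <- rexp(300, haz)
  expect_identical(pick_low_risk_cluster(labels, time, rep(1, 300)), 2L)
  risk <- risk_from_clusters(labels, 2L)
  expect_identical(unname(risk[c(1, 101, 201)]), c("high", "low", "high"))
})
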