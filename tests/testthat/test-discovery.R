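test_that("mRMR puts a strongly planted feature first and penalizes duplicates", {
  hits <- 0
  for (s in 1:20) {
    tab <- generate_feature_table(120, 100, 1, 3, seed = s)
    r <- mrmr_rank(tab$values, tab$labels, 10)
    hits <- hits + (r$order[1] == tab$informative)
  }
  expect_gte(hits, 18)
  # an exact duplicate of the top feature is pushed below rank 2
  tab <- generate_feature_table(120, 50, 1, 3, seed = 1)
  dup <- cbind(tab$values, DUP = tab$values[, tab$informative])
  r <- mrmr_rank(dup, tab$labels, 10)
  expect_equal(r$order[1], tab$informative)
  expect_gt(which(r$order == ncol(dup)), 2)
  # k = p returns every feature exactly once
  rall <- mrmr_rank(tab$values[, 1:8], tab$labels, 8)
  expect_setequal(rall$order, 1:8)
  expect_error(mrmr_rank(tab$values, rep(1, 120), 5), "single class")
})

test_that("redundancy pruning follows the greedy top-down rule", {
  # exact construction: corr(A,B) = 0.95, corr(A,C) = 0.8, corr(B,C) = 0.92
  basis <- withr::with_seed(51, {
    m <- scale(matrix(rnorm(200 * 3), 200, 3), scale = FALSE)
    qr.Q(qr(m))
  })
  e1 <- basis[, 1]; e2 <- basis[, 2]; e3 <- basis[, 3]
  A <- e1
  B <- 0.95 * e1 + sqrt(1 - 0.95^2) * e2
  beta <- (0.92 - 0.95 * 0.8) / sqrt(1 - 0.95^2)
  C <- 0.8 * e1 + beta * e2 + sqrt(1 - 0.8^2 - beta^2) * e3
  X <- cbind(A, B, C)
  expect_equal(cor(X)[1, 2], 0.95, tolerance = 1e-10)
  expect_equal(cor(X)[2, 3], 0.92, tolerance = 1e-10)
  # B is dropped against A; C survives because only A remains
  expect_equal(prune_redundant(1:3, X, 0.90), c(1, 3))
  # perfectly correlated pair: lower-ranked one removed
  expect_equal(prune_redundant(1:2, cbind(A, 2 * A + 1), 0.90), 1)
  # orthogonal features: untouched
  expect_equal(prune_redundant(1:3, basis, 0.90), 1:3)
})

test_that("the two-stage protocol retains the top decile and caps at ten", {
  tab <- generate_feature_table(30, 1980, 0, 0, seed = 61)
  cfg <- discovery_config(n_iterations = 2, seed = 1)
  dr <- discovery_protocol(tab$values, tab$labels, cfg)
  expect_length(dr$stage1_retained, ceiling(0.10 * 1980))
  expect_lte(length(dr$top_features), 10)
  expect_true(all(dr$top_features %in% dr$stage1_retained))
  # determinism under a fixed seed
  small <- tab$values[, 1:120]
  d1 <- discovery_protocol(small, tab$labels,
                           discovery_config(n_iterations = 5, seed = 42))
  d2 <- discovery_protocol(small, tab$labels,
                           discovery_config(n_iterations = 5, seed = 42))
  expect_identical(d1$top_features, d2$top_features)
  expect_identical(d1$selection_frequency, d2$selection_frequency)
})

test_that("majority downsampling bounds the per-iteration sample size", {
  tab <- generate_feature_table(80, 60, 3, 1.5, seed = 71,
                                class_balance = 0.25)
  expect_equal(sum(tab$labels == 1), 20)  # minority
  cfg <- discovery_config(n_iterations = 10, downsample_majority_to = 20,
                          seed = 3)
  dr <- discovery_protocol(tab$values, tab$labels, cfg)
  expect_true(all(dr$iteration_n == 40))  # 20 majority + 20 minority
  cfg0 <- discovery_config(n_iterations = 10, seed = 3)
  dr0 <- discovery_protocol(tab$values, tab$labels, cfg0)
  expect_true(all(dr0$iteration_n == 80))
})

test_that("null tables yield approximately uniform selection frequencies", {
  counts <- numeric(40)
  for (s in 1:100) {
    tab <- generate_feature_table(60, 40, 0, 0, seed = 300 + s)
    r <- mrmr_rank(tab$values, tab$labels, 10)
    counts[r$order] <- counts[r$order] + 1
  }
  gof <- chisq.test(counts)
  expect_gt(gof$p.value, 0.01)
})
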