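test_that("DLDA thresholds at the midpoint and matches LDA when diagonal", {
  x <- withr::with_seed(61, matrix(c(rnorm(20, 0), rnorm(20, 4)), ncol = 1))
  y <- rep(c(0, 1), each = 20)
  m <- train_classifier("DLDA", x, y)
  mid <- (mean(x[1:20, 1]) + mean(x[21:40, 1])) / 2
  s <- predict_score(m, matrix(c(mid - 1e-7, mid + 1e-7), ncol = 1))
  expect_lt(s[1], 0.5)
  expect_gt(s[2], 0.5)
  # data built with exactly diagonal pooled covariance: LDA == DLDA
  mk <- function(seed, shift) {
    q <- withr::with_seed(seed, qr.Q(qr(scale(matrix(rnorm(60), 30, 2),
                                              scale = FALSE)))) * 3
    sweep(q, 2, shift, "+")
  }
  x2 <- rbind(mk(1, c(0, 0)), mk(2, c(1.5, 1)))
  y2 <- rep(c(0, 1), each = 30)
  lda <- train_classifier("LDA", x2, y2)
  dlda <- train_classifier("DLDA", x2, y2)
  expect_equal(unname(predict_score(lda, x2)),
               unname(predict_score(dlda, x2)), tolerance = 1e-8)
})

test_that("all five classifiers separate cleanly separated training data", {
  tab <- generate_feature_table(60, 5, 5, 8, seed = 62)
  for (kind in classifier_kinds()) {
    m <- train_classifier(kind, tab$values, tab$labels)
    sc <- predict_score(m, tab$values)
    expect_equal(binary_metrics(sc, tab$labels, m$threshold)[["auc"]], 1,
                 info = kind)
  }
})

test_that("binary metrics follow the rank/threshold definitions", {
  m <- binary_metrics(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
  expect_equal(unname(m), c(1, 1, 1, 1))
  # all-tie scores: AUC 0.5 by the tie convention
  expect_equal(binary_metrics(rep(0.4, 8),
                              rep(c(0, 1), 4))[["auc"]], 0.5)
  # monotone transform invariance of the AUC
  sc <- withr::with_seed(63, runif(30))
  y <- rep(c(0, 1), 15)
  a1 <- binary_metrics(sc, y)[["auc"]]
  a2 <- binary_metrics(qlogis(sc), y, threshold = 0)[["auc"]]
  expect_equal(a1, a2)
  # pCR is always the positive class regardless of label encoding
  lab <- c("pCR", "pCR", "non_pCR", "non_pCR")
  m2 <- binary_metrics(c(0.9, 0.1, 0.9, 0.1), lab)
  expect_equal(m2[["sensitivity"]], 0.5)
  expect_equal(m2[["specificity"]], 0.5)
  expect_error(binary_metrics(1:3, c(1, 1, 1)), "one class")
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  sc <- withr::with_seed(64, rnorm(50))
  y <- withr::with_seed(65, rbinom(50, 1, 0.4))
  ours <- binary_metrics(sc, y)[["auc"]]
  theirs <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("holdout evaluation matches resubstitution when train == test", {
  tab <- generate_feature_table(50, 8, 4, 1.5, seed = 66)
  hr <- evaluate_holdout(tab$values, tab$labels, tab$values, tab$labels,
                         1:8, "DLDA")
  m <- train_classifier("DLDA", tab$values, tab$labels)
  resub <- binary_metrics(predict_score(m, tab$values), tab$labels,
                          m$threshold)
  expect_equal(hr$auc, resub[["auc"]])
  expect_equal(hr$accuracy, resub[["accuracy"]])
  expect_error(
    evaluate_holdout(tab$values, tab$labels,
                     tab$values[, 1:3], tab$labels, c("F0001", "F0008"),
                     "DLDA"),
    "missing"
  )
})

test_that("sequential evaluation grows prefixes and improves with signal", {
  tab <- generate_feature_table(80, 12, 10, 0.9, seed = 67)
  ranked <- tab$informative
  seq_cv <- sequential_feature_eval(tab$values, tab$labels, ranked,
                                    "DLDA", mode = "cv", n_repeats = 5,
                                    seed = 2)
  expect_equal(nrow(seq_cv), 10)
  expect_equal(seq_cv$n_features_used, 1:10)
  # prefix 1 is definitionally a single-feature cross-validation
  single <- cross_validate(tab$values, tab$labels, ranked[1], "DLDA",
                           n_repeats = 5, seed = 2)
  expect_equal(seq_cv$auc[1], single$auc)
  # independent informative features: more of them helps
  expect_gt(seq_cv$auc[10], seq_cv$auc[1])
})

test_that("cross-validation reports mean and SD across repetitions", {
  tab <- generate_feature_table(60, 6, 3, 1.2, seed = 68)
  r <- cross_validate(tab$values, tab$labels, 1:6, "SVM",
                      n_repeats = 10, seed = 4)
  expect_true(all(c("auc", "auc_sd", "sensitivity", "specificity")
                  %in% names(r)))
  expect_gt(r$auc_sd, 0)
  expect_true(r$auc >= 0 && r$auc <= 1)
  # determinism under a fixed seed
  r2 <- cross_validate(tab$values, tab$labels, 1:6, "SVM",
                       n_repeats = 10, seed = 4)
  expect_equal(r, r2)
})
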