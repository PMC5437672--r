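#' The five response classifiers
#'
#' Trains one of the five standard classifiers used to validate the
#' discovered feature sets: linear discriminant analysis (LDA),
#' diagonal LDA (pooled diagonal covariance), quadratic discriminant
#' analysis (QDA), Gaussian naive Bayes (per-class variances) and a
#' linear support vector machine (C = 1).  Every fitted model exposes a
#' continuous score for the positive (pCR) class via
#' [predict_score()]: a posterior probability for the probabilistic
#' models (decision threshold 0.5) or a signed margin for the SVM
#' (threshold 0).  Class priors are the empirical frequencies.
#' Singular covariances fall back to a ridge-regularized discriminant
#' with a warning.
#'
#' @param kind one of `"LDA"`, `"DLDA"`, `"QDA"`, `"NaiveBayes"`,
#'   `"SVM"`.
#' @param x numeric matrix (samples x features).
#' @param y two-class labels (positive class `"pCR"` or `1`).
#' @return object of class `periradiomics_clf` with fields `kind`,
#'   `fit`, `threshold` and `positive`.
#' @export
train_classifier <- function(kind = c("LDA", "DLDA", "QDA", "NaiveBayes",
                                      "SVM"),
                             x, y) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  yb <- as_binary_labels(y)
  if (min(table(yb)) < 2L) stop("need at least 2 samples per class")
  yf <- factor(yb, levels = c(0L, 1L))
  fit <- switch(
    kind,
    LDA = tryCatch(MASS::lda(x, grouping = yf),
                   error = function(e) {
                     warning("singular covariance in LDA; ridge applied")
                     gaussian_discriminant(x, yb, pooled = TRUE,
                                           diagonal = FALSE)
                   }),
    DLDA = gaussian_discriminant(x, yb, pooled = TRUE, diagonal = TRUE),
    QDA = tryCatch(MASS::qda(x, grouping = yf),
                   error = function(e) {
                     warning("singular covariance in QDA; ridge applied")
                     gaussian_discriminant(x, yb, pooled = FALSE,
                                           diagonal = FALSE)
                   }),
    NaiveBayes = e1071::naiveBayes(x, yf),
    SVM = e1071::svm(x, yf, kernel = "linear", cost = 1, scale = FALSE)
  )
  structure(list(kind = kind, fit = fit,
                 threshold = if (kind == "SVM") 0 else 0.5,
                 positive = attr(yb, "positive")),
            class = "periradiomics_clf")
}

# Hand-rolled Gaussian discriminant used for DLDA (pooled diagonal
# covariance) and as a ridge fallback when MASS' LDA/QDA hit a singular
# covariance.  Pooled variances use the n - 2 denominator so that DLDA
# coincides with LDA when the pooled covariance happens to be diagonal.
gaussian_discriminant <- function(x, yb, pooled, diagonal) {
  n <- nrow(x)
  p <- ncol(x)
  cls <- c(0L, 1L)
  means <- lapply(cls, function(c) colMeans(x[yb == c, , drop = FALSE]))
  prior <- vapply(cls, function(c) mean(yb == c), 0)
  centered <- x - do.call(rbind, means[yb + 1L])
  if (pooled) {
    if (diagonal) {
      v <- colSums(centered^2) / (n - 2)
      v[v <= 0] <- max(v[v > 0], 1e-12) * 1e-8
      covs <- list(diag(v, p), diag(v, p))
    } else {
      s <- crossprod(centered) / (n - 2)
      s <- s + diag(mean(diag(s)) * 1e-6 + 1e-12, p)
      covs <- list(s, s)
    }
  } else {
    covs <- lapply(cls, function(c) {
      cc <- centered[yb == c, , drop = FALSE]
      s <- crossprod(cc) / max(1, nrow(cc) - 1)
      s + diag(mean(diag(s)) * 1e-3 + 1e-12, p)
    })
  }
  structure(list(means = means, covs = covs, prior = prior),
            class = "gaussian_discriminant")
}

log_mvnorm <- function(x, mu, sigma) {
  ch <- chol(sigma)
  z <- forwardsolve(t(ch), t(x) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - ncol(x) / 2 * log(2 * pi)
}

#' Continuous classification score for the positive class
#'
#' @param model a fitted `periradiomics_clf`.
#' @param newdata matrix of feature values.
#' @return numeric vector: posterior probability of the positive class,
#'   or the signed SVM margin (positive = positive class).
#' @export
predict_score <- function(model, newdata) {
  newdata <- as.matrix(newdata)
  fit <- model$fit
  if (inherits(fit, "gaussian_discriminant")) {
    l0 <- log_mvnorm(newdata, fit$means[[1]], fit$covs[[1]]) +
      log(fit$prior[1])
    l1 <- log_mvnorm(newdata, fit$means[[2]], fit$covs[[2]]) +
      log(fit$prior[2])
    return(1 / (1 + exp(l0 - l1)))
  }
  switch(
    model$kind,
    LDA = ,
    QDA = predict(fit, newdata)$posterior[, "1"],
    NaiveBayes = predict(fit, newdata, type = "raw")[, "1"],
    SVM = {
      pr <- predict(fit, newdata, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # e1071 labels the column "a/b": positive values favor class a
      if (startsWith(colnames(dv)[1], "1")) dv[, 1] else -dv[, 1]
    }
  )
}

#' Threshold-free and thresholded binary metrics
#'
#' AUC by the rank statistic (Mann-Whitney with half credit for ties),
#' plus accuracy, sensitivity (positive = pCR class) and specificity at
#' a fixed decision threshold.  The AUC is invariant under strictly
#' monotone transformations of the scores.
#'
#' @param scores continuous classifier scores, larger = more positive.
#' @param labels two-class labels.
#' @param threshold decision threshold applied to `scores` (0.5 for
#'   posteriors, 0 for margins).
#' @return named vector `auc`, `accuracy`, `sensitivity`,
#'   `specificity`.
#' @export
binary_metrics <- function(scores, labels, threshold = 0.5) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC undefined: one class absent")
  r <- rank(scores)
  auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred <- as.integer(scores >= threshold)
  c(auc = auc,
    accuracy = mean(pred == y),
    sensitivity = mean(pred[y == 1L] == 1L),
    specificity = mean(pred[y == 0L] == 0L))
}

#' Repeated stratified cross-validation of one classifier
#'
#' `n_repeats` repetitions of stratified `n_folds`-fold
#' cross-validation on a feature subset.  Out-of-fold scores are pooled
#' within each repetition, metrics computed once per repetition, and
#' summarized as mean and SD across repetitions.
#'
#' @param x feature matrix or `feature_table`.
#' @param labels two-class labels.
#' @param feature_subset column indices or names.
#' @param kind classifier kind (see [train_classifier()]).
#' @param n_repeats,n_folds repetition and fold counts.
#' @param seed integer RNG seed.
#' @return an `eval_report` row: data.frame with the four metric means,
#'   their SDs, `n_features_used`, `classifier` and `mode = "cv"`.
#' @export
cross_validate <- function(x, labels, feature_subset, kind,
                           n_repeats = 50, n_folds = 3, seed = 1L) {
  x <- feature_values(x)[, feature_subset, drop = FALSE]
  y <- as_binary_labels(labels)
  thr <- if (kind == "SVM") 0 else 0.5
  withr::with_seed(seed, {
    per_rep <- matrix(NA_real_, n_repeats, 4)
    for (rep in seq_len(n_repeats)) {
      folds <- make_stratified_folds(y, n_folds)
      tries <- 0L
      while (any(vapply(seq_len(n_folds), function(f) {
        min(table(y[folds != f])) < 2L || length(unique(y[folds != f])) < 2L
      }, TRUE)) && tries < 100L) {
        if (tries == 0L) warning("fold without both classes; refolding")
        folds <- make_stratified_folds(y, n_folds)
        tries <- tries + 1L
      }
      scores <- numeric(length(y))
      for (f in seq_len(n_folds)) {
        tr <- folds != f
        model <- train_classifier(kind, x[tr, , drop = FALSE], y[tr])
        scores[!tr] <- predict_score(model, x[!tr, , drop = FALSE])
      }
      per_rep[rep, ] <- binary_metrics(scores, y, thr)
    }
    eval_report(colMeans(per_rep), apply(per_rep, 2, sd),
                length(feature_subset), kind, "cv")
  })
}

eval_report <- function(means, sds, n_features, kind, mode) {
  data.frame(
    auc = means[1], accuracy = means[2], sensitivity = means[3],
    specificity = means[4],
    auc_sd = sds[1], accuracy_sd = sds[2], sensitivity_sd = sds[3],
    specificity_sd = sds[4],
    n_features_used = n_features, classifier = kind, mode = mode,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Holdout evaluation of one classifier
#'
#' Trains on the full training table and reports point metrics on an
#' independent test table.  The caller is responsible for normalizing
#' the test table against training statistics.
#'
#' @param train_x,train_labels training data.
#' @param test_x,test_labels holdout data.
#' @param feature_subset column indices or names present in both.
#' @param kind classifier kind.
#' @return an `eval_report` row with `mode = "holdout"` (SDs are NA).
#' @export
evaluate_holdout <- function(train_x, train_labels, test_x, test_labels,
                             feature_subset, kind) {
  train_x <- feature_values(train_x)
  test_x <- feature_values(test_x)
  if (is.character(feature_subset) &&
      !all(feature_subset %in% colnames(test_x))) {
    stop("feature subset missing from the test table")
  }
  model <- train_classifier(kind,
                            train_x[, feature_subset, drop = FALSE],
                            train_labels)
  sc <- predict_score(model, test_x[, feature_subset, drop = FALSE])
  m <- binary_metrics(sc, test_labels, model$threshold)
  eval_report(m, rep(NA_real_, 4), length(feature_subset), kind, "holdout")
}

#' Sequential top-1..top-k feature evaluation
#'
#' Re-evaluates a classifier while growing the feature set one ranked
#' feature at a time (top-1, top-2, ..., top-`min(10, length)`), either
#' by repeated cross-validation or on a holdout set.
#'
#' @param x,labels training data.
#' @param ranked_features ranked feature names or indices (best first).
#' @param kind classifier kind.
#' @param mode `"cv"` or `"holdout"`.
#' @param test_x,test_labels holdout data (required for
#'   `mode = "holdout"`).
#' @param max_prefix largest prefix evaluated (default 10).
#' @param ... passed to [cross_validate()].
#' @return data.frame of `eval_report` rows, one per prefix length.
#' @export
sequential_feature_eval <- function(x, labels, ranked_features, kind,
                                    mode = c("cv", "holdout"),
                                    test_x = NULL, test_labels = NULL,
                                    max_prefix = 10, ...) {
  mode <- match.arg(mode)
  ks <- seq_len(min(max_prefix, length(ranked_features)))
  out <- lapply(ks, function(k) {
    subset <- ranked_features[seq_len(k)]
    if (mode == "cv") {
      cross_validate(x, labels, subset, kind, ...)
    } else {
      evaluate_holdout(x, labels, test_x, test_labels, subset, kind)
    }
  })
  do.call(rbind, out)
}

#' Names of the five supported classifier kinds
#'
#' @return character vector of classifier identifiers.
#' @export
classifier_kinds <- function() c("LDA", "DLDA", "QDA", "NaiveBayes", "SVM")
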