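#' Configuration of the iterated mRMR discovery protocol
#'
#' @param n_select_per_run features picked by each mRMR run.
#' @param n_iterations cross-validation iterations per stage.
#' @param n_folds folds per iteration (stratified by class).
#' @param retain_fraction fraction of features kept after stage 1 (the
#'   bottom `1 - retain_fraction` by selection frequency is dropped).
#' @param redundancy_r_threshold absolute Pearson correlation above
#'   which a lower-ranked feature is considered redundant.
#' @param cap maximum size of the final feature set.
#' @param downsample_majority_to optional per-iteration downsampling of
#'   the majority class to this count (used for heavily imbalanced
#'   receptor groups).
#' @param n_bins quantile bins for the mutual-information estimates.
#' @param seed integer RNG seed.
#' @return object of class `discovery_config`.
#' @export
discovery_config <- function(n_select_per_run = 10, n_iterations = 200,
                             n_folds = 3, retain_fraction = 0.10,
                             redundancy_r_threshold = 0.90, cap = 10,
                             downsample_majority_to = NULL,
                             n_bins = 10, seed = 1L) {
  if (retain_fraction <= 0 || retain_fraction >= 1) {
    stop("retain_fraction must be in (0, 1)")
  }
  if (cap > n_select_per_run) stop("cap must not exceed n_select_per_run")
  structure(list(n_select_per_run = n_select_per_run,
                 n_iterations = n_iterations, n_folds = n_folds,
                 retain_fraction = retain_fraction,
                 redundancy_r_threshold = redundancy_r_threshold,
                 cap = cap, downsample_majority_to = downsample_majority_to,
                 n_bins = n_bins, seed = as.integer(seed)),
            class = "discovery_config")
}

#' Greedy mRMR feature ranking
#'
#' Minimum-redundancy maximum-relevance selection with the MID
#' (difference) criterion: the first feature maximizes mutual
#' information with the class labels; each subsequent feature maximizes
#' relevance minus mean redundancy against the already-selected set.
#' Mutual information is estimated on quantile-binned features.
#'
#' @param x numeric matrix (samples x features) or `feature_table`.
#' @param labels two-class labels.
#' @param k number of features to select.
#' @param n_bins quantile bins for discretization.
#' @return list with `order` (selected column indices, in selection
#'   order), `names` and `score` (criterion value at selection).
#' @export
mrmr_rank <- function(x, labels, k, n_bins = 10) {
  x <- feature_values(x)
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L) stop("labels contain a single class")
  if (min(table(y)) < 2L) stop("need at least 2 samples per class")
  res <- mrmr_rank_cpp(x, as.integer(y), as.integer(k), as.integer(n_bins))
  list(order = res$order,
       names = colnames(x)[res$order],
       score = res$score)
}

#' Greedy redundancy pruning
#'
#' Walks a ranked feature list top-down and drops any feature whose
#' absolute Pearson correlation with a higher-ranked kept feature
#' reaches the threshold.  Deterministic given the input order.
#'
#' @param ranked column indices (or names) in rank order.
#' @param x feature matrix or `feature_table` on which correlations are
#'   computed.
#' @param r_threshold absolute correlation threshold.
#' @return the pruned subset of `ranked`, order preserved.
#' @export
prune_redundant <- function(ranked, x, r_threshold = 0.90) {
  x <- feature_values(x)
  if (length(ranked) == 0L) stop("ranked feature list is empty")
  kept <- ranked[1]
  for (f in ranked[-1]) {
    r <- abs(stats::cor(x[, f], x[, kept, drop = FALSE]))
    r[is.na(r)] <- 0
    if (all(r < r_threshold)) kept <- c(kept, f)
  }
  kept
}

# One stage of cross-validated selection: counts how often each feature
# is selected over n_iterations x n_folds fold-training sets, with
# optional per-iteration majority downsampling.
selection_stage <- function(x, y, config) {
  p <- ncol(x)
  freq <- numeric(p)
  score_sum <- numeric(p)
  iteration_n <- integer(config$n_iterations)
  maj <- if (mean(y) > 0.5) 1L else 0L
  for (it in seq_len(config$n_iterations)) {
    idx <- seq_along(y)
    m <- config$downsample_majority_to
    if (!is.null(m) && sum(y == maj) > m) {
      keep_maj <- sample(which(y == maj), m)
      idx <- sort(c(which(y != maj), keep_maj))
    }
    iteration_n[it] <- length(idx)
    folds <- make_stratified_folds(y[idx], config$n_folds)
    for (f in seq_len(config$n_folds)) {
      tr <- idx[folds != f]
      sel <- mrmr_rank_cpp(x[tr, , drop = FALSE],
                           as.integer(y[tr]),
                           as.integer(min(config$n_select_per_run, p)),
                           as.integer(config$n_bins))
      freq[sel$order] <- freq[sel$order] + 1
      score_sum[sel$order] <- score_sum[sel$order] + sel$score
    }
  }
  list(freq = freq, score_sum = score_sum, iteration_n = iteration_n)
}

# Rank features by selection frequency; ties break by mean criterion
# score at selection, then lexicographic feature name.
rank_by_frequency <- function(freq, score_sum, names) {
  mean_score <- ifelse(freq > 0, score_sum / freq, -Inf)
  order(-freq, -mean_score, names)
}

#' Two-stage cross-validated mRMR feature discovery
#'
#' Stage 1 runs mRMR on every fold-training set of
#' `n_iterations x n_folds` stratified cross-validation splits, ranks
#' features by how often they were selected, and drops the bottom
#' `1 - retain_fraction` (for 1980 inputs at the default 10% this keeps
#' 198).  Stage 2 repeats the same cross-validated selection within the
#' retained set, ranks by frequency again, greedily removes features
#' correlated at `|r| >=` threshold with a higher-ranked survivor, and
#' truncates to at most `cap` features.
#'
#' @param x feature matrix or `feature_table` (training patients only).
#' @param labels two-class labels aligned with the rows.
#' @param config a [discovery_config()].
#' @return object of class `discovery_result`: `top_features` (names),
#'   `top_indices`, `stage1_retained` (names), `selection_frequency`
#'   (list of per-stage counts) and `truncated_below_cap` flag.
#' @export
discovery_protocol <- function(x, labels, config = discovery_config()) {
  xv <- feature_values(x)
  if (is.null(colnames(xv))) {
    colnames(xv) <- sprintf("F%04d", seq_len(ncol(xv)))
  }
  y <- as_binary_labels(labels)
  withr::with_seed(config$seed, {
    s1 <- selection_stage(xv, y, config)
    r1 <- rank_by_frequency(s1$freq, s1$score_sum, colnames(xv))
    n_keep <- ceiling(config$retain_fraction * ncol(xv))
    retained <- r1[seq_len(n_keep)]
    s2 <- selection_stage(xv[, retained, drop = FALSE], y, config)
    r2 <- rank_by_frequency(s2$freq, s2$score_sum, colnames(xv)[retained])
    ranked2 <- retained[r2]
    pruned <- prune_redundant(ranked2, xv, config$redundancy_r_threshold)
    top <- head(pruned, config$cap)
    structure(
      list(top_features = colnames(xv)[top],
           top_indices = top,
           stage1_retained = colnames(xv)[retained],
           stage1_retained_indices = retained,
           selection_frequency = list(
             stage1 = setNames(s1$freq, colnames(xv)),
             stage2 = setNames(s2$freq, colnames(xv)[retained])
           ),
           iteration_n = s1$iteration_n,
           truncated_below_cap = length(pruned) < config$cap),
      class = "discovery_result"
    )
  })
}

#' @export
print.discovery_result <- function(x, ...) {
  cat("<discovery_result>", length(x$top_features), "top features from",
      length(x$stage1_retained), "retained:\n")
  cat(paste0("  ", seq_along(x$top_features), ". ", x$top_features,
             collapse = "\n"), "\n")
  invisible(x)
}
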