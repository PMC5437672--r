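#' Consensus clustering configuration
#'
#' @param k number of clusters (the response analysis uses 2).
#' @param n_iterations subsampled clustering runs.
#' @param subsample_fraction fraction of patients drawn (without
#'   replacement) per run.
#' @param linkage agglomeration method for both the inner and the final
#'   hierarchical clustering.
#' @param seed integer RNG seed.
#' @return object of class `consensus_config`.
#' @export
consensus_config <- function(k = 2, n_iterations = 1000,
                             subsample_fraction = 0.80,
                             linkage = "average", seed = 1L) {
  if (subsample_fraction <= 0 || subsample_fraction > 1) {
    stop("subsample_fraction must be in (0, 1]")
  }
  if (k < 2) stop("k must be at least 2")
  structure(list(k = k, n_iterations = n_iterations,
                 subsample_fraction = subsample_fraction,
                 linkage = linkage, seed = as.integer(seed)),
            class = "consensus_config")
}

# 1 - Pearson correlation between patient feature vectors; undefined
# correlations (constant vectors) become distance 1.
pearson_distance <- function(x) {
  suppressWarnings(cc <- stats::cor(t(x)))
  if (anyNA(cc)) {
    warning("constant feature vectors: undefined correlations set to distance 1")
    cc[is.na(cc)] <- 0
  }
  stats::as.dist(1 - cc)
}

#' Subsampled hierarchical consensus clustering
#'
#' Repeatedly draws a patient subsample, clusters it hierarchically
#' with Pearson distance, cuts at `k`, and accumulates how often each
#' pair of patients lands in the same cluster.  The consensus for a
#' pair is its co-clustering count divided by its co-sampling count
#' (0 when never co-sampled).  The final assignment hierarchically
#' clusters `1 - consensus`.
#'
#' @param x numeric matrix (patients x selected features) or
#'   `feature_table`.
#' @param config a [consensus_config()].
#' @return object of class `consensus_matrix`: `consensus` (symmetric,
#'   unit diagonal), `cosample_counts`, `together_counts`,
#'   `final_assignment` (integer cluster per patient) and `config`.
#' @export
consensus_cluster <- function(x, config = consensus_config()) {
  x <- feature_values(x)
  n <- nrow(x)
  if (n < config$k + 1) stop("need at least k + 1 patients")
  m <- floor(config$subsample_fraction * n)
  withr::with_seed(config$seed, {
    together <- matrix(0, n, n)
    cosample <- matrix(0, n, n)
    for (it in seq_len(config$n_iterations)) {
      idx <- sort(sample.int(n, m))
      d <- pearson_distance(x[idx, , drop = FALSE])
      cl <- cutree(hclust(d, method = config$linkage), k = config$k)
      cosample[idx, idx] <- cosample[idx, idx] + 1
      together[idx, idx] <- together[idx, idx] +
        outer(cl, cl, "==")
    }
    consensus <- ifelse(cosample > 0, together / pmax(cosample, 1), 0)
    diag(consensus) <- 1
    final <- cutree(hclust(stats::as.dist(1 - consensus),
                           method = config$linkage), k = config$k)
    structure(
      list(consensus = consensus, cosample_counts = cosample,
           together_counts = together, final_assignment = final,
           config = config),
      class = "consensus_matrix"
    )
  })
}

#' @export
print.consensus_matrix <- function(x, ...) {
  cat("<consensus_matrix>", nrow(x$consensus), "patients,",
      x$config$n_iterations, "iterations, k =", x$config$k, "\n")
  print(table(cluster = x$final_assignment))
  invisible(x)
}

#' Per-class clustering accuracy against response labels
#'
#' Maps every cluster to its majority label and reports, for each true
#' class, the fraction of its patients that fall in a cluster whose
#' majority is that class.  Invariant to permutations of the cluster
#' ids.
#'
#' @param assignment integer cluster ids.
#' @param labels true class labels, aligned with `assignment`.
#' @return named numeric vector, one accuracy per class.
#' @export
cluster_label_accuracy <- function(assignment, labels) {
  labels <- as.character(labels)
  stopifnot(length(assignment) == length(labels))
  classes <- sort(unique(labels))
  majority <- vapply(sort(unique(assignment)), function(cl) {
    tab <- sort(table(labels[assignment == cl]), decreasing = TRUE)
    names(tab)[1]
  }, "")
  names(majority) <- sort(unique(assignment))
  correct <- majority[as.character(assignment)] == labels
  vapply(classes, function(cl) mean(correct[labels == cl]),
         0, USE.NAMES = TRUE)
}
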