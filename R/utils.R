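#' @useDynLib periradiomics, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor cutree hclust as.dist median quantile sd var
#'   predict optimize rnorm runif setNames aggregate
#' @importFrom utils head
NULL

#' 2D filtering with mirror-padded borders
#'
#' Correlates an image with a (possibly complex) kernel, reflecting the
#' image at its borders.  Small real kernels are evaluated directly in
#' compiled code; large or complex kernels go through an FFT path that
#' produces the same result to numerical precision.
#'
#' @param image numeric matrix.
#' @param kernel numeric or complex matrix with odd dimensions.
#' @return matrix of filter responses, same size as `image`.
#' @keywords internal
conv2_mirror <- function(image, kernel) {
  kr <- nrow(kernel)
  kc <- ncol(kernel)
  if (kr %% 2 == 0L || kc %% 2 == 0L) {
    stop("kernel dimensions must be odd")
  }
  if (kr > 2 * nrow(image) - 1 || kc > 2 * ncol(image) - 1) {
    stop("kernel too large for image")
  }
  if (is.complex(kernel) || kr * kc > 169L) {
    conv2_mirror_fft(image, kernel)
  } else {
    conv2_mirror_cpp(image, kernel)
  }
}

mirror_pad <- function(image, pr, pc) {
  nr <- nrow(image)
  nc <- ncol(image)
  ridx <- c(rev(seq_len(pr) + 1L), seq_len(nr), nr - seq_len(pr))
  cidx <- c(rev(seq_len(pc) + 1L), seq_len(nc), nc - seq_len(pc))
  image[ridx, cidx, drop = FALSE]
}

conv2_mirror_fft <- function(image, kernel) {
  nr <- nrow(image)
  nc <- ncol(image)
  hr <- nrow(kernel) %/% 2L
  hc <- ncol(kernel) %/% 2L
  padded <- mirror_pad(image, hr, hc)
  np_r <- nrow(padded) + nrow(kernel) - 1L
  np_c <- ncol(padded) + ncol(kernel) - 1L
  a <- matrix(0 + 0i, np_r, np_c)
  a[seq_len(nrow(padded)), seq_len(ncol(padded))] <- padded
  # correlation = convolution with the index-reversed kernel
  krev <- kernel[rev(seq_len(nrow(kernel))), rev(seq_len(ncol(kernel))),
                 drop = FALSE]
  b <- matrix(0 + 0i, np_r, np_c)
  b[seq_len(nrow(kernel)), seq_len(ncol(kernel))] <- krev
  full <- stats::fft(stats::fft(a) * stats::fft(b), inverse = TRUE) /
    (np_r * np_c)
  out <- full[nrow(kernel) + seq_len(nr) - 1L,
              ncol(kernel) + seq_len(nc) - 1L, drop = FALSE]
  if (is.complex(kernel)) out else Re(out)
}

#' First-order statistics of a set of values
#'
#' Computes the five summary statistics used to aggregate voxel-wise
#' descriptor maps into patient-level features: mean, median, standard
#' deviation (n - 1 denominator), moment skewness and non-excess moment
#' kurtosis.  A constant input has undefined standardized moments; both
#' are reported as 0 by convention and flagged via the `"degenerate"`
#' attribute.
#'
#' @param x numeric vector, non-empty.
#' @return named numeric vector `mean`, `median`, `sd`, `skewness`,
#'   `kurtosis`, with attribute `degenerate = TRUE` when `x` is constant.
#' @examples
#' aggregate_stats(c(1, 2, 3, 4, 5))
#' @export
aggregate_stats <- function(x) {
  if (length(x) == 0L) stop("empty region: no values to aggregate")
  if (anyNA(x)) stop("NA values in region")
  m <- mean(x)
  s2 <- stats::var(x)
  out <- c(mean = m, median = stats::median(x), sd = sqrt(s2),
           skewness = 0, kurtosis = 0)
  cm2 <- mean((x - m)^2)
  if (cm2 > 0) {
    out[["skewness"]] <- mean((x - m)^3) / cm2^1.5
    out[["kurtosis"]] <- mean((x - m)^4) / cm2^2
  } else {
    attr(out, "degenerate") <- TRUE
  }
  out
}

# Small memo cache for deterministic precomputations (filter banks and
# their FFTs), keyed by a string.
.pr_cache <- new.env(parent = emptyenv())

cache_get <- function(key, expr) {
  if (!exists(key, envir = .pr_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .pr_cache)
  }
  get(key, envir = .pr_cache, inherits = FALSE)
}

# Stratified fold assignment: permutes within each class and deals folds
# round-robin, so every fold holds both classes whenever n_class >= k.
make_stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Canonical binary labels: returns integer 0/1 with 1 = positive class.
# The positive class is "pCR" when present, otherwise the larger value of
# a 0/1 coding, otherwise the second factor level.
as_binary_labels <- function(labels, positive = NULL) {
  lab <- as.character(labels)
  u <- sort(unique(lab))
  if (length(u) > 2L) stop("more than two classes")
  if (is.null(positive)) {
    positive <- if ("pCR" %in% u) "pCR" else u[length(u)]
  }
  structure(as.integer(lab == positive), positive = positive)
}
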