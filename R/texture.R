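#' @title Voxel-wise texture descriptor maps
#' @description
#' The four texture families computed on each 2D slice of a contrast
#' phase: 25 Laws energy measures, 48 Gabor magnitude responses, 13
#' Haralick gray-level co-occurrence statistics and 13 CoLlAGe
#' (co-occurrence of local anisotropic gradient orientations)
#' statistics, for a total of 99 voxel-wise descriptor maps.  All maps
#' are computed in-plane with mirror-padded borders.
#' @name texture_maps
NULL

# The five classical 1D Laws kernels.  L sums to 16; the others sum to 0.
laws_kernels_1d <- function() {
  list(
    L5 = c(1, 4, 6, 4, 1),
    E5 = c(-1, -2, 0, 2, 1),
    S5 = c(-1, 0, 2, 0, -1),
    W5 = c(-1, 2, 0, -2, 1),
    R5 = c(1, -4, 6, -4, 1)
  )
}

#' The 13 co-occurrence statistic names
#'
#' Canonical order used for both the Haralick and the CoLlAGe families.
#' @return character vector of length 13.
#' @export
glcm_statistic_names <- function() {
  c("energy", "entropy", "contrast", "correlation", "variance",
    "inverse_difference_moment", "sum_average", "sum_variance",
    "sum_entropy", "difference_variance", "difference_entropy",
    "imc1", "imc2")
}

#' Laws texture energy maps
#'
#' Filters a slice with the 25 separable 5x5 Laws kernels, every ordered
#' pair (row kernel, column kernel) of level (L5), edge (E5), spot (S5),
#' wave (W5) and ripple (R5).  Borders are mirror padded.
#'
#' @param image numeric matrix (one slice), at least 5x5.
#' @return named list of 25 response maps, row-major in (row kernel,
#'   column kernel) order: `L5L5`, `L5E5`, ..., `R5R5`.
#' @export
laws_maps <- function(image) {
  if (nrow(image) < 5L || ncol(image) < 5L) {
    stop("slice smaller than the 5x5 Laws kernels")
  }
  k1 <- laws_kernels_1d()
  out <- vector("list", 25L)
  nm <- character(25L)
  i <- 0L
  for (a in names(k1)) {
    for (b in names(k1)) {
      i <- i + 1L
      out[[i]] <- conv2_mirror(image, outer(k1[[a]], k1[[b]]))
      nm[i] <- paste0(a, b)
    }
  }
  names(out) <- nm
  out
}

#' Gabor filter bank
#'
#' Builds the complex Gabor kernels for the bank of 6 frequencies and 8
#' orientations.  The frequency parameter `f` is interpreted as cycles
#' per reference window of `ref_width` pixels; the isotropic Gaussian
#' envelope has one-octave bandwidth (sigma proportional to the
#' wavelength).  `f = 0` has no oscillation and is implemented as the
#' normalized low-pass Gaussian envelope at the unit-frequency scale.
#' Kernels with `f > 0` are DC-corrected so a constant image gives zero
#' response.
#'
#' @param frequencies numeric vector of frequency parameters.
#' @param thetas orientations in degrees.  The default is the uniform
#'   22.5-degree grid 0..157.5; `gabor_theta_grid("printed")` gives the
#'   variant ending at 167.5.
#' @param ref_width reference window width in pixels that `f` counts
#'   cycles across.
#' @param max_halfwidth kernels are truncated at 2.5 sigma and capped at
#'   this half-width.
#' @return named list of complex kernel matrices, frequency-major.
#' @export
gabor_bank <- function(frequencies = c(0, 2, 4, 8, 16, 32),
                       thetas = gabor_theta_grid("uniform"),
                       ref_width = 64, max_halfwidth = 63) {
  bw_factor <- sqrt(log(2) / 2) / pi * 3  # one-octave bandwidth
  kernels <- list()
  for (f in frequencies) {
    lambda <- if (f > 0) ref_width / f else ref_width
    sigma <- bw_factor * lambda
    h <- min(max(2L, as.integer(ceiling(2.5 * sigma))), max_halfwidth)
    g <- seq(-h, h)
    env <- exp(-outer(g^2, g^2, "+") / (2 * sigma^2))
    for (th in thetas) {
      rad <- th * pi / 180
      if (f > 0) {
        # x along the orientation: row offsets are y, column offsets x
        phase <- 2 * pi * (f / ref_width) *
          (outer(g, rep(1, length(g))) * sin(rad) +
           outer(rep(1, length(g)), g) * cos(rad))
        ker <- env * exp(1i * phase)
        ker <- ker - env * (sum(Re(ker)) / sum(env))  # remove DC
      } else {
        ker <- env / sum(env)
      }
      kernels[[sprintf("f%g_th%g", f, th)]] <- ker
    }
  }
  kernels
}

#' @rdname gabor_bank
#' @param which `"uniform"` for the even 22.5-degree grid, `"printed"`
#'   for the variant whose last orientation is 167.5 degrees.
#' @export
gabor_theta_grid <- function(which = c("uniform", "printed")) {
  which <- match.arg(which)
  if (which == "uniform") {
    seq(0, 157.5, by = 22.5)
  } else {
    c(seq(0, 135, by = 22.5), 167.5)
  }
}

#' Gabor magnitude response maps
#'
#' Magnitude of the complex Gabor filter responses for the 48-filter
#' bank (or any bank from [gabor_bank()]).
#'
#' @param image numeric matrix (one slice).
#' @param bank optional precomputed kernel list; by default the standard
#'   bank capped so the kernels fit the slice.
#' @inheritParams gabor_bank
#' @return named list of response-magnitude maps, frequency-major.
#' @export
gabor_maps <- function(image, bank = NULL,
                       frequencies = c(0, 2, 4, 8, 16, 32),
                       thetas = gabor_theta_grid("uniform"),
                       ref_width = 64) {
  if (is.null(bank)) {
    cap <- min(nrow(image), ncol(image)) - 1L
    key <- paste("bank", paste(frequencies, collapse = ","),
                 paste(thetas, collapse = ","), ref_width, cap, sep = "|")
    bank <- cache_get(key, gabor_bank(frequencies, thetas, ref_width,
                                      max_halfwidth = cap))
  }
  out <- vector("list", length(bank))
  names(out) <- names(bank)
  sizes <- vapply(bank, nrow, 0L)
  nr <- nrow(image)
  nc <- ncol(image)
  for (sz in unique(sizes)) {
    members <- which(sizes == sz)
    h <- sz %/% 2L
    padded <- mirror_pad(image, h, h)
    np_r <- stats::nextn(nrow(padded) + sz - 1L, c(2, 3, 5))
    np_c <- stats::nextn(ncol(padded) + sz - 1L, c(2, 3, 5))
    a <- matrix(0 + 0i, np_r, np_c)
    a[seq_len(nrow(padded)), seq_len(ncol(padded))] <- padded
    fa <- stats::fft(a)
    for (m in members) {
      kname <- names(bank)[m]
      fkey <- paste("fk", kname, sz, np_r, np_c, ref_width, sep = "|")
      fk <- cache_get(fkey, {
        k <- bank[[m]]
        krev <- k[rev(seq_len(sz)), rev(seq_len(sz)), drop = FALSE]
        b <- matrix(0 + 0i, np_r, np_c)
        b[seq_len(sz), seq_len(sz)] <- krev
        stats::fft(b)
      })
      full <- stats::fft(fa * fk, inverse = TRUE) / (np_r * np_c)
      resp <- full[sz + seq_len(nr) - 1L, sz + seq_len(nc) - 1L,
                   drop = FALSE]
      out[[m]] <- if (is.complex(bank[[m]])) Mod(resp) else Re(resp)
    }
  }
  out
}

# Min-max quantization to integer levels 0 .. n_levels - 1.  The range
# is taken from `range_values` (e.g. the voxels of tumor + ring on this
# slice) when given, otherwise from the whole slice.
quantize_image <- function(image, n_levels, range_values = NULL) {
  if (n_levels < 2L) stop("n_gray_levels must be >= 2")
  v <- if (is.null(range_values)) image else range_values
  lo <- min(v)
  hi <- max(v)
  if (hi <= lo) {
    return(matrix(0L, nrow(image), ncol(image)))
  }
  q <- floor((image - lo) / (hi - lo) * n_levels)
  q[q < 0] <- 0
  q[q >= n_levels] <- n_levels - 1L
  matrix(as.integer(q), nrow(image), ncol(image))
}

#' Windowed Haralick co-occurrence maps
#'
#' For every pixel, quantizes the slice to `n_gray_levels`, accumulates
#' a symmetric gray-level co-occurrence matrix over unit-offset pairs in
#' the selected directions within the pixel's `window` x `window`
#' neighborhood (mirror padded), normalizes it, and computes the 13
#' classical statistics.
#'
#' @param image numeric matrix (one slice).
#' @param n_gray_levels quantization bins (default 64).
#' @param window odd window size in pixels (default 5).
#' @param directions logical length-4 vector selecting the 0, 45, 90 and
#'   135 degree unit offsets.
#' @param quant_range optional numeric vector whose min/max define the
#'   quantization range (e.g. tumor + ring voxel values for the slice).
#' @return named list of 13 maps in [glcm_statistic_names()] order.
#' @export
haralick_maps <- function(image, n_gray_levels = 64, window = 5,
                          directions = c(TRUE, TRUE, TRUE, TRUE),
                          quant_range = NULL) {
  if (window %% 2 == 0L) stop("window must be odd")
  q <- quantize_image(image, n_gray_levels, quant_range)
  arr <- glcm_window_stats_cpp(q, as.integer(n_gray_levels),
                               as.integer(window), directions)
  setNames(lapply(seq_len(13), function(s) arr[, , s]),
           glcm_statistic_names())
}

# Central-difference gradients with mirror-padded borders (zero at the
# edges since the reflection is symmetric).
image_gradients <- function(image) {
  p <- mirror_pad(image, 1L, 1L)
  nr <- nrow(image)
  nc <- ncol(image)
  gx <- (p[1 + seq_len(nr), 2 + seq_len(nc)] -
           p[1 + seq_len(nr), seq_len(nc)]) / 2
  gy <- (p[2 + seq_len(nr), 1 + seq_len(nc)] -
           p[seq_len(nr), 1 + seq_len(nc)]) / 2
  list(gx = gx, gy = gy)
}

#' CoLlAGe maps: co-occurrence of local anisotropic gradient orientations
#'
#' Per pixel: (1) image gradients by central differences; (2) the
#' dominant gradient orientation of each pixel as the principal singular
#' vector of the gradient samples in its own window; (3) orientations
#' quantized into `n_orientation_bins` over `[0, pi)`; (4) a symmetric
#' co-occurrence matrix of binned orientations over unit offsets within
#' the window; (5) the 13 Haralick statistics of that matrix.  Pixels
#' whose gradient window is identically zero take orientation bin 0.
#'
#' @param image numeric matrix (one slice).
#' @param n_orientation_bins orientation quantization bins (default 64).
#' @param window odd window size in pixels (default 5), used both for
#'   the dominant-orientation estimate and the co-occurrence window.
#' @param directions as in [haralick_maps()].
#' @return named list of 13 maps in [glcm_statistic_names()] order.
#' @export
collage_maps <- function(image, n_orientation_bins = 64, window = 5,
                         directions = c(TRUE, TRUE, TRUE, TRUE)) {
  if (window %% 2 == 0L) stop("window must be odd")
  g <- image_gradients(image)
  theta <- dominant_orientation_cpp(g$gx, g$gy, as.integer(window))
  q <- floor(theta / pi * n_orientation_bins)
  q[q >= n_orientation_bins] <- n_orientation_bins - 1L
  q <- matrix(as.integer(q), nrow(image), ncol(image))
  arr <- glcm_window_stats_cpp(q, as.integer(n_orientation_bins),
                               as.integer(window), directions)
  setNames(lapply(seq_len(13), function(s) arr[, , s]),
           glcm_statistic_names())
}

#' The full 99-descriptor texture bank
#'
#' Computes all four families on one slice with a stable map ordering:
#' Laws (25, row-major), Gabor (48, frequency-major), Haralick (13),
#' CoLlAGe (13).
#'
#' @param image numeric matrix (one slice).
#' @param n_gray_levels Haralick quantization bins.
#' @param n_orientation_bins CoLlAGe orientation bins.
#' @param window co-occurrence window size.
#' @param quant_range optional values defining the Haralick quantization
#'   range (tumor + ring voxels of the slice in the pipeline).
#' @param gabor_bank optional precomputed Gabor kernels.
#' @return object of class `texture_map_set`: list with `maps` (named
#'   list of 99 matrices) and `family` (factor aligned with `maps`).
#' @export
texture_bank <- function(image, n_gray_levels = 64, n_orientation_bins = 64,
                         window = 5, quant_range = NULL, gabor_bank = NULL) {
  fams <- list(
    Laws = laws_maps(image),
    Gabor = gabor_maps(image, bank = gabor_bank),
    Haralick = haralick_maps(image, n_gray_levels, window,
                             quant_range = quant_range),
    CoLlAGe = collage_maps(image, n_orientation_bins, window)
  )
  maps <- c(fams$Laws, fams$Gabor, fams$Haralick, fams$CoLlAGe)
  names(maps) <- unlist(lapply(names(fams), function(f) {
    paste(f, names(fams[[f]]), sep = "_")
  }))
  stopifnot(length(maps) == 99L, !anyDuplicated(names(maps)))
  structure(
    list(maps = maps,
         family = factor(rep(names(fams), vapply(fams, length, 0L)),
                         levels = names(fams))),
    class = "texture_map_set"
  )
}

#' @export
print.texture_map_set <- function(x, ...) {
  cat("<texture_map_set>", length(x$maps), "maps:",
      paste(sprintf("%s (%d)", levels(x$family), table(x$family)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Descriptor names of the 99-map texture bank
#'
#' Enumerates the canonical descriptor names without computing any maps.
#' @return data.frame with columns `family` and `descriptor`.
#' @export
texture_descriptor_table <- function() {
  k <- names(laws_kernels_1d())
  laws <- as.vector(t(outer(k, k, paste0)))
  gb <- as.vector(vapply(c(0, 2, 4, 8, 16, 32), function(f) {
    sprintf("f%g_th%g", f, gabor_theta_grid("uniform"))
  }, character(8)))
  data.frame(
    family = rep(c("Laws", "Gabor", "Haralick", "CoLlAGe"),
                 c(25L, 48L, 13L, 13L)),
    descriptor = c(laws, gb, glcm_statistic_names(), glcm_statistic_names()),
    stringsAsFactors = FALSE
  )
}
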