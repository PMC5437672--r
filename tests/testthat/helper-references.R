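# Independent naive reference implementations used as oracles.
# Everything here is written directly from the textbook definitions and
# shares no code with the package internals.

ref_pad_mirror <- function(img, h) {
  n <- nrow(img)
  m <- ncol(img)
  ri <- c((h + 1):2, 1:n, (n - 1):(n - h))
  ci <- c((h + 1):2, 1:m, (m - 1):(m - h))
  img[ri, ci, drop = FALSE]
}

ref_quantize <- function(img, nlev, lo = min(img), hi = max(img)) {
  if (hi <= lo) return(matrix(0L, nrow(img), ncol(img)))
  q <- floor((img - lo) / (hi - lo) * nlev)
  matrix(as.integer(pmin(pmax(q, 0), nlev - 1)), nrow(img), ncol(img))
}

# 13 Haralick statistics from a normalized symmetric co-occurrence
# matrix p (1-based level indexing, natural log).
ref_glcm_stats <- function(p) {
  n <- nrow(p)
  i <- row(p)
  j <- col(p)
  px <- rowSums(p)
  mu <- sum((1:n) * px)
  sig2 <- sum(((1:n) - mu)^2 * px)
  nz <- p > 0
  energy <- sum(p^2)
  entropy <- -sum(p[nz] * log(p[nz]))
  contrast <- sum((i - j)^2 * p)
  corr <- if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else 0
  vari <- sum((i - mu)^2 * p)
  idm <- sum(p / (1 + (i - j)^2))
  psum <- tapply(as.vector(p), as.vector(i + j), sum)
  ks <- as.numeric(names(psum))
  sum_avg <- sum(ks * psum)
  sum_var <- sum((ks - sum_avg)^2 * psum)
  pn <- psum[psum > 0]
  sum_ent <- -sum(pn * log(pn))
  pdiff <- tapply(as.vector(p), as.vector(abs(i - j)), sum)
  kd <- as.numeric(names(pdiff))
  dmu <- sum(kd * pdiff)
  diff_var <- sum((kd - dmu)^2 * pdiff)
  pdn <- pdiff[pdiff > 0]
  diff_ent <- -sum(pdn * log(pdn))
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  pxy <- outer(px, px)
  hxy1 <- -sum(p[nz] * log(pxy[nz]))
  hxy2 <- -sum(pxy[pxy > 0] * log(pxy[pxy > 0]))
  imc1 <- if (hx > 0) (entropy - hxy1) / hx else 0
  arg <- 1 - exp(-2 * (hxy2 - entropy))
  imc2 <- if (arg > 0) sqrt(arg) else 0
  c(energy = energy, entropy = entropy, contrast = contrast,
    correlation = corr, variance = vari,
    inverse_difference_moment = idm, sum_average = sum_avg,
    sum_variance = sum_var, sum_entropy = sum_ent,
    difference_variance = diff_var, difference_entropy = diff_ent,
    imc1 = imc1, imc2 = imc2)
}

# Symmetric co-occurrence matrix of a quantized window over unit
# offsets in the 4 standard directions (within-window pairs only).
ref_window_glcm <- function(win, nlev,
                            directions = c(TRUE, TRUE, TRUE, TRUE)) {
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))[directions]
  cnt <- matrix(0, nlev, nlev)
  w <- nrow(win)
  for (o in offs) {
    for (r in 1:w) {
      for (c in 1:w) {
        r2 <- r + o[1]
        c2 <- c + o[2]
        if (r2 >= 1 && r2 <= w && c2 >= 1 && c2 <= w) {
          a <- win[r, c] + 1L
          b <- win[r2, c2] + 1L
          cnt[a, b] <- cnt[a, b] + 1
          cnt[b, a] <- cnt[b, a] + 1
        }
      }
    }
  }
  cnt
}

# Naive double-loop windowed Haralick maps (13 x pixels).
ref_haralick_maps <- function(img, nlev, window = 5,
                              directions = c(TRUE, TRUE, TRUE, TRUE)) {
  q <- ref_quantize(img, nlev)
  h <- window %/% 2
  pad <- ref_pad_mirror(q, h)
  out <- array(0, c(nrow(img), ncol(img), 13))
  for (r in seq_len(nrow(img))) {
    for (c in seq_len(ncol(img))) {
      win <- pad[r:(r + window - 1), c:(c + window - 1)]
      cnt <- ref_window_glcm(win, nlev, directions)
      out[r, c, ] <- ref_glcm_stats(cnt / sum(cnt))
    }
  }
  out
}

# Naive CoLlAGe: central-difference gradients, dominant orientation by
# R's svd of the window's gradient sample matrix, binned into [0, pi),
# then windowed co-occurrence statistics of the binned orientations.
ref_collage_maps <- function(img, nbins = 64, window = 5) {
  h <- window %/% 2
  pad <- ref_pad_mirror(img, 1)
  n <- nrow(img)
  m <- ncol(img)
  gx <- (pad[1 + 1:n, 2 + 1:m] - pad[1 + 1:n, 1:m]) / 2
  gy <- (pad[2 + 1:n, 1 + 1:m] - pad[1:n, 1 + 1:m]) / 2
  gxp <- ref_pad_mirror(gx, h)
  gyp <- ref_pad_mirror(gy, h)
  theta <- matrix(0, n, m)
  for (r in 1:n) {
    for (c in 1:m) {
      mat <- cbind(as.vector(gxp[r:(r + window - 1), c:(c + window - 1)]),
                   as.vector(gyp[r:(r + window - 1), c:(c + window - 1)]))
      if (any(mat != 0)) {
        v <- svd(mat)$v[, 1]
        th <- atan2(v[2], v[1]) %% pi
        if (th >= pi) th <- th - pi
        theta[r, c] <- th
      }
    }
  }
  q <- matrix(as.integer(pmin(floor(theta / pi * nbins), nbins - 1)), n, m)
  padq <- ref_pad_mirror(q, h)
  out <- array(0, c(n, m, 13))
  for (r in 1:n) {
    for (c in 1:m) {
      win <- padq[r:(r + window - 1), c:(c + window - 1)]
      cnt <- ref_window_glcm(win, nbins)
      out[r, c, ] <- ref_glcm_stats(cnt / sum(cnt))
    }
  }
  out
}

# Tiny phantom configuration used to keep pipeline tests fast.
tiny_phantom <- function(...) {
  defaults <- list(seed = 1, grid_shape = c(5L, 28L, 28L),
                   pixel_spacing_mm = c(0.8, 0.8), slice_thickness_mm = 3,
                   tumor_radius_mm = 4.5, class_label = "pCR")
  do.call(phantom_config, utils::modifyList(defaults, list(...)))
}

# Two-class feature matrix with tight, well-separated clusters.
separated_groups <- function(n_per = 20, p = 10, sd = 0.2, seed = 5) {
  withr::with_seed(seed, {
    m1 <- rnorm(p, sd = 2)
    m2 <- -m1
    x <- rbind(
      matrix(rnorm(n_per * p, mean = rep(m1, each = n_per), sd = sd),
             n_per, p),
      matrix(rnorm(n_per * p, mean = rep(m2, each = n_per), sd = sd),
             n_per, p)
    )
    list(x = x, groups = rep(1:2, each = n_per))
  })
}
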