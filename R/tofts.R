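#' Population arterial input function
#'
#' Bi-exponential (Weinmann-type) plasma concentration curve
#' `Cp(t) = dose * (a1 exp(-m1 t) + a2 exp(-m2 t))` with the standard
#' published constants `a = (3.99, 4.78) kg/L` and
#' `m = (0.144, 0.0111) /min`, scaled by the injected dose in mmol/kg.
#' Used as the plasma driver of the Tofts model when no measured input
#' function is available.
#'
#' @param dose injected contrast dose in mmol/kg (default 0.1).
#' @param amplitudes,rates bi-exponential term parameters.
#' @return object of class `aif`: a list with the parameters and a
#'   vectorized concentration function `cp(t)` (mmol/L, 0 for `t < 0`).
#' @export
aif_biexponential <- function(dose = 0.1, amplitudes = c(3.99, 4.78),
                              rates = c(0.144, 0.0111)) {
  force(dose); force(amplitudes); force(rates)
  cp <- function(t) {
    out <- dose * (amplitudes[1] * exp(-rates[1] * t) +
                     amplitudes[2] * exp(-rates[2] * t))
    out[t < 0] <- 0
    out
  }
  structure(list(dose = dose, amplitudes = amplitudes, rates = rates,
                 cp = cp), class = "aif")
}

# Tissue response basis g(t; kep) = integral_0^t Cp(u) exp(-kep (t-u)) du
# for each kep (rows) at each requested time (columns), evaluated by
# trapezoidal quadrature on a fine internal grid via the standard
# exponential recursion.  The forward Tofts curve is ktrans * g.
tofts_basis <- function(times, keps, aif = aif_biexponential(), dt = 0.005) {
  tmax <- max(times)
  grid <- seq(0, tmax, by = dt)
  if (grid[length(grid)] < tmax) grid <- c(grid, tmax)
  cp <- aif$cp(grid)
  nk <- length(keps)
  g <- matrix(0, nk, length(grid))
  for (i in seq_along(grid)[-1]) {
    h <- grid[i] - grid[i - 1]
    dec <- exp(-keps * h)
    g[, i] <- g[, i - 1] * dec + h / 2 * (cp[i] + cp[i - 1] * dec)
  }
  idx <- vapply(times, function(tt) which.min(abs(grid - tt)), 0L)
  # exact landing on requested times (grid contains tmax; interior times
  # are multiples of dt up to rounding)
  out <- g[, idx, drop = FALSE]
  dimnames(out) <- NULL
  out
}

#' Forward Tofts model
#'
#' Tissue concentration
#' `C_t(t) = Ktrans * integral_0^t Cp(u) exp(-kep (t - u)) du`
#' evaluated by trapezoidal quadrature on a fine internal time grid.
#' The model is linear in `ktrans`; as `kep -> 0` it tends to the
#' cumulative integral of the input function scaled by `ktrans`.
#'
#' @param ktrans transfer constant, per minute, `>= 0`.
#' @param kep efflux rate, per minute, `>= 0`.
#' @param times acquisition times in minutes, sorted, non-negative.
#' @param aif arterial input function from [aif_biexponential()].
#' @param dt internal quadrature step in minutes.
#' @return numeric vector of tissue concentrations at `times`.
#' @export
tofts_forward <- function(ktrans, kep, times, aif = aif_biexponential(),
                          dt = 0.005) {
  if (ktrans < 0 || kep < 0) stop("PK parameters must be non-negative")
  if (is.unsorted(times) || any(times < 0)) {
    stop("times must be sorted and non-negative")
  }
  as.vector(ktrans * tofts_basis(times, kep, aif, dt))
}

#' Fit the Tofts model to one concentration curve
#'
#' Nonlinear least squares over `(ktrans, kep)` in the box `[0, 5]`/min.
#' The model is linear in `ktrans`, so the fit profiles it out: a coarse
#' multi-start grid over `kep` (with the conditionally optimal `ktrans`
#' in closed form) is refined by 1D optimization.  The extravascular
#' volume fraction is derived as `ve = ktrans / kep` and constrained to
#' `<= 1` (fits landing above it are re-solved on the `ve = 1`
#' boundary and flagged).
#'
#' @param curve tissue concentration values at `times`.
#' @param times acquisition times in minutes (same length as `curve`);
#'   at least 3 samples.
#' @param aif arterial input function.
#' @param bounds box constraint for both rates, per minute.
#' @param n_starts number of `kep` grid starts.
#' @param dt quadrature step.
#' @return list with `ktrans`, `kep`, `ve`, `sse` and `flag`
#'   (`"ok"`, `"flat"` for an all-zero curve, `"ve_constrained"`).
#' @export
fit_tofts <- function(curve, times, aif = aif_biexponential(),
                      bounds = c(0, 5), n_starts = 51, dt = 0.005) {
  if (length(curve) != length(times)) stop("curve/times length mismatch")
  if (length(curve) < 3L) stop("need at least 3 samples")
  if (any(!is.finite(curve))) stop("non-finite curve values")
  if (all(curve == 0)) {
    return(list(ktrans = 0, kep = 0, ve = 0, sse = 0, flag = "flat"))
  }
  sse_at <- function(kep, constrain_ve = FALSE) {
    g <- as.vector(tofts_basis(times, kep, aif, dt))
    gg <- sum(g * g)
    kt <- if (gg > 0) sum(curve * g) / gg else 0
    hi <- if (constrain_ve) min(bounds[2], kep) else bounds[2]
    kt <- min(max(kt, bounds[1]), hi)
    c(sse = sum((curve - kt * g)^2), ktrans = kt)
  }
  kgrid <- seq(bounds[1], bounds[2], length.out = n_starts)
  coarse <- vapply(kgrid, sse_at, c(0, 0))
  best <- which.min(coarse[1, ])
  lo <- kgrid[max(1L, best - 1L)]
  hi <- kgrid[min(n_starts, best + 1L)]
  opt <- stats::optimize(function(k) sse_at(k)[1], c(lo, hi),
                         tol = 1e-8)
  kep <- opt$minimum
  fit <- sse_at(kep)
  if (coarse[1, best] < fit[1]) {  # guard: keep the better point
    kep <- kgrid[best]
    fit <- sse_at(kep)
  }
  ktrans <- fit[2]
  flag <- "ok"
  if (kep > 0 && ktrans / kep > 1) {
    # re-solve on the ve = 1 boundary (kep = ktrans)
    optb <- stats::optimize(function(k) sse_at(k, constrain_ve = TRUE)[1],
                            bounds, tol = 1e-8)
    kep <- optb$minimum
    fitb <- sse_at(kep, constrain_ve = TRUE)
    ktrans <- fitb[2]
    fit <- fitb
    flag <- "ve_constrained"
  }
  ve <- if (kep > 0) ktrans / kep else 0
  list(ktrans = unname(ktrans), kep = unname(kep), ve = unname(ve),
       sse = unname(fit[1]), flag = flag)
}

#' Voxel-wise pharmacokinetic parameter maps
#'
#' Converts the multi-phase signal of every voxel in tumor-plus-ring to
#' relative enhancement `(S(t) - S0) / S0` as a concentration proxy and
#' fits the Tofts model per voxel, producing `ktrans`, `kep` and `ve`
#' maps.  The per-voxel fit profiles `ktrans` out over a shared fine
#' `kep` grid, which makes the whole-region fit a few matrix products.
#' Voxels with non-positive baseline signal are masked out with a
#' warning.
#'
#' @param series a `dce_series` (see [generate_phantom()]).
#' @param region a `region_pair` from [peritumoral_ring()].
#' @param aif arterial input function.
#' @param kep_grid `kep` candidates per minute.
#' @param dt quadrature step.
#' @return list of three arrays `ktrans`, `kep`, `ve` on the series
#'   grid (zero outside the region) plus the logical `region_mask` of
#'   voxels actually fitted.
#' @export
pk_maps <- function(series, region, aif = aif_biexponential(),
                    kep_grid = seq(0, 5, by = 0.01), dt = 0.005) {
  times <- series$times
  post <- which(times > times[1])
  if (length(post) < 3L) stop("need at least 3 postcontrast phases")
  mask <- region$tumor_mask | region$peritumoral_mask
  vox <- which(mask)
  dims <- dim(series$data)
  nvox_grid <- prod(dims[1:3])
  s0 <- series$data[vox]  # phase 1 = precontrast
  bad <- s0 <= 0
  if (any(bad)) {
    warning(sum(bad), " voxels with non-positive baseline masked out")
  }
  fitted <- vox[!bad]
  s0 <- s0[!bad]
  conc <- matrix(vapply(post, function(p) {
    series$data[fitted + (p - 1) * nvox_grid] / s0 - 1
  }, numeric(length(fitted))), nrow = length(fitted))  # voxels x phases
  g <- tofts_basis(times[post] - times[1], kep_grid, aif, dt)
  gg <- rowSums(g * g)                      # per kep
  num <- g %*% t(conc)                      # kep x voxels
  kt_hi <- pmin(5, kep_grid)                # ve <= 1 constraint
  kt <- pmin(pmax(num / ifelse(gg > 0, gg, 1), 0), kt_hi)
  sse <- matrix(colSums(t(conc)^2), nrow(kt), ncol(kt), byrow = TRUE) -
    2 * kt * num + kt^2 * gg
  pick <- max.col(-t(sse), ties.method = "first")
  kep_v <- kep_grid[pick]
  kt_v <- kt[cbind(pick, seq_along(fitted))]
  ve_v <- ifelse(kep_v > 0, kt_v / kep_v, 0)
  out <- lapply(list(ktrans = kt_v, kep = kep_v, ve = ve_v), function(v) {
    a <- array(0, dims[1:3])
    a[fitted] <- v
    a
  })
  fitted_mask <- array(FALSE, dims[1:3])
  fitted_mask[fitted] <- TRUE
  c(out, list(region_mask = fitted_mask))
}
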