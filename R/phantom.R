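#' Digital phantom configuration
#'
#' Describes one synthetic DCE-MRI patient: a lobulated ellipsoidal
#' tumor on a 3D grid, imaged at one precontrast and five postcontrast
#' phases (t = 2, 3.5, 5, 6.5 and 8 min by default), with
#' class-dependent Tofts enhancement kinetics and class-linked texture
#' effects.  Responders (pCR) enhance less aggressively with ordered
#' gradients and a quiet peritumoral rim; non-responders carry stronger
#' peritumoral speckle, more disordered enhancement gradients and more
#' heterogeneous intratumoral enhancement.
#'
#' @param seed integer RNG seed; the phantom is a deterministic function
#'   of its configuration.
#' @param grid_shape voxel grid as (z, y, x).
#' @param pixel_spacing_mm in-plane (row, col) spacing, cohort range
#'   0.5--1.0 mm.
#' @param slice_thickness_mm slice spacing in mm.
#' @param phase_times_min acquisition times, first entry precontrast
#'   (t = 0), strictly increasing.
#' @param tumor_radius_mm nominal tumor radius in mm.
#' @param lobulation relative amplitude of the in-plane boundary
#'   lobulation (0 = ellipsoid).
#' @param class_label `"pCR"` or `"non_pCR"`.
#' @param texture_effect list with `peritumoral_speckle_amplitude`,
#'   `gradient_disorder` (in `[0, 1]`) and `enhancement_heterogeneity`
#'   (`>= 0`); `NULL` selects class-dependent defaults.
#' @param pk list with `ktrans` and `kep` (per minute) for the tumor
#'   enhancement curve; `NULL` selects class-dependent defaults.
#' @param ring_uptake_fraction peritumoral `ktrans` as a fraction of the
#'   tumor `ktrans`.
#' @param s0 baseline (precontrast) signal level, arbitrary units.
#' @param noise_sd additive Gaussian signal noise, same units as `s0`.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(seed = 1L,
                           grid_shape = c(7L, 40L, 40L),
                           pixel_spacing_mm = c(0.8, 0.8),
                           slice_thickness_mm = 3,
                           phase_times_min = c(0, 2, 3.5, 5, 6.5, 8),
                           tumor_radius_mm = 6,
                           lobulation = 0.15,
                           class_label = c("pCR", "non_pCR"),
                           texture_effect = NULL,
                           pk = NULL,
                           ring_uptake_fraction = 0.3,
                           s0 = 100,
                           noise_sd = 0.5) {
  class_label <- match.arg(class_label)
  if (is.null(texture_effect)) {
    texture_effect <- if (class_label == "pCR") {
      list(peritumoral_speckle_amplitude = 0.08,
           gradient_disorder = 0.15,
           enhancement_heterogeneity = 0.10)
    } else {
      list(peritumoral_speckle_amplitude = 0.35,
           gradient_disorder = 0.65,
           enhancement_heterogeneity = 0.35)
    }
  }
  if (is.null(pk)) {
    pk <- if (class_label == "pCR") {
      list(ktrans = 0.25, kep = 0.6)
    } else {
      list(ktrans = 0.4, kep = 0.9)
    }
  }
  cfg <- list(seed = as.integer(seed), grid_shape = as.integer(grid_shape),
              pixel_spacing_mm = rep(pixel_spacing_mm, length.out = 2L),
              slice_thickness_mm = slice_thickness_mm,
              phase_times_min = phase_times_min,
              tumor_radius_mm = tumor_radius_mm, lobulation = lobulation,
              class_label = class_label, texture_effect = texture_effect,
              pk = pk, ring_uptake_fraction = ring_uptake_fraction,
              s0 = s0, noise_sd = noise_sd)
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  t <- cfg$phase_times_min
  if (length(t) < 2L || any(diff(t) <= 0)) {
    stop("phase times must be strictly increasing")
  }
  if (t[1] != 0) stop("first phase must be the precontrast time 0")
  if (any(cfg$pixel_spacing_mm <= 0) || cfg$slice_thickness_mm <= 0) {
    stop("spacings must be positive")
  }
  te <- cfg$texture_effect
  if (te$gradient_disorder < 0 || te$gradient_disorder > 1) {
    stop("gradient_disorder must be in [0, 1]")
  }
  if (te$peritumoral_speckle_amplitude < 0 ||
      te$enhancement_heterogeneity < 0) {
    stop("texture effect amplitudes must be non-negative")
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  r <- cfg$tumor_radius_mm * (1 + cfg$lobulation)
  half_mm <- (cfg$grid_shape - 1) / 2 *
    c(cfg$slice_thickness_mm, cfg$pixel_spacing_mm)
  if (cfg$tumor_radius_mm > half_mm[1] || any(r > half_mm[2:3])) {
    stop("tumor larger than grid")
  }
  invisible(cfg)
}

# Tumor mask and normalized ellipsoid coordinate rho (0 center, 1 at the
# lobulated boundary).
phantom_geometry <- function(cfg) {
  d <- cfg$grid_shape
  cz <- (d[1] + 1) / 2
  cy <- (d[2] + 1) / 2
  cx <- (d[3] + 1) / 2
  z_mm <- (seq_len(d[1]) - cz) * cfg$slice_thickness_mm
  y_mm <- (seq_len(d[2]) - cy) * cfg$pixel_spacing_mm[1]
  x_mm <- (seq_len(d[3]) - cx) * cfg$pixel_spacing_mm[2]
  zz <- array(rep(z_mm, times = d[2] * d[3]), d)
  yy <- array(rep(rep(y_mm, each = d[1]), times = d[3]), d)
  xx <- array(rep(x_mm, each = d[1] * d[2]), d)
  phi <- atan2(yy, xx)
  r_eff <- cfg$tumor_radius_mm * (1 + cfg$lobulation * cos(3 * phi))
  rho <- sqrt((zz / cfg$tumor_radius_mm)^2 + (xx^2 + yy^2) / r_eff^2)
  list(mask = rho <= 1, rho = pmin(rho, 1))
}

#' Generate one DCE-MRI phantom
#'
#' Simulates the multi-phase series and tumor mask described by a
#' [phantom_config()].  Tumor voxels follow the Tofts forward curve for
#' the class kinetics, spatially modulated by an enhancement pattern
#' that interpolates between an ordered radial gradient and a smoothed
#' random field (`gradient_disorder`) with overall amplitude
#' `enhancement_heterogeneity`.  Ring voxels follow a weaker uptake
#' curve with multiplicative high-frequency speckle.  Background stays
#' at baseline.  Output is a deterministic function of the
#' configuration (including its seed).
#'
#' @param config a [phantom_config()].
#' @return list with `series` (class `dce_series`: `data` array of
#'   dimension (z, y, x, phase), `times`, `pixel_spacing_mm`,
#'   `slice_thickness_mm`), `tumor_mask` (logical (z, y, x) array) and
#'   `config`.
#' @export
generate_phantom <- function(config) {
  validate_phantom_config(config)
  withr::with_seed(config$seed, generate_phantom_impl(config))
}

generate_phantom_impl <- function(cfg) {
  geo <- phantom_geometry(cfg)
  mask <- geo$mask
  region <- peritumoral_ring(mask, cfg$pixel_spacing_mm)
  ring <- region$peritumoral_mask
  d <- cfg$grid_shape
  te <- cfg$texture_effect

  # Fixed draw order so that identical seeds give aligned random fields
  # regardless of amplitude settings (monotonicity in the amplitudes).
  raw_field <- array(rnorm(prod(d)), d)
  speckle_z <- rnorm(sum(ring))

  # smoothed in-plane random field for the disordered gradient component
  gk <- outer(stats::dnorm(-3:3, sd = 1.5), stats::dnorm(-3:3, sd = 1.5))
  gk <- gk / sum(gk)
  smooth_field <- raw_field
  for (z in seq_len(d[1])) {
    smooth_field[z, , ] <- conv2_mirror(raw_field[z, , ], gk)
  }
  tv <- smooth_field[mask]
  if (length(tv) > 1L && sd(tv) > 0) {
    smooth_field <- (smooth_field - mean(tv)) / sd(tv)
  }

  dis <- te$gradient_disorder
  pattern <- (1 - dis) * (2 * geo$rho - 1) + dis * smooth_field
  mod_tumor <- 1 + te$enhancement_heterogeneity * pattern

  times <- cfg$phase_times_min
  ct_tumor <- tofts_forward(cfg$pk$ktrans, cfg$pk$kep, times)
  ct_ring <- tofts_forward(cfg$pk$ktrans * cfg$ring_uptake_fraction,
                           cfg$pk$kep, times)

  data <- array(cfg$s0, c(d, length(times)))
  enh <- array(0, d)
  enh[mask] <- mod_tumor[mask]
  ring_mod <- 1 + te$peritumoral_speckle_amplitude * speckle_z
  for (p in seq_along(times)) {
    vol <- array(cfg$s0, d)
    vol[mask] <- cfg$s0 * (1 + ct_tumor[p] * mod_tumor[mask])
    vol[ring] <- cfg$s0 * (1 + ct_ring[p] * ring_mod)
    data[, , , p] <- vol
  }
  if (cfg$noise_sd > 0) {
    data <- data + rnorm(length(data), sd = cfg$noise_sd)
  }
  series <- structure(
    list(data = data, times = times,
         pixel_spacing_mm = cfg$pixel_spacing_mm,
         slice_thickness_mm = cfg$slice_thickness_mm),
    class = "dce_series"
  )
  list(series = series, tumor_mask = mask, config = cfg)
}

#' @export
print.dce_series <- function(x, ...) {
  d <- dim(x$data)
  cat("<dce_series>", paste(d[1:3], collapse = " x "), "voxels,",
      d[4], "phases at t =", paste(x$times, collapse = ", "), "min\n")
  invisible(x)
}

#' Cohort specification
#'
#' @param n_pcr,n_non_pcr class sizes.
#' @param group receptor group label attached to every patient.
#' @param seed integer; patient i is generated with seed `seed + i`.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pcr, n_non_pcr,
                        group = c("all", "HR+HER2-", "TN/HER2+"),
                        seed = 1L) {
  group <- match.arg(group)
  if (n_pcr < 0 || n_non_pcr < 0) stop("counts must be non-negative")
  structure(list(n_pcr = as.integer(n_pcr),
                 n_non_pcr = as.integer(n_non_pcr),
                 group = group, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a phantom cohort
#'
#' One phantom per patient, pCR patients first, each built from the
#' default configuration with the class label and a per-patient seed
#' `spec$seed + i`.
#'
#' @param spec a [cohort_spec()].
#' @param phantom_defaults a [phantom_config()] serving as the template;
#'   its `seed` and `class_label` are overridden per patient.
#' @return list of patients, each a list with `series`, `tumor_mask`,
#'   `label`, `group`, `patient_id`.
#' @export
generate_cohort <- function(spec, phantom_defaults = phantom_config()) {
  labels <- c(rep("pCR", spec$n_pcr), rep("non_pCR", spec$n_non_pcr))
  lapply(seq_along(labels), function(i) {
    cfg <- phantom_defaults
    cfg$seed <- spec$seed + i
    cfg$class_label <- labels[i]
    # class-linked defaults follow the label unless explicitly pinned
    tmpl <- phantom_config(seed = cfg$seed, class_label = labels[i])
    if (identical(phantom_defaults$texture_effect,
                  phantom_config(class_label =
                                   phantom_defaults$class_label)$texture_effect)) {
      cfg$texture_effect <- tmpl$texture_effect
    }
    if (identical(phantom_defaults$pk,
                  phantom_config(class_label =
                                   phantom_defaults$class_label)$pk)) {
      cfg$pk <- tmpl$pk
    }
    ph <- generate_phantom(cfg)
    list(series = ph$series, tumor_mask = ph$tumor_mask,
         label = labels[i], group = spec$group,
         patient_id = sprintf("%s_%03d", gsub("[^A-Za-z0-9]+", "", spec$group), i))
  })
}

#' Synthetic feature table with planted class effects
#'
#' Builds an `n_samples x n_features` Gaussian feature matrix in which
#' `n_informative` randomly placed columns differ between the two
#' classes by `effect_size` standard deviations; all other columns are
#' pure noise.  Used to test feature discovery and classification with
#' known ground truth.
#'
#' @param n_samples number of rows (patients).
#' @param n_features number of columns.
#' @param n_informative number of class-linked columns,
#'   `<= n_features`.
#' @param effect_size standardized mean difference (Cohen's d) of the
#'   informative columns.
#' @param seed integer RNG seed.
#' @param class_balance fraction of positive-class samples.
#' @return list with `values` (matrix with columns `F0001`, ...),
#'   `labels` (integer 0/1, 1 = positive class) and `informative`
#'   (ground-truth column indices).
#' @export
generate_feature_table <- function(n_samples, n_features, n_informative,
                                   effect_size, seed = 1L,
                                   class_balance = 0.5) {
  if (n_informative > n_features) {
    stop("n_informative must not exceed n_features")
  }
  withr::with_seed(seed, {
    n_pos <- round(n_samples * class_balance)
    labels <- c(rep(1L, n_pos), rep(0L, n_samples - n_pos))
    x <- matrix(rnorm(n_samples * n_features), n_samples, n_features)
    informative <- sort(sample.int(n_features, n_informative))
    x[labels == 1L, informative] <- x[labels == 1L, informative] +
      effect_size
    colnames(x) <- sprintf("F%04d", seq_len(n_features))
    list(values = x, labels = labels, informative = informative)
  })
}
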