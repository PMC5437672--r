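#' Canonical feature identifiers
#'
#' Enumerates the 1980 radiomic feature ids (99 descriptors x 2 regions
#' x 2 phases x 5 first-order statistics) followed by the 15
#' pharmacokinetic ids (3 Tofts parameters x 5 statistics, computed
#' region-level over tumor + ring).  Order is region-major, then phase,
#' then descriptor (Laws, Gabor, Haralick, CoLlAGe), then statistic;
#' the PK block comes last.
#'
#' @return data.frame with columns `name`, `family`, `descriptor`,
#'   `region`, `phase`, `statistic`; 1995 rows.
#' @export
feature_ids <- function() {
  desc <- texture_descriptor_table()
  stats <- c("mean", "median", "sd", "skewness", "kurtosis")
  regions <- c("intratumoral", "peritumoral")
  phases <- c("initial", "peak")
  rad <- expand.grid(statistic = stats, di = seq_len(nrow(desc)),
                     phase = phases, region = regions,
                     stringsAsFactors = FALSE)
  rad <- data.frame(
    family = desc$family[rad$di],
    descriptor = desc$descriptor[rad$di],
    region = rad$region, phase = rad$phase, statistic = rad$statistic,
    stringsAsFactors = FALSE
  )
  pk <- expand.grid(statistic = stats, descriptor = c("ktrans", "kep", "ve"),
                    stringsAsFactors = FALSE)
  pk <- data.frame(family = "PK", descriptor = pk$descriptor,
                   region = "tumor+ring", phase = "all",
                   statistic = pk$statistic, stringsAsFactors = FALSE)
  out <- rbind(rad, pk)
  out$name <- ifelse(
    out$family == "PK",
    paste("PK", out$descriptor, out$statistic, sep = "_"),
    paste(out$region, out$phase, out$family, out$descriptor,
          out$statistic, sep = "_")
  )
  rownames(out) <- NULL
  out[, c("name", "family", "descriptor", "region", "phase", "statistic")]
}

#' Select the initial and peak contrast phases
#'
#' The initial phase is the first postcontrast acquisition; the peak
#' phase is the postcontrast acquisition maximizing mean signal inside
#' the tumor mask.
#'
#' @param series a `dce_series`.
#' @param tumor_mask logical array on the series grid.
#' @return list with `initial` and `peak`, 1-based phase indices into
#'   the series (phase 1 is precontrast).
#' @export
select_phases <- function(series, tumor_mask) {
  nph <- dim(series$data)[4]
  if (nph < 3L) stop("need at least 2 postcontrast phases")
  post <- 2:nph
  means <- vapply(post, function(p) {
    mean(series$data[, , , p][tumor_mask > 0])
  }, 0)
  list(initial = post[1], peak = post[which.max(means)])
}

#' Extract the full feature vector of one patient
#'
#' Computes the 99 texture descriptor maps slice-wise at the initial
#' and peak phases, pools the voxel values of each map over the
#' intratumoral and peritumoral masks across slices, and summarizes
#' each (descriptor, region, phase) with the five first-order
#' statistics; appends the 15 PK statistics from the Tofts parameter
#' maps.  Haralick quantization uses the min-max range of tumor + ring
#' voxels per slice.
#'
#' @param series a `dce_series`.
#' @param tumor_mask binary array on the series grid.
#' @param n_gray_levels,n_orientation_bins,window texture parameters
#'   (see [texture_bank()]).
#' @param pk logical; compute the PK block (set `FALSE` to skip the
#'   per-voxel fits when only radiomic features are needed).
#' @return named numeric vector aligned with [feature_ids()] (length
#'   1995, or 1980 without PK).
#' @export
extract_patient_features <- function(series, tumor_mask,
                                     n_gray_levels = 64,
                                     n_orientation_bins = 64,
                                     window = 5, pk = TRUE) {
  region <- peritumoral_ring(tumor_mask, series$pixel_spacing_mm)
  ph <- select_phases(series, tumor_mask)
  ids <- feature_ids()
  desc <- texture_descriptor_table()
  map_names <- paste(desc$family, desc$descriptor, sep = "_")
  stats5 <- c("mean", "median", "sd", "skewness", "kurtosis")
  union_mask <- region$tumor_mask | region$peritumoral_mask
  slices <- which(apply(union_mask, 1, any))
  vals <- numeric(0)
  for (reg_name in c("intratumoral", "peritumoral")) {
    reg_mask <- if (reg_name == "intratumoral") region$tumor_mask
                else region$peritumoral_mask
    for (ph_name in c("initial", "peak")) {
      p <- ph[[if (ph_name == "initial") "initial" else "peak"]]
      pooled <- vector("list", length(map_names))
      names(pooled) <- map_names
      for (z in slices) {
        sl <- series$data[z, , , p]
        rm_z <- reg_mask[z, , ]
        if (!any(rm_z)) next
        bank <- texture_bank(sl, n_gray_levels, n_orientation_bins, window,
                             quant_range = sl[union_mask[z, , ]])
        for (m in map_names) {
          pooled[[m]] <- c(pooled[[m]], bank$maps[[m]][rm_z])
        }
      }
      for (m in map_names) {
        vals <- c(vals, aggregate_stats(pooled[[m]]))
      }
    }
  }
  out <- vals
  if (pk) {
    pkm <- pk_maps(series, region)
    for (par in c("ktrans", "kep", "ve")) {
      out <- c(out, aggregate_stats(pkm[[par]][pkm$region_mask]))
    }
  }
  names(out) <- ids$name[seq_along(out)]
  out
}

#' Assemble a cohort feature table
#'
#' Runs [extract_patient_features()] for every patient of a cohort from
#' [generate_cohort()] and stacks the rows.
#'
#' @param cohort list of patients.
#' @param ... passed to [extract_patient_features()].
#' @return object of class `feature_table`: list with `values`
#'   (patients x features matrix), `ids` ([feature_ids()] rows for the
#'   columns) and `meta` (data.frame `patient_id`, `label`, `group`).
#' @export
build_feature_table <- function(cohort, ...) {
  rows <- lapply(cohort, function(p) {
    extract_patient_features(p$series, p$tumor_mask, ...)
  })
  values <- do.call(rbind, rows)
  if (anyNA(values)) stop("feature assembly produced missing values")
  ids <- feature_ids()
  ids <- ids[seq_len(ncol(values)), , drop = FALSE]
  meta <- data.frame(
    patient_id = vapply(cohort, `[[`, "", "patient_id"),
    label = vapply(cohort, `[[`, "", "label"),
    group = vapply(cohort, `[[`, "", "group"),
    stringsAsFactors = FALSE
  )
  rownames(values) <- meta$patient_id
  structure(list(values = values, ids = ids, meta = meta),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table>", nrow(x$values), "patients x", ncol(x$values),
      "features;", sum(x$meta$label == "pCR"), "pCR /",
      sum(x$meta$label != "pCR"), "non-pCR\n")
  invisible(x)
}

# Accept either a feature_table or a plain matrix.
feature_values <- function(x) {
  if (inherits(x, "feature_table")) x$values else as.matrix(x)
}

#' Normalize features to [-1, 1]
#'
#' Per-column affine map sending the reference minimum to -1 and the
#' reference maximum to +1.  By default the table is its own reference;
#' for holdout data pass the training table (or its stored
#' `normalization` attribute parameters) so that test statistics never
#' leak into the scaling.  Out-of-range values are clipped to
#' `[-1, 1]`; constant reference columns map to 0.
#'
#' @param table `feature_table` or numeric matrix.
#' @param reference `feature_table`, matrix, or a list with `lo`/`hi`
#'   per column (as stored in the `normalization` attribute of a
#'   previously normalized table).  `NULL` means self.
#' @return same type as `table`, values in `[-1, 1]`, with attribute
#'   `normalization = list(lo, hi)`.
#' @export
normalize_features <- function(table, reference = NULL) {
  x <- feature_values(table)
  if (is.null(reference)) {
    lo <- apply(x, 2, min)
    hi <- apply(x, 2, max)
  } else if (is.list(reference) && !inherits(reference, "feature_table") &&
             all(c("lo", "hi") %in% names(reference))) {
    lo <- reference$lo
    hi <- reference$hi
  } else {
    r <- feature_values(reference)
    if (ncol(r) != ncol(x)) stop("reference columns do not match")
    lo <- apply(r, 2, min)
    hi <- apply(r, 2, max)
  }
  rng <- hi - lo
  scaled <- sweep(x, 2, lo)
  scaled <- sweep(scaled, 2, ifelse(rng > 0, rng, 1), "/") * 2 - 1
  scaled[, rng <= 0] <- 0
  scaled[scaled > 1] <- 1
  scaled[scaled < -1] <- -1
  if (inherits(table, "feature_table")) {
    table$values <- scaled
    attr(table, "normalization") <- list(lo = lo, hi = hi)
    table
  } else {
    structure(scaled, normalization = list(lo = lo, hi = hi))
  }
}
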