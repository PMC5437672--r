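#' Write a phantom cohort to NIfTI files
#'
#' Stores each patient's multi-phase series as a 4D NIfTI volume and
#' the tumor mask as an integer NIfTI on the same grid, with a CSV
#' manifest (`patient_id`, `label`, `group`, paths).  Requires the
#' suggested RNifti package.
#'
#' @param cohort list of patients from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return path of the manifest CSV, invisibly.
#' @export
write_cohort_nifti <- function(cohort, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("write_cohort_nifti requires the RNifti package")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(p) {
    sp <- p$series$pixel_spacing_mm
    # store as (x, y, z, t) with the stated voxel dimensions
    arr <- aperm(p$series$data, c(3, 2, 1, 4))
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(sp[2], sp[1], p$series$slice_thickness_mm, 1)
    series_path <- file.path(dir, paste0(p$patient_id, "_dce.nii.gz"))
    mask_path <- file.path(dir, paste0(p$patient_id, "_mask.nii.gz"))
    RNifti::writeNifti(img, series_path)
    marr <- aperm(array(as.integer(p$tumor_mask), dim(p$tumor_mask)),
                  c(3, 2, 1))
    RNifti::writeNifti(RNifti::asNifti(marr), mask_path)
    data.frame(patient_id = p$patient_id, label = p$label,
               group = p$group, series = series_path, mask = mask_path,
               stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' Write a feature table to CSV
#'
#' Values with patient ids as row names, plus a JSON sidecar holding
#' the column annotation (family, descriptor, region, phase, statistic)
#' and patient metadata.
#'
#' @param table a `feature_table`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table$values, path, row.names = TRUE)
  jsonlite::write_json(list(ids = table$ids, meta = table$meta),
                       paste0(path, ".json"), dataframe = "columns")
  invisible(path)
}

#' Write a discovery result as JSON
#'
#' @param result a `discovery_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_discovery_json <- function(result, path) {
  jsonlite::write_json(
    list(top_features = result$top_features,
         stage1_retained = result$stage1_retained,
         selection_frequency = lapply(result$selection_frequency,
                                      function(f) as.list(f[f > 0]))),
    path, auto_unbox = TRUE
  )
  invisible(path)
}

#' Read a phantom configuration from YAML
#'
#' Reads a flat YAML mapping of [phantom_config()] arguments (unknown
#' keys are rejected).  Requires the suggested yaml package.
#'
#' @param path YAML file.
#' @return a `phantom_config`.
#' @export
read_phantom_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("read_phantom_config requires the yaml package")
  }
  args <- yaml::read_yaml(path)
  known <- names(formals(phantom_config))
  bad <- setdiff(names(args), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(phantom_config, args)
}
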