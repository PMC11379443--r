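# File interfaces: NIfTI-1 volumes (via RNifti), cohort tables as CSV,
# specifications as YAML, and JSON sidecars carrying GLM metadata.

#' Write a response map as NIfTI-1
#'
#' The voxel size is stored in the NIfTI header; degrees of freedom, space
#' tag and flip state go to a JSON sidecar next to the image.
#'
#' @param map a [response_map()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_response_map <- function(map, path) {
  stopifnot(inherits(map, "response_map"))
  img <- RNifti::asNifti(map$data)
  RNifti::pixdim(img) <- map$voxel_size
  RNifti::writeNifti(img, path)
  side <- list(dof = map$dof, space = map$space, flipped = map$flipped)
  jsonlite::write_json(side, sub("\\.nii(\\.gz)?$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a response map written by [write_response_map()]
#'
#' @param path NIfTI path.
#' @return a [response_map()].
#' @export
read_response_map <- function(path) {
  img <- RNifti::readNifti(path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  side <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  response_map(array(as.numeric(img), dim(img)),
               voxel_size = RNifti::pixdim(img)[1:3],
               space = side$space %||% "common",
               flipped = isTRUE(side$flipped),
               dof = as.numeric(side$dof %||% NA))
}

#' Write a BOLD series as 4-d NIfTI plus a motion text file
#'
#' @param series a [bold_series()].
#' @param path output NIfTI path; the motion trace goes to `<path>.motion.txt`
#'   (6 whitespace-separated columns).
#' @export
write_bold_series <- function(series, path) {
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(series$voxel_size, series$paradigm$tr)
  RNifti::writeNifti(img, path)
  utils::write.table(series$motion,
                     sub("\\.nii(\\.gz)?$", ".motion.txt", path),
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a whitespace- or comma-separated 6-column motion trace
#'
#' @param path text file path.
#' @return volumes x 6 matrix with standard column names.
#' @export
read_motion_trace <- function(path) {
  first <- readLines(path, n = 1)
  m <- as.matrix(utils::read.table(path,
                                   sep = if (grepl(",", first)) "," else ""))
  stopifnot(ncol(m) == 6)
  colnames(m) <- c("tx", "ty", "tz", "yaw", "pitch", "roll")
  unname(m)
  m
}

#' Write the cohort table as CSV
#'
#' One row per map: patient id, map id, the tested setting (voltage,
#' frequency, pulse width, contact x/y/z), and the optimal flag.
#'
#' @param dataset a [build_cohort_dataset()] result.
#' @param path CSV path.
#' @export
write_cohort_csv <- function(dataset, path) {
  cols <- c("patient_id", "map_id", "voltage", "frequency", "pulse_width",
            "x", "y", "z", "is_optimal")
  utils::write.csv(dataset$table[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Write / read a cohort specification as YAML
#'
#' @param spec a [cohort_spec()].
#' @param path YAML path.
#' @export
write_cohort_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path, precision = 15)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  do.call(cohort_spec, yaml::read_yaml(path))
}
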