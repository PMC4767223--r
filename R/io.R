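#' Write / read a simulated run as NIfTI
#'
#' The voxels x volumes signal matrix is stored as a 4-D NIfTI volume
#' (voxels along x, singleton y/z, time along the 4th dimension) with the TR
#' in the time-step header field. Requires the suggested `RNifti` package.
#'
#' @param run an `sd_run`.
#' @param path output `.nii` / `.nii.gz` path.
#' @return `write_run_nifti()`: `path`, invisibly. `read_run_nifti()`: a
#'   list with the voxels x volumes `signal` matrix and `tr`.
#' @export
write_run_nifti <- function(run, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    abort("the 'RNifti' package is required for NIfTI i/o",
          class = "surfdecode_missing_package")
  stopifnot(inherits(run, "sd_run"))
  arr <- array(run$signal,
               dim = c(nrow(run$signal), 1L, 1L, ncol(run$signal)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(1, 1, 1, run$tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_run_nifti
#' @export
read_run_nifti <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    abort("the 'RNifti' package is required for NIfTI i/o",
          class = "surfdecode_missing_package")
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4) abort("expected a 4-D NIfTI volume")
  list(signal = matrix(img, d[1], d[4]),
       tr = RNifti::pixdim(img)[4])
}

#' Write a block schedule to CSV
#'
#' @param schedule an `sd_schedule`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}

#' Read a block schedule from CSV
#'
#' @param path CSV path written by [write_schedule_csv()].
#' @param tr,n_dummy_volumes timing attributes to restore.
#' @return An `sd_schedule` tibble.
#' @export
read_schedule_csv <- function(path, tr = 2, n_dummy_volumes = 4) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("run_id", "block", "label", "onset", "n_vol")
  if (!all(need %in% names(d)))
    abort(paste0("schedule CSV must have columns: ",
                 paste(need, collapse = ", ")))
  out <- as_tibble(d[need])
  attr(out, "tr") <- tr
  attr(out, "n_dummy_volumes") <- as.integer(n_dummy_volumes)
  class(out) <- c("sd_schedule", class(out))
  out
}

#' Write extracted patterns or a QC report to CSV
#'
#' @param x an `sd_patterns` (written in the long tibble form of its
#'   `as_tibble()` method) or the QC report tibble from [exclude_runs()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_patterns_csv <- function(x, path) {
  stopifnot(inherits(x, "sd_patterns"))
  utils::write.csv(as.data.frame(as_tibble(x)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_patterns_csv
#' @export
write_qc_csv <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
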