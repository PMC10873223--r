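#' Write a 4D series, volume or mask as NIfTI-1
#'
#' @param x a [series4d()], 3D numeric array, or logical mask.
#' @param path output `.nii` or `.nii.gz` file.
#' @param voxel_size_mm voxel size for plain arrays (taken from the
#'   object for a `series4d`).
#' @param frame_interval_s time step stored in the 4th pixdim slot for
#'   4D data.
#' @return the path, invisibly.
#' @export
write_nifti_volume <- function(x, path, voxel_size_mm = c(1, 1, 1),
                               frame_interval_s = 1) {
  if (inherits(x, "series4d")) {
    arr <- x$data
    voxel_size_mm <- x$voxel_size_mm
    frame_interval_s <- if (length(x$times) > 1) diff(x$times)[1] else 1
  } else {
    arr <- x
  }
  if (is.logical(arr)) arr <- array(as.integer(arr), dim = dim(arr))
  img <- RNifti::asNifti(arr)
  pd <- if (length(dim(arr)) == 4L) c(voxel_size_mm, frame_interval_s)
        else voxel_size_mm
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file as a plain array with voxel size
#'
#' @param path NIfTI file.
#' @return list with `data` (array stripped of NIfTI attributes) and
#'   `voxel_size_mm`.
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  list(data = array(as.numeric(img), dim = dim(img)),
       voxel_size_mm = pd[seq_len(min(3L, length(pd)))])
}

#' Read a 4D NIfTI series
#'
#' @param path NIfTI file with a time axis.
#' @return a [series4d()]; frame times are reconstructed from the time
#'   step in `pixdim`.
#' @export
read_nifti_series <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stop("expected a 4D series")
  pd <- RNifti::pixdim(img)
  dt <- if (length(pd) >= 4L && pd[4] > 0) pd[4] else 1
  series4d(array(as.numeric(img), dim = d),
           times = (seq_len(d[4]) - 1) * dt,
           voxel_size_mm = pd[1:3])
}
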