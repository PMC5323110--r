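# Containers for single-subject data: a 4D BOLD series and its motion trace.

#' Construct a BOLD series object
#'
#' @param data 4D numeric array (x, y, z, t)
#' @param tr_s repetition time in seconds
#' @param voxel_size_mm isotropic voxel size in mm
#' @param mask logical 3D array of in-brain voxels
#' @param affine optional 4x4 voxel-to-world affine (defaults to a
#'   grid-centred diagonal affine)
#' @return a `bold_series` object
#' @export
bold_series <- function(data, tr_s, voxel_size_mm, mask, affine = NULL) {
  d <- dim(data)
  stopifnot(length(d) == 4, d[4] >= 2, tr_s > 0, voxel_size_mm > 0)
  stopifnot(identical(dim(mask), d[1:3]))
  if (!all(is.finite(data[rep_len(as.vector(mask), length(data))])))
    stop("BOLD values inside the mask must be finite")
  if (is.null(affine)) {
    affine <- diag(c(rep(voxel_size_mm, 3), 1))
    affine[1:3, 4] <- -voxel_size_mm * (d[1:3] - 1) / 2
  }
  structure(list(data = data, tr_s = tr_s, voxel_size_mm = voxel_size_mm,
                 mask = mask, affine = affine),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_series> %d x %d x %d grid, %d volumes, TR = %g s, %d mask voxels\n",
              d[1], d[2], d[3], d[4], x$tr_s, sum(x$mask)))
  invisible(x)
}

n_volumes <- function(series) dim(series$data)[4]

# time x voxel matrix view (full grid, column-major voxel order)
series_matrix <- function(series) {
  d <- dim(series$data)
  t(matrix(series$data, prod(d[1:3]), d[4]))
}

# rebuild a bold_series from a time x voxel matrix, preserving geometry
series_from_matrix <- function(series, Y) {
  d <- dim(series$data)
  d[4] <- nrow(Y)
  series$data <- array(t(Y), d)
  series
}

# Replace in-mask voxel time series only; out-of-mask voxels untouched.
replace_in_mask <- function(series, fun) {
  Y <- series_matrix(series)
  vox <- which(as.vector(series$mask))
  Y[, vox] <- fun(Y[, vox, drop = FALSE])
  series_from_matrix(series, Y)
}

#' Construct a motion trace
#'
#' @param params numeric matrix with t rows and 6 columns: three translations
#'   (mm) then three rotations (degrees)
#' @return a `motion_trace` object
#' @export
motion_trace <- function(params) {
  params <- as.matrix(params)
  stopifnot(ncol(params) == 6, nrow(params) >= 1, all(is.finite(params)))
  colnames(params) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  structure(list(params = params), class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %d volumes, max |trans| %.3f mm, max |rot| %.3f deg\n",
              nrow(x$params), max(abs(x$params[, 1:3])),
              max(abs(x$params[, 4:6]))))
  invisible(x)
}
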