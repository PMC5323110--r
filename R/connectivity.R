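# Seed-based whole-brain functional connectivity.
#
# Pipeline order for this branch: scrub -> smooth the data (8 mm FWHM) ->
# mean seed time course -> voxelwise Pearson correlation -> Fisher z.
# Correlation runs on the scrubbed series with flagged volumes deleted, and
# degrees of freedom for r-based inference use the retained volume count.

#' Smooth every volume of a BOLD series
#'
#' @param series a [bold_series()]
#' @param fwhm_mm Gaussian FWHM in mm
#' @return the smoothed [bold_series()] (in-mask smoothing per volume)
#' @export
smooth_series <- function(series, fwhm_mm = 8) {
  if (fwhm_mm == 0) return(series)
  d <- dim(series$data)
  for (v in seq_len(d[4]))
    series$data[, , , v] <- smooth_map(series$data[, , , v], fwhm_mm,
                                       series$voxel_size_mm, series$mask)
  series
}

#' Mean seed time course
#'
#' @param series a [bold_series()]
#' @param roi a [seed_roi()] or integer voxel indices, inside the mask
#' @return numeric vector, one value per volume
#' @export
seed_timeseries <- function(series, roi) {
  idx <- if (inherits(roi, "seed_roi")) roi$voxels else as.integer(roi)
  if (!length(idx)) stop("seed ROI is empty")
  if (!all(as.vector(series$mask)[idx]))
    stop("seed ROI extends outside the series mask")
  Y <- series_matrix(series)
  rowMeans(Y[, idx, drop = FALSE])
}

#' Voxelwise correlation with a reference time course
#'
#' Pearson r between every in-mask voxel and the reference series.
#' Zero-variance voxels are recorded as r = 0 and flagged.
#'
#' @param series a [bold_series()]
#' @param reference numeric vector of length t
#' @param mask logical 3D array (defaults to the series mask)
#' @return list with `r` (3D array of correlations, 0 outside mask),
#'   `flagged` (indices of zero-variance voxels) and `n_volumes`
#' @export
fc_map <- function(series, reference, mask = series$mask) {
  t <- n_volumes(series)
  stopifnot(length(reference) == t, t >= 10)
  Y <- series_matrix(series)
  vox <- which(as.vector(mask))
  Yc <- sweep(Y[, vox, drop = FALSE], 2, colMeans(Y[, vox, drop = FALSE]))
  rc <- reference - mean(reference)
  ss <- sqrt(colSums(Yc^2)) * sqrt(sum(rc^2))
  r <- as.vector(crossprod(Yc, rc))
  zero_var <- ss == 0
  r[!zero_var] <- r[!zero_var] / ss[!zero_var]
  r[zero_var] <- 0
  out <- array(0, dim(mask))
  out[vox] <- r
  list(r = out, flagged = vox[zero_var], n_volumes = t)
}

#' Fisher z transformation
#'
#' `z = atanh(r) = 0.5 ln((1 + r) / (1 - r))`. Values with `|r| >= 1` are
#' clamped to `1 - 1e-7` in magnitude with a warning.
#'
#' @param r correlation value(s); vector or array
#' @return transformed value(s), same shape
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    warning("|r| >= 1 clamped before Fisher z")
    r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
  }
  atanh(r)
}

#' Subject-level Fisher-z connectivity map
#'
#' Convenience wrapper: seed time course, voxelwise correlation, Fisher z.
#'
#' @param series a (scrubbed, smoothed) [bold_series()]
#' @param roi a [seed_roi()]
#' @param mask analysis mask
#' @return 3D array of Fisher-z correlations
#' @export
fc_zmap <- function(series, roi, mask = series$mask) {
  ref <- seed_timeseries(series, roi)
  fm <- fc_map(series, ref, mask)
  z <- fm$r
  z[mask] <- fisher_z(fm$r[mask])
  z
}

#' Positive-connectivity restriction mask
#'
#' Voxels whose group-mean connectivity is significantly positive in the
#' one-sample map; downstream group comparisons are restricted to this set
#' to avoid interpreting apparently negative connectivity induced by
#' global-signal correction.
#'
#' @param group_map result of [one_sample_map()]
#' @return logical 3D array
#' @export
positive_mask <- function(group_map) {
  m <- group_map$significant
  if (!any(m)) warning("positive-connectivity mask is empty")
  m
}
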