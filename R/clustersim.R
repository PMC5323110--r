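# Monte-Carlo estimation of the minimum cluster extent controlling the
# familywise error of suprathreshold clusters (AlphaSim-style).
#
# Each iteration fills the mask with unit white noise, smooths it with the
# nominal Gaussian FWHM, standardizes it back to unit variance, thresholds
# two-sided at the voxel-level p, and records the largest cluster formed
# per sign. The extent threshold is one voxel above the (1 - alpha)
# order-statistic quantile of the null maximum extents, so surviving
# clusters are strictly larger than the null quantile.
#
# Variance standardization is exact rather than empirical: with separable
# Gaussian smoothing of white noise, the per-voxel output variance is the
# product over dimensions of the sums of squared (edge-truncated) kernel
# weights, so dividing by its square root makes the voxelwise exceedance
# rate equal voxel_p in expectation everywhere, including at mask edges.

#' Estimate the cluster-extent threshold by Monte-Carlo simulation
#'
#' @param mask logical 3D array defining the search region
#' @param fwhm_mm smoothness applied to the null noise (mm)
#' @param voxel_size_mm isotropic voxel size (mm)
#' @param voxel_p two-sided voxel-level p threshold (0 < p < 0.5)
#' @param alpha target familywise (cluster-wise) alpha
#' @param n_iter number of iterations (>= 500)
#' @param seed RNG seed
#' @param connectivity cluster connectivity: 6, 18 or 26 (default)
#' @return a `cluster_sim` object: `extent_threshold_voxels`,
#'   `extent_threshold_mm3`, `null_max_extent_quantiles`, `n_iterations`,
#'   `realized_exceedance`, and the parameter set
#' @export
estimate_extent_threshold <- function(mask, fwhm_mm, voxel_size_mm = 3,
                                      voxel_p = 0.005, alpha = 0.05,
                                      n_iter = 1000, seed = 1,
                                      connectivity = 26L) {
  stopifnot(voxel_p > 0, voxel_p < 0.5, alpha > 0, alpha < 1, n_iter >= 500)
  d <- dim(mask)
  stopifnot(length(d) == 3)
  set.seed(seed)
  zcrit <- stats::qnorm(1 - voxel_p / 2)
  smooth_it <- fwhm_mm > 0
  if (smooth_it) {
    k <- gaussian_kernel_1d(fwhm_to_sigma(fwhm_mm, voxel_size_mm))
    K <- lapply(1:3, function(i) conv_matrix_1d(d[i], k))
    vv <- lapply(K, function(Ki) rowSums(Ki^2))
    sd_arr <- sqrt(outer(outer(vv[[1]], vv[[2]]), vv[[3]]))
    dim(sd_arr) <- d
  }
  maxext <- integer(n_iter)
  exceed <- numeric(n_iter)
  nmask <- sum(mask)
  for (it in seq_len(n_iter)) {
    x <- array(stats::rnorm(prod(d)), d)
    if (smooth_it) {
      for (i in 1:3) x <- conv_along_dim(x, K[[i]], i)
      x <- x / sd_arr
    }
    supra_p <- mask & x > zcrit
    supra_n <- mask & x < -zcrit
    exceed[it] <- (sum(supra_p) + sum(supra_n)) / nmask
    m <- 0L
    for (supra in list(supra_p, supra_n)) {
      if (!any(supra)) next
      lab <- label_components(supra, connectivity)
      m <- max(m, tabulate(lab[lab > 0]))
    }
    maxext[it] <- m
  }
  q <- stats::quantile(maxext, 1 - alpha, type = 1, names = FALSE)
  thr <- as.integer(ceiling(q)) + 1L
  structure(
    list(extent_threshold_voxels = thr,
         extent_threshold_mm3 = thr * voxel_size_mm^3,
         null_max_extent_quantiles = stats::quantile(
           maxext, c(0.5, 0.9, 0.95, 0.99), type = 1),
         n_iterations = n_iter,
         realized_exceedance = mean(exceed),
         params = list(mask_voxels = nmask, fwhm_mm = fwhm_mm,
                       voxel_p = voxel_p, alpha = alpha,
                       connectivity = connectivity, seed = seed)),
    class = "cluster_sim")
}

#' @export
print.cluster_sim <- function(x, ...) {
  cat(sprintf(
    "<cluster_sim> extent threshold %d voxels (%.0f mm^3) at voxel p = %g, alpha = %g (%d iterations)\n",
    x$extent_threshold_voxels, x$extent_threshold_mm3, x$params$voxel_p,
    x$params$alpha, x$n_iterations))
  invisible(x)
}
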