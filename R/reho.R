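# Regional homogeneity: Kendall's coefficient of concordance (KCC) over a
# voxel's local neighbourhood, whole-brain-mean normalization, map
# smoothing, and seed discovery from group-difference clusters.
#
# ReHo is computed on the unsmoothed preprocessed series and the resulting
# *map* is smoothed afterwards; the connectivity branch instead smooths the
# data before correlation.

#' Kendall's coefficient of concordance
#'
#' Concordance of k series over n time points:
#' `W = 12 S / (k^2 (n^3 - n))`, where ranks are taken within each series
#' over time, `R_t` is the across-series rank sum at time t, and
#' `S = sum_t (R_t - k (n + 1) / 2)^2`. W is 1 for perfectly concordant
#' series and has expectation 1/k for independent ones. No tie correction is
#' applied (BOLD values are continuous); a constant series is ranked by
#' first occurrence and triggers a warning.
#'
#' @param block numeric matrix, k series in rows, n time points in columns
#' @return W in \[0, 1\]
#' @export
kendalls_w <- function(block) {
  block <- as.matrix(block)
  k <- nrow(block); n <- ncol(block)
  stopifnot(k >= 2, n >= 2)
  if (any(apply(block, 1, function(x) max(x) == min(x))))
    warning("constant series in KCC block; ranked by first occurrence")
  ranks <- t(apply(block, 1, rank, ties.method = "first"))
  R <- colSums(ranks)
  S <- sum((R - k * (n + 1) / 2)^2)
  12 * S / (k^2 * (n^3 - n))
}

#' A ReHo map container
#'
#' @param values 3D array of KCC values (0 outside the mask)
#' @param mask logical 3D array
#' @param neighborhood 7, 19 or 27
#' @param normalized has the map been divided by its whole-brain mean?
#' @return a `reho_map` object
#' @export
reho_map_obj <- function(values, mask, neighborhood, normalized = FALSE) {
  structure(list(values = values, mask = mask,
                 neighborhood = as.integer(neighborhood),
                 normalized = normalized),
            class = "reho_map")
}

#' Whole-brain regional homogeneity map
#'
#' Each in-mask voxel's value is the KCC of its own time series together
#' with its in-mask neighbours (nearest 26, 18 or 6 neighbours for
#' `neighborhood` 27, 19, 7). At mask edges the neighbourhood is intersected
#' with the mask and k is the actual series count; voxels with fewer than 2
#' in-mask series are set to 0. Out-of-mask voxels are 0.
#'
#' @param series a [bold_series()] (preprocessed, unsmoothed)
#' @param mask logical 3D array (defaults to the series mask)
#' @param neighborhood 7, 19 or 27 (default)
#' @return a `reho_map`
#' @export
reho_map <- function(series, mask = series$mask, neighborhood = 27L) {
  stopifnot(neighborhood %in% c(7L, 19L, 27L))
  t <- n_volumes(series)
  stopifnot(t >= 10)
  d <- dim(mask)
  V <- prod(d)
  Y <- series_matrix(series)
  vox <- which(as.vector(mask))
  RK <- matrix(0, t, V)
  RK[, vox] <- apply(Y[, vox, drop = FALSE], 2, rank, ties.method = "first")
  conn <- c(`7` = 6L, `19` = 18L, `27` = 26L)[as.character(neighborhood)]
  offs <- rbind(c(0L, 0L, 0L), neighbour_offsets(conn))
  Rsum <- matrix(0, t, V)
  kcount <- numeric(V)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    xs <- max(1, 1 - o[1]):min(d[1], d[1] - o[1])
    ys <- max(1, 1 - o[2]):min(d[2], d[2] - o[2])
    zs <- max(1, 1 - o[3]):min(d[3], d[3] - o[3])
    valid <- array(FALSE, d)
    valid[xs, ys, zs] <- mask[xs, ys, zs] &
      mask[xs + o[1], ys + o[2], zs + o[3]]
    tv <- which(valid)
    if (!length(tv)) next
    sv <- tv + o[1] + d[1] * o[2] + d[1] * d[2] * o[3]
    Rsum[, tv] <- Rsum[, tv] + RK[, sv]
    kcount[tv] <- kcount[tv] + 1
  }
  W <- numeric(V)
  ok <- kcount >= 2
  if (any(ok)) {
    S <- colSums((Rsum[, ok, drop = FALSE] -
                    rep(kcount[ok] * (t + 1) / 2, each = t))^2)
    W[ok] <- 12 * S / (kcount[ok]^2 * (t^3 - t))
  }
  reho_map_obj(array(W, d), mask, neighborhood)
}

#' Normalize a ReHo map by its whole-brain mean
#'
#' @param map a `reho_map`
#' @return the normalized `reho_map` (in-mask mean exactly 1)
#' @export
normalize_reho <- function(map) {
  m <- mean(map$values[map$mask])
  if (!is.finite(m) || m <= 0) stop("in-mask mean ReHo must be positive")
  map$values[map$mask] <- map$values[map$mask] / m
  map$normalized <- TRUE
  map
}

#' A seed region of interest
#'
#' @param name region label
#' @param voxels integer voxel indices (1-based, linear)
#' @param source `"reho_cluster"` or `"sphere"`
#' @return a `seed_roi`
#' @export
seed_roi <- function(name, voxels, source = c("reho_cluster", "sphere")) {
  voxels <- as.integer(voxels)
  if (!length(voxels)) stop("seed ROI must be nonempty")
  structure(list(name = name, voxels = voxels,
                 source = match.arg(source)),
            class = "seed_roi")
}

#' Select seed ROIs from a thresholded group-difference map
#'
#' Turns each surviving cluster of a (ReHo) group-difference statistical map
#' into a seed ROI named after the atlas region at the cluster peak. The
#' choice of which discovered seeds to carry forward into connectivity
#' analysis is a judgement call left to the user.
#'
#' @param group_diff a `stat_map` of the group difference
#' @param atlas an [atlas_spec()] for labels
#' @param voxel_p voxel-level two-sided p threshold
#' @param min_extent_voxels minimum surviving cluster extent (voxels)
#' @return list of [seed_roi()]s (empty, with a warning, if no cluster
#'   survives)
#' @export
select_seeds <- function(group_diff, atlas, voxel_p = 0.005,
                         min_extent_voxels = 30) {
  ct <- cluster_table(group_diff, voxel_p = voxel_p,
                      min_extent_voxels = min_extent_voxels, atlas = atlas)
  if (nrow(ct$table) == 0) {
    warning("no clusters survive; returning no seeds")
    return(list())
  }
  lapply(seq_len(nrow(ct$table)), function(i)
    seed_roi(ct$table$region_label[i], ct$clusters[[i]], "reho_cluster"))
}
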