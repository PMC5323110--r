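# Shared numerical helpers: separable Gaussian smoothing, connected
# components, and small array utilities. Everything here operates on plain
# 3D arrays / logical masks so the statistical modules stay array-in,
# array-out.

#' Gaussian kernel standard deviation in voxels
#'
#' Converts a full-width-at-half-maximum in millimetres to the standard
#' deviation (in voxel units) of the corresponding Gaussian kernel,
#' sigma = FWHM / (2 sqrt(2 ln 2)) / voxel size.
#'
#' @param fwhm_mm kernel full width at half maximum (mm)
#' @param voxel_size_mm isotropic voxel edge length (mm)
#' @return standard deviation in voxels
#' @export
fwhm_to_sigma <- function(fwhm_mm, voxel_size_mm) {
  fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
}

# 1D normalized Gaussian kernel; half-width covers +-3.5 sigma.
gaussian_kernel_1d <- function(sigma_vox) {
  h <- max(1L, ceiling(3.5 * sigma_vox))
  k <- stats::dnorm(seq(-h, h), sd = sigma_vox)
  k / sum(k)
}

# Dense banded convolution matrix for one array dimension (truncated at the
# edges, i.e. plain convolution with zero outside the grid).
conv_matrix_1d <- function(n, k) {
  h <- (length(k) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (d in -h:h) {
    idx <- seq_len(n - abs(d))
    if (d >= 0) K[cbind(idx + d, idx)] <- k[h + 1L + d]
    else        K[cbind(idx, idx - d)] <- k[h + 1L - d]
  }
  K
}

# Apply a 1D kernel along one dimension of a 3D array via matrix products.
conv_along_dim <- function(arr, K, dim_i) {
  d <- dim(arr)
  perm <- switch(dim_i, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  inv <- order(perm)
  a <- aperm(arr, perm)
  da <- dim(a)
  a <- K %*% matrix(a, da[1], da[2] * da[3])
  aperm(array(a, da), inv)
}

# Separable 3D convolution with a shared 1D kernel (isotropic voxels).
conv3d_separable <- function(arr, k) {
  d <- dim(arr)
  for (i in 1:3) arr <- conv_along_dim(arr, conv_matrix_1d(d[i], k), i)
  arr
}

#' Smooth a 3D map with an isotropic Gaussian kernel
#'
#' Smoothing is mask-respecting when a mask is supplied: the map and the mask
#' indicator are convolved separately and their ratio taken inside the mask,
#' so in-mask values are a convex combination of in-mask neighbours only and
#' no intensity bleeds in from outside. Out-of-mask voxels are returned as 0.
#' With `fwhm_mm = 0` the map is returned unchanged.
#'
#' @param map 3D numeric array
#' @param fwhm_mm Gaussian full width at half maximum (mm)
#' @param voxel_size_mm isotropic voxel size (mm)
#' @param mask optional logical 3D array; smoothing is restricted to it
#' @return smoothed 3D array
#' @export
smooth_map <- function(map, fwhm_mm, voxel_size_mm, mask = NULL) {
  stopifnot(length(dim(map)) == 3, fwhm_mm >= 0, voxel_size_mm > 0)
  if (fwhm_mm == 0) return(map)
  k <- gaussian_kernel_1d(fwhm_to_sigma(fwhm_mm, voxel_size_mm))
  if (is.null(mask)) return(conv3d_separable(map, k))
  m <- array(as.numeric(mask), dim(map))
  num <- conv3d_separable(map * m, k)
  den <- conv3d_separable(m, k)
  out <- array(0, dim(map))
  inside <- mask & den > 0
  out[inside] <- num[inside] / den[inside]
  out
}

# 26/18/6-neighbourhood integer offsets as an n x 3 matrix (excluding 0,0,0).
neighbour_offsets <- function(connectivity = 26L) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  switch(as.character(connectivity),
    "6"  = g[rowSums(abs(g)) == 1, , drop = FALSE],
    "18" = g[rowSums(abs(g)) <= 2, , drop = FALSE],
    "26" = g,
    stop("connectivity must be 6, 18 or 26")
  )
}

#' Label connected components of a 3D logical array
#'
#' Components are formed under 26-, 18- or 6-connectivity (26 is the default,
#' matching cluster formation in the statistical modules). Implemented as a
#' vectorized edge enumeration over the true voxels followed by union-find.
#'
#' @param x logical 3D array
#' @param connectivity 6, 18 or 26
#' @return integer array of the same shape: 0 outside, component id inside
#' @export
label_components <- function(x, connectivity = 26L) {
  d <- dim(x)
  stopifnot(length(d) == 3)
  idx <- which(x)
  lab <- array(0L, d)
  nv <- length(idx)
  if (nv == 0L) return(lab)
  pos <- array(0L, d)
  pos[idx] <- seq_len(nv)
  co <- arrayInd(idx, d)
  offs <- neighbour_offsets(connectivity)
  # half the offsets suffice to enumerate each edge once
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 |
          (offs[, 2] == 0 & offs[, 1] > 0))), , drop = FALSE]
  parent <- seq_len(nv)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    ok <- co[, 1] + o[1] >= 1 & co[, 1] + o[1] <= d[1] &
          co[, 2] + o[2] >= 1 & co[, 2] + o[2] <= d[2] &
          co[, 3] + o[3] >= 1 & co[, 3] + o[3] <= d[3]
    if (!any(ok)) next
    nb <- idx[ok] + o[1] + d[1] * o[2] + d[1] * d[2] * o[3]
    j <- pos[nb]
    hit <- j > 0L
    if (!any(hit)) next
    a <- which(ok)[hit]
    b <- j[hit]
    for (e in seq_along(a)) {
      ra <- find(a[e]); rb <- find(b[e])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(nv), find, integer(1))
  lab[idx] <- match(roots, unique(roots))
  lab
}

# Deterministic sub-seed derivation: keeps everything inside 32-bit range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 7919) %% 2147483629)
}

# Convert 1-based voxel indices (n x 3) to world mm via a 4x4 affine.
voxel_to_world <- function(ijk, affine) {
  ijk <- matrix(ijk, ncol = 3)
  xyz <- cbind(ijk - 1, 1) %*% t(affine)
  xyz[, 1:3, drop = FALSE]
}
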