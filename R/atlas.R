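# Synthetic atlas geometry and generative ground truth.
#
# The default atlas is a 24 x 28 x 24 grid at 3 mm isotropic resolution (the
# analysis resolution the pipeline targets) holding an ellipsoidal brain
# mask, two seed regions (DLPFC-like and RSC-like), six coupling targets
# named after the regions of the two networks (MCC, caudate, ACG/SMA,
# bilateral IPL, PCC/precuneus), and deep WM / CSF compartments for nuisance
# extraction.

#' Construct an atlas specification
#'
#' @param grid_shape integer vector of 3 positive grid dimensions (voxels)
#' @param voxel_size_mm isotropic voxel edge length in mm
#' @param regions named list of integer voxel indices (linear, 1-based); must
#'   contain the seed, target, `wm` and `csf` entries used by the generator
#' @param brain_mask logical 3D array of `grid_shape`
#' @param affine optional 4x4 voxel-to-world (mm) affine; defaults to a
#'   grid-centred diagonal affine
#' @return an `atlas_spec` object
#' @export
atlas_spec <- function(grid_shape, voxel_size_mm, regions, brain_mask,
                       affine = NULL) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape > 0), voxel_size_mm > 0)
  stopifnot(identical(dim(brain_mask), grid_shape))
  if (is.null(affine)) {
    affine <- diag(c(rep(voxel_size_mm, 3), 1))
    affine[1:3, 4] <- -voxel_size_mm * (grid_shape - 1) / 2
  }
  atlas <- structure(
    list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
         affine = affine, regions = lapply(regions, as.integer),
         brain_mask = brain_mask),
    class = "atlas_spec")
  validate_atlas(atlas)
  atlas
}

# Region invariants: nonempty, pairwise disjoint, GM regions inside the brain
# mask, WM/CSF inside the brain but disjoint from every GM region.
validate_atlas <- function(atlas) {
  r <- atlas$regions
  needed <- c("seed_DLPFC", "seed_RSC", "target_MCC", "target_IPL_L",
              "target_IPL_R", "target_PCC_PCu", "target_caudate",
              "target_ACG_SMA", "wm", "csf", "background")
  missing <- setdiff(needed, names(r))
  if (length(missing))
    stop("atlas regions missing: ", paste(missing, collapse = ", "))
  if (any(lengths(r) == 0)) stop("every atlas region must be nonempty")
  all_idx <- unlist(r, use.names = FALSE)
  if (anyDuplicated(all_idx)) stop("atlas regions must be disjoint")
  inside <- which(atlas$brain_mask)
  gm <- setdiff(needed, c("wm", "csf", "background"))
  for (nm in gm)
    if (!all(r[[nm]] %in% inside))
      stop("region ", nm, " is not inside the brain mask")
  for (nm in c("wm", "csf"))
    if (!all(r[[nm]] %in% inside))
      stop("region ", nm, " is not inside the brain mask")
  if (any(r$background %in% inside))
    stop("background must lie outside the brain mask")
  invisible(atlas)
}

# Linear indices of a box given inclusive ranges per dimension.
box_indices <- function(d, xr, yr, zr) {
  g <- expand.grid(x = xr, y = yr, z = zr)
  g$x + d[1] * (g$y - 1) + d[1] * d[2] * (g$z - 1)
}

#' Default desk-scale atlas
#'
#' 24 x 28 x 24 voxels at 3 mm with an ellipsoidal brain, box-shaped seed and
#' target regions placed to echo the anatomy of the two networks (DLPFC-like
#' seed right frontal, RSC-like seed right posterior, MCC and PCC/PCu on the
#' midline, IPL lateral pair, caudate deep anterior, ACG/SMA left superior),
#' plus WM and CSF compartments.
#'
#' @param grid_shape grid dimensions, default `c(24, 28, 24)`
#' @param voxel_size_mm voxel size, default 3
#' @return an `atlas_spec`
#' @export
default_atlas <- function(grid_shape = c(24L, 28L, 24L), voxel_size_mm = 3) {
  d <- as.integer(grid_shape)
  ctr <- (d + 1) / 2
  semi <- (d - 3) / 2
  co <- as.matrix(expand.grid(x = 1:d[1], y = 1:d[2], z = 1:d[3]))
  rr <- ((co[, 1] - ctr[1]) / semi[1])^2 + ((co[, 2] - ctr[2]) / semi[2])^2 +
        ((co[, 3] - ctr[3]) / semi[3])^2
  brain <- array(rr <= 1, d)
  regions <- list(
    seed_DLPFC     = box_indices(d, 16:19, 18:21, 14:17),
    seed_RSC       = box_indices(d, 14:17, 6:9, 8:10),
    target_MCC     = box_indices(d, 10:15, 12:17, 14:19),
    target_caudate = box_indices(d, 10:14, 17:20, 9:12),
    target_ACG_SMA = box_indices(d, 5:9, 13:17, 16:19),
    target_IPL_L   = box_indices(d, 5:9, 9:13, 12:15),
    target_IPL_R   = box_indices(d, 16:20, 9:13, 12:15),
    target_PCC_PCu = box_indices(d, 10:15, 5:9, 11:15),
    wm             = box_indices(d, 11:14, 10:12, 6:9),
    csf            = box_indices(d, 11:13, 13:15, 10:12)
  )
  regions <- lapply(regions, function(ix) ix[brain[ix]])
  regions$background <- which(!brain)
  atlas_spec(d, voxel_size_mm, regions, brain)
}

#' Gray-matter analysis mask of an atlas
#'
#' Brain mask minus the WM and CSF compartments; this is the voxel set over
#' which ReHo, connectivity and the group statistics are computed.
#'
#' @param atlas an `atlas_spec`
#' @return logical 3D array
#' @export
gm_mask <- function(atlas) {
  m <- atlas$brain_mask
  m[atlas$regions$wm] <- FALSE
  m[atlas$regions$csf] <- FALSE
  m
}

#' Integer region-label volume of an atlas
#'
#' @param atlas an `atlas_spec`
#' @return list with `labels` (integer 3D array, 0 = unlabeled) and
#'   `names` (region name per label value)
#' @export
atlas_labels <- function(atlas) {
  nm <- setdiff(names(atlas$regions), "background")
  lab <- array(0L, atlas$grid_shape)
  for (i in seq_along(nm)) lab[atlas$regions[[nm[i]]]] <- i
  list(labels = lab, names = nm)
}

#' Generative ground truth for a synthetic cohort
#'
#' Bundles everything the generator needs to plant recoverable effects:
#' seed-to-target coupling weights per group on the Fisher-z scale, the
#' three-path mediation parameters (`a`: EF to FC, `b`: FC to EM given EF,
#' `c_prime`: direct EF to EM), noise standard deviations, ReHo hotspot
#' gains per group (share of within-region variance carried by a common
#' signal), and the neuropsychological calibration targets the phenotype
#' generator aims at (group means/SDs of the EM and EF composites).
#'
#' The total EF-to-EM effect is `c = c_prime + a * b`; with the defaults
#' `a = 0.15`, `b = -0.858`, `c_prime = -0.1713` the mediated fraction
#' `(a * b) / c` is 0.429 and `c` is negative, so cohorts show the negative
#' EM-EF association expected when EF is timed (higher = slower = worse).
#'
#' @param a,b,c_prime mediation path coefficients (EF and EM on the pooled
#'   composite z scale, FC on the Fisher-z scale)
#' @param sd_fc SD of the subject-level coupling noise (Fisher z)
#' @param group_coupling named list (`patient`, `control`) of named numeric
#'   vectors: planted seed-to-target coupling per target region (Fisher z)
#' @param networks named list mapping each seed region to its target regions
#' @param mediation_region target region whose coupling is the mediator
#' @param reho_hotspots named list per group of hotspot gains in (0, 1) for
#'   the seed regions
#' @param region_coherence share of a target voxel's variance carried by
#'   region-wide band-limited signal; the remainder is voxel-private white
#'   noise that spatial smoothing averages away
#' @param calibration list of composite calibration targets (`em_mean`,
#'   `em_sd`, `ef_mean`, `ef_sd`, each a named patient/control vector)
#' @param atrophy_regions regions where patient GM maps lose probability mass
#' @return a `ground_truth` object
#' @export
ground_truth <- function(
    a = 0.15, b = -0.858, c_prime = -0.1713, sd_fc = 0.25,
    group_coupling = list(
      patient = c(target_MCC = 0.4, target_caudate = 0.35,
                  target_ACG_SMA = 0.35, target_IPL_L = 0.25,
                  target_IPL_R = 0.2, target_PCC_PCu = 0.1),
      control = c(target_MCC = 0.1, target_caudate = 0.1,
                  target_ACG_SMA = 0.1, target_IPL_L = 0.25,
                  target_IPL_R = 0.2, target_PCC_PCu = 0.4)),
    networks = list(
      seed_DLPFC = c("target_MCC", "target_caudate", "target_ACG_SMA",
                     "target_IPL_L"),
      seed_RSC = c("target_PCC_PCu", "target_IPL_R")),
    mediation_region = "target_MCC",
    reho_hotspots = list(patient = c(seed_DLPFC = 0.35, seed_RSC = 0.35),
                         control = c(seed_DLPFC = 0.7, seed_RSC = 0.7)),
    region_coherence = 0.8,
    calibration = list(
      em_mean = c(patient = -0.74, control = 0.50),
      em_sd = c(patient = 0.71, control = 0.51),
      ef_mean = c(patient = 0.44, control = -0.27),
      ef_sd = c(patient = 0.95, control = 0.52)),
    atrophy_regions = c("seed_DLPFC", "seed_RSC")) {
  stopifnot(sd_fc > 0, region_coherence > 0, region_coherence < 1)
  stopifnot(all(c("patient", "control") %in% names(group_coupling)))
  cpl <- unlist(group_coupling)
  if (!all(is.finite(cpl))) stop("coupling weights must be finite")
  structure(
    list(a = a, b = b, c_prime = c_prime, c_total = c_prime + a * b,
         sd_fc = sd_fc, group_coupling = group_coupling,
         networks = networks, mediation_region = mediation_region,
         reho_hotspots = reho_hotspots, region_coherence = region_coherence,
         calibration = calibration, atrophy_regions = atrophy_regions),
    class = "ground_truth")
}
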