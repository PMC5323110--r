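# Voxelwise group statistics: one-sample network maps with familywise
# correction, covariate-adjusted group differences with a voxelwise
# gray-matter covariate, behaviour-connectivity regression, partial
# correlation on extracted strengths, conjunction, and cluster tabulation.

#' A voxelwise statistical map
#'
#' @param stat 3D array of t statistics (0 outside mask)
#' @param df residual degrees of freedom (n - design columns)
#' @param mask logical 3D array
#' @param contrast label
#' @param beta,se optional effect-size and standard-error arrays for the
#'   tested column
#' @return a `stat_map` object
#' @export
stat_map <- function(stat, df, mask, contrast = "", beta = NULL, se = NULL) {
  stopifnot(identical(dim(stat), dim(mask)), df >= 1)
  structure(list(stat = stat, df = df, mask = mask, contrast = contrast,
                 beta = beta, se = se),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> '%s', df = %d, max |t| = %.2f over %d voxels\n",
              x$contrast, x$df, max(abs(x$stat[x$mask])), sum(x$mask)))
  invisible(x)
}

# n x V matrix from a list of per-subject 3D maps, restricted to the mask.
map_stack <- function(maps, mask) {
  vox <- which(as.vector(mask))
  do.call(rbind, lapply(maps, function(m) as.vector(m)[vox]))
}

#' Logit transform of gray-matter probability maps
#'
#' `logit(a) = 0.5 ln(a / (1 - a))` after clamping to `[eps, 1 - eps]`,
#' followed by Gaussian smoothing — the normalization applied before GM
#' enters the group model as a voxelwise covariate.
#'
#' @param gm 3D array of GM probabilities
#' @param voxel_size_mm voxel size for the smoothing kernel
#' @param fwhm_mm smoothing FWHM (default 8 mm; 0 skips smoothing)
#' @param mask optional smoothing mask
#' @param eps clamping bound, default 1e-6
#' @return 3D array of smoothed half-logit values
#' @export
logit_gm <- function(gm, voxel_size_mm = 3, fwhm_mm = 8, mask = NULL,
                     eps = 1e-6) {
  a <- pmin(pmax(gm, eps), 1 - eps)
  l <- 0.5 * log(a / (1 - a))
  smooth_map(l, fwhm_mm, voxel_size_mm, mask)
}

#' One-sample network map with familywise-error control
#'
#' Voxelwise one-sample t of the subjects' Fisher-z maps against zero.
#' Significance requires a Bonferroni-adjusted two-sided p below `alpha_fwe`
#' over the in-mask voxels *and* a positive t (positive-connectivity rule).
#'
#' @param fc_maps list of per-subject 3D Fisher-z arrays
#' @param mask analysis mask
#' @param alpha_fwe familywise alpha (default 0.01)
#' @return list with `map` (a `stat_map`) and `significant` (logical array)
#' @export
one_sample_map <- function(fc_maps, mask, alpha_fwe = 0.01) {
  n <- length(fc_maps)
  stopifnot(n >= 3)
  Y <- map_stack(fc_maps, mask)
  mu <- colMeans(Y)
  se <- apply(Y, 2, stats::sd) / sqrt(n)
  tv <- ifelse(se > 0, mu / se, 0)
  df <- n - 1
  nvox <- sum(mask)
  p2 <- 2 * stats::pt(-abs(tv), df)
  sig <- p2 < alpha_fwe / nvox & tv > 0
  d <- dim(mask)
  arr <- function(x) { a <- array(0, d); a[mask] <- x; a }
  sg <- array(FALSE, d); sg[mask] <- sig
  list(map = stat_map(arr(tv), df, mask, "one-sample mean z > 0",
                      beta = arr(mu), se = arr(se)),
       significant = sg)
}

#' Group-difference GLM with covariates and voxelwise gray matter
#'
#' Per-voxel OLS of connectivity on
#' `[1, group, age, gender, education, GM(voxel)]`, where the GM covariate
#' is that voxel's (logit-transformed, smoothed) GM value per subject.
#' Returns the t map for the group column (patient minus control for
#' patient coded 1).
#'
#' @param fc_maps list of per-subject 3D Fisher-z arrays
#' @param group character/factor vector; `"patient"` is coded 1
#' @param covariates data frame with `age`, `gender`, `education`
#' @param gm_maps list of per-subject 3D GM covariate arrays (e.g. from
#'   [logit_gm()]), or `NULL` to omit the GM column
#' @param mask analysis mask
#' @return a `stat_map` with `beta` and `se` for the group column
#' @export
group_glm <- function(fc_maps, group, covariates, gm_maps = NULL, mask) {
  n <- length(fc_maps)
  g <- as.integer(group == "patient")
  if (length(unique(g)) < 2 || min(table(g)) < 3)
    stop("need at least 3 subjects per group")
  X0 <- cbind(intercept = 1, group = g, age = covariates$age,
              gender = covariates$gender, education = covariates$education)
  if (qr(X0)$rank < ncol(X0)) {
    bad <- colnames(X0)[qr(X0)$pivot[-seq_len(qr(X0)$rank)]]
    stop("collinear design columns: ", paste(bad, collapse = ", "))
  }
  Y <- map_stack(fc_maps, mask)
  G <- if (!is.null(gm_maps)) map_stack(gm_maps, mask) else NULL
  V <- ncol(Y)
  p <- ncol(X0) + !is.null(G)
  df <- n - p
  stopifnot(df >= 1)
  beta <- se <- tv <- numeric(V)
  for (v in seq_len(V)) {
    X <- if (is.null(G)) X0 else cbind(X0, gm = G[, v])
    fit <- stats::lm.fit(X, Y[, v])
    if (fit$rank < ncol(X)) next
    res <- fit$residuals
    sigma2 <- sum(res^2) / df
    xtxinv <- chol2inv(qr.R(fit$qr))
    beta[v] <- fit$coefficients["group"]
    se[v] <- sqrt(sigma2 * xtxinv[2, 2])
    tv[v] <- if (se[v] > 0) beta[v] / se[v] else 0
  }
  d <- dim(mask)
  arr <- function(x) { a <- array(0, d); a[mask] <- x; a }
  stat_map(arr(tv), df, mask, "group (patient - control)",
           beta = arr(beta), se = arr(se))
}

#' Behaviour-connectivity multiple regression
#'
#' Per-voxel OLS of connectivity on a behavioural score with covariates;
#' returns the t map for the score coefficient. The design is shared across
#' voxels so the fit is fully vectorized.
#'
#' @param fc_maps list of per-subject 3D Fisher-z arrays
#' @param score per-subject behavioural score (e.g. an EM or EF composite)
#' @param covariates data frame of nuisance covariates (may be `NULL`)
#' @param mask analysis mask
#' @param contrast label for the returned map
#' @return a `stat_map` with `beta` and `se` for the score column
#' @export
behavior_regression <- function(fc_maps, score, covariates = NULL, mask,
                                contrast = "score") {
  n <- length(fc_maps)
  if (stats::sd(score) == 0) stop("behavioural score is constant")
  X <- cbind(intercept = 1, score = score)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  stopifnot(n >= ncol(X) + 2, nrow(X) == n)
  Y <- map_stack(fc_maps, mask)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("collinear behavioural design")
  B <- qr.coef(qx, Y)
  res <- Y - X %*% B
  df <- n - ncol(X)
  sigma2 <- colSums(res^2) / df
  xtxinv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * xtxinv[2, 2])
  tv <- ifelse(se > 0, B[2, ] / se, 0)
  d <- dim(mask)
  arr <- function(x) { a <- array(0, d); a[mask] <- x; a }
  stat_map(arr(tv), df, mask, contrast, beta = arr(B[2, ]), se = arr(se))
}

#' Partial correlation of extracted strengths and behaviour
#'
#' Correlation of the OLS residuals of both variables on the covariates;
#' the p value comes from the t distribution with `n - k - 2` degrees of
#' freedom (k covariates). Without covariates this is the Pearson
#' correlation.
#'
#' @param strengths per-subject scalar (e.g. mean cluster connectivity)
#' @param score per-subject behavioural score
#' @param covariates data frame or matrix of covariates (may be `NULL`)
#' @return list with `r_partial`, `p`, `df`
#' @export
partial_correlation <- function(strengths, score, covariates = NULL) {
  n <- length(strengths)
  stopifnot(length(score) == n)
  k <- 0
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    k <- ncol(C)
    X <- cbind(1, C)
    strengths <- stats::lm.fit(X, strengths)$residuals
    score <- stats::lm.fit(X, score)$residuals
  }
  stopifnot(n >= k + 3)
  df <- n - k - 2
  # a variable fully explained by the covariates has nothing left to correlate
  if (stats::sd(strengths) < 1e-10 || stats::sd(score) < 1e-10)
    return(list(r_partial = 0, p = 1, df = df))
  r <- stats::cor(strengths, score)
  tv <- r * sqrt(df / (1 - r^2))
  list(r_partial = r, p = 2 * stats::pt(-abs(tv), df), df = df)
}

# Atlas region label containing a voxel (linear index), or "unlabeled".
region_at <- function(atlas, voxel) {
  for (nm in setdiff(names(atlas$regions), "background"))
    if (voxel %in% atlas$regions[[nm]]) return(nm)
  "unlabeled"
}

# Label for a cluster: the region at its peak, falling back to the region
# with the largest overlap when the peak lies between regions.
cluster_label <- function(atlas, peak, voxels) {
  lab <- region_at(atlas, peak)
  if (lab != "unlabeled") return(lab)
  nms <- setdiff(names(atlas$regions), "background")
  ov <- vapply(nms, function(nm)
    length(intersect(voxels, atlas$regions[[nm]])), integer(1))
  if (max(ov) > 0) nms[which.max(ov)] else "unlabeled"
}

#' Tabulate suprathreshold clusters of a statistical map
#'
#' Thresholds the map two-sided at the voxel-level p value, forms connected
#' components per sign (26-connectivity by default), keeps clusters of at
#' least `min_extent_voxels`, and reports one row per cluster sorted by
#' extent: region label at the peak, side, extent in voxels and mm^3, peak
#' world-mm coordinate and peak statistic.
#'
#' @param map a `stat_map`
#' @param voxel_p two-sided voxel-level p threshold
#' @param min_extent_voxels minimum cluster extent in voxels
#' @param atlas an [atlas_spec()] for labels and geometry
#' @param network optional network label copied into the table
#' @param connectivity 6, 18 or 26
#' @return list with `table` (data frame) and `clusters` (list of voxel
#'   index vectors, parallel to the rows)
#' @export
cluster_table <- function(map, voxel_p = 0.005, min_extent_voxels = 75,
                          atlas, network = NA_character_,
                          connectivity = 26L) {
  t_crit <- stats::qt(1 - voxel_p / 2, map$df)
  vol <- atlas$voxel_size_mm^3
  rows <- list(); clusters <- list()
  for (sgn in c(1, -1)) {
    supra <- map$mask & (sgn * map$stat > t_crit)
    if (!any(supra)) next
    lab <- label_components(supra, connectivity)
    for (id in seq_len(max(lab))) {
      vx <- which(lab == id)
      if (length(vx) < min_extent_voxels) next
      peak <- vx[which.max(sgn * map$stat[vx])]
      xyz <- voxel_to_world(arrayInd(peak, dim(lab)), atlas$affine)
      wx <- voxel_to_world(arrayInd(vx, dim(lab)), atlas$affine)[, 1]
      side <- if (min(wx) < -atlas$voxel_size_mm &&
                  max(wx) > atlas$voxel_size_mm) "L/R"
              else if (xyz[1] < 0) "L" else "R"
      rows[[length(rows) + 1]] <- data.frame(
        region_label = cluster_label(atlas, peak, vx), side = side,
        network = network, extent_voxels = length(vx),
        extent_mm3 = length(vx) * vol,
        peak_x = xyz[1], peak_y = xyz[2], peak_z = xyz[3],
        peak_stat = map$stat[peak], stringsAsFactors = FALSE)
      clusters[[length(clusters) + 1]] <- vx
    }
  }
  if (!length(rows)) {
    tab <- data.frame(region_label = character(), side = character(),
                      network = character(), extent_voxels = integer(),
                      extent_mm3 = numeric(), peak_x = numeric(),
                      peak_y = numeric(), peak_z = numeric(),
                      peak_stat = numeric(), stringsAsFactors = FALSE)
    return(list(table = tab, clusters = list()))
  }
  tab <- do.call(rbind, rows)
  ord <- order(-tab$extent_voxels)
  list(table = tab[ord, , drop = FALSE], clusters = clusters[ord])
}

#' Conjunction of two significant voxel sets
#'
#' Voxelwise intersection, tabulated as clusters. Peak statistics come from
#' the conjunction rule min(|a|, |b|) when reference maps are supplied.
#'
#' @param sig_a,sig_b logical 3D arrays of significant voxels
#' @param atlas an [atlas_spec()]
#' @param stat_a,stat_b optional `stat_map`s for the two effects
#' @param min_extent_voxels minimum tabulated cluster extent
#' @param network optional network label
#' @return list with `mask` (logical intersection), `table`, `clusters`
#' @export
conjunction <- function(sig_a, sig_b, atlas, stat_a = NULL, stat_b = NULL,
                        min_extent_voxels = 1, network = NA_character_) {
  stopifnot(identical(dim(sig_a), dim(sig_b)))
  inter <- sig_a & sig_b
  cstat <- if (!is.null(stat_a) && !is.null(stat_b))
    pmin(abs(stat_a$stat), abs(stat_b$stat)) else array(1, dim(inter))
  df <- if (!is.null(stat_a)) stat_a$df else 1
  sm <- stat_map(cstat * inter, max(df, 1), inter, "conjunction")
  ct <- cluster_table(sm, voxel_p = 0.999999,
                      min_extent_voxels = min_extent_voxels, atlas = atlas,
                      network = network)
  list(mask = inter, table = ct$table, clusters = ct$clusters)
}
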