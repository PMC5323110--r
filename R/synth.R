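# Synthetic cohort generator.
#
# The generator plants three kinds of recoverable structure:
#   * seed regions carry a band-limited (0.01-0.08 Hz) latent signal whose
#     within-region shared fraction (the "hotspot gain") differs by group,
#     giving a ReHo group contrast;
#   * target regions mix their parent seed's latent with a subject-specific
#     weight tanh(z_i), where z_i is the planted Fisher-z coupling
#     (group value + subject noise, plus an EF pathway for the mediation
#     target), giving seed-based FC group differences;
#   * phenotypes follow the three-path generative model
#     FC = a*EF + noise, EM = c'*EF + b*FC + noise, with EF timed
#     (higher = worse), so the pooled EM-EF association is negative.
#
# All randomness flows from one integer seed; per-subject image seeds are
# derived deterministically so volumes can be regenerated lazily.

#' Generate a six-parameter motion trace
#'
#' The baseline is a smooth low-amplitude random walk. Each spike is a
#' sustained step of `spike_mm` applied simultaneously to all three
#' translation axes from the spike volume onward, so a spike produces a
#' single large frame-to-frame transition of known size.
#'
#' @param n_volumes number of volumes
#' @param spike_times integer volume indices (1-based) at which a step occurs
#' @param spike_mm step amplitude per translation axis (mm)
#' @param seed RNG seed
#' @param walk_sd per-volume random-walk step SD (mm or degrees)
#' @return a [motion_trace()]
#' @export
generate_motion <- function(n_volumes, spike_times = integer(0),
                            spike_mm = 1.0, seed = 1, walk_sd = 0.015) {
  stopifnot(n_volumes >= 2)
  spike_times <- as.integer(spike_times)
  if (length(spike_times) && (min(spike_times) < 2 ||
                              max(spike_times) > n_volumes))
    stop("spike_times must lie in 2..n_volumes")
  set.seed(seed)
  steps <- matrix(stats::rnorm(n_volumes * 6, sd = walk_sd), n_volumes, 6)
  steps[1, ] <- 0
  params <- apply(steps, 2, cumsum)
  for (v in spike_times)
    params[v:n_volumes, 1:3] <- params[v:n_volumes, 1:3] + spike_mm
  motion_trace(params)
}

#' Generate a smooth gray-matter probability map
#'
#' A smooth logistic-scale random field over the atlas, with tissue-typical
#' baselines (GM high, WM lower, CSF low, background near zero). For the
#' patient group, `atrophy_effect` of probability mass is removed over a
#' smoothed indicator of the truth's atrophy regions. Values are clamped to
#' the open interval (0, 1) so the logit transform stays finite.
#'
#' @param atlas an [atlas_spec()]
#' @param atrophy_effect probability-mass loss in atrophy regions (>= 0)
#' @param group `"patient"` or `"control"`
#' @param seed RNG seed
#' @param truth a [ground_truth()] naming the atrophy regions
#' @return 3D array of GM probabilities in (0, 1)
#' @export
generate_gm_map <- function(atlas, atrophy_effect = 0.05, group, seed,
                            truth = ground_truth()) {
  stopifnot(atrophy_effect >= 0, group %in% c("patient", "control"))
  set.seed(seed)
  d <- atlas$grid_shape
  base <- array(0.02, d)
  base[atlas$brain_mask] <- 0.65
  base[atlas$regions$wm] <- 0.25
  base[atlas$regions$csf] <- 0.08
  noise <- smooth_map(array(stats::rnorm(prod(d)), d), fwhm_mm = 9,
                      voxel_size_mm = atlas$voxel_size_mm)
  noise <- noise / stats::sd(noise) * 0.25
  p <- stats::plogis(stats::qlogis(base) + noise)
  if (group == "patient" && atrophy_effect > 0) {
    ind <- array(0, d)
    for (nm in truth$atrophy_regions) ind[atlas$regions[[nm]]] <- 1
    ind <- smooth_map(ind, fwhm_mm = 6, voxel_size_mm = atlas$voxel_size_mm)
    p <- p - atrophy_effect * ind
  }
  pmin(pmax(p, 1e-4), 1 - 1e-4)
}

# t x n matrix of independent band-limited unit-variance series.
band_limited_noise <- function(n_volumes, n_series, tr_s,
                               low_hz = 0.01, high_hz = 0.08) {
  Y <- matrix(stats::rnorm(n_volumes * n_series), n_volumes, n_series)
  Y <- butter_bandpass_matrix(Y, tr_s, low_hz, high_hz)
  sweep(sweep(Y, 2, colMeans(Y)), 2, apply(Y, 2, stats::sd), "/")
}

# Phenotype generative model (see file header). Raw neuropsychological test
# scores are built so the three member tests of each composite carry
# sum-to-zero noise around the latent factor: pooled z-scoring then
# reconstructs the latent composite exactly (up to sample centring), which
# keeps the mediation structure intact at the composite level.
generate_phenotypes <- function(n_patient, n_control, truth,
                                calibrate = TRUE) {
  n <- n_patient + n_control
  group <- rep(c("patient", "control"), c(n_patient, n_control))
  w <- c(patient = n_patient / n, control = n_control / n)
  cal <- truth$calibration
  if (!calibrate)
    cal <- list(em_mean = c(patient = 0, control = 0),
                em_sd = c(patient = 1, control = 1),
                ef_mean = c(patient = 0, control = 0),
                ef_sd = c(patient = 1, control = 1))
  a <- truth$a; b <- truth$b; cp <- truth$c_prime
  ctot <- cp + a * b
  # note: pooled z-scoring centres composites on the cohort mean, so group
  # means can only be realized up to the weighted mean of the targets
  # (~0.01, a rounding artefact of the calibration values)
  ef <- stats::rnorm(n, cal$ef_mean[group], cal$ef_sd[group])
  ef_bar <- sum(w * cal$ef_mean)
  # planted couplings, Fisher z, one column per target region
  targets <- unique(unlist(truth$networks))
  fc <- sapply(targets, function(tg) {
    z <- sapply(truth$group_coupling, `[[`, tg)[group] +
      stats::rnorm(n, 0, truth$sd_fc)
    if (tg == truth$mediation_region) z <- z + a * (ef - ef_bar)
    z
  })
  colnames(fc) <- paste0("fc_", sub("^target_", "", targets))
  med <- fc[, paste0("fc_", sub("^target_", "", truth$mediation_region))]
  cpl_med <- sapply(truth$group_coupling, `[[`, truth$mediation_region)
  med_bar <- sum(w * cpl_med)
  # residual EM noise per group so composite SDs match the calibration
  sd3sq <- cal$em_sd^2 - ctot^2 * cal$ef_sd^2 - b^2 * truth$sd_fc^2
  if (any(sd3sq <= 0))
    stop("EM calibration SDs are too small for the mediation parameters")
  # reduced form: EM = base + (c' + a b) EFc + b e2 + e3, so the group-mean
  # compensation must use the total effect
  base <- cal$em_mean - ctot * (cal$ef_mean - ef_bar) -
    b * (cpl_med - med_bar)
  em <- base[group] + cp * (ef - ef_bar) + b * (med - med_bar) +
    stats::rnorm(n, 0, sqrt(sd3sq)[group])
  # raw member tests: latent factor + zero-sum triplet noise
  zero_sum_noise <- function(sd_d) {
    e <- matrix(stats::rnorm(n * 3, 0, sd_d * sqrt(1.5)), n, 3)
    e - rowMeans(e)
  }
  mix_var <- function(mu, sdv) {
    m <- sum(w * mu)
    sum(w * sdv^2) + sum(w * (mu - m)^2)
  }
  sd_d_em <- sqrt(max(1 - mix_var(cal$em_mean, cal$em_sd), 0.04))
  sd_d_ef <- sqrt(max(1 - mix_var(cal$ef_mean, cal$ef_sd), 0.04))
  em_tests <- em + zero_sum_noise(sd_d_em)
  ef_tests <- ef + zero_sum_noise(sd_d_ef)
  data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    group = group,
    age = round(stats::runif(n, 54, 80), 1),
    gender = stats::rbinom(n, 1, 0.5),
    education = sample(6:20, n, replace = TRUE),
    AVLT_DR = 5.5 + 2.5 * em_tests[, 1],
    CFT_DR = 18 + 6 * em_tests[, 2],
    LMT_DR = 10 + 4 * em_tests[, 3],
    TMT_A = 60 + 25 * ef_tests[, 1],
    TMT_B = 160 + 60 * ef_tests[, 2],
    SCWT_C = 80 + 25 * ef_tests[, 3],
    latent_em = em, latent_ef = ef,
    fc, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic cohort
#'
#' Produces phenotypes (demographics, raw neuropsychological scores, planted
#' subject-level couplings), motion traces, per-subject GM probability maps,
#' and deterministic per-subject seeds from which the 4D BOLD volumes are
#' generated on demand with [generate_bold()] (or all at once with
#' [write_cohort()]). Everything is reproducible from the single `seed`.
#'
#' @param n_patient,n_control group sizes (each >= 2)
#' @param atlas an [atlas_spec()]
#' @param truth a [ground_truth()]
#' @param seed integer master seed
#' @param n_volumes volumes per BOLD series
#' @param tr_s repetition time (s)
#' @param calibrate if `TRUE`, composites are calibrated to the truth's
#'   group means/SDs; if `FALSE`, both groups draw from standard normals
#' @param spike_prob per-subject probability of a motion spike
#' @param atrophy_effect GM probability loss in patient atrophy regions
#' @param phenotypes_only skip motion traces and GM maps (fast mode for
#'   phenotype-level simulation studies)
#' @return an `fc_cohort` object
#' @export
generate_cohort <- function(n_patient, n_control, atlas = default_atlas(),
                            truth = ground_truth(), seed = 1,
                            n_volumes = 240, tr_s = 2, calibrate = TRUE,
                            spike_prob = 0.25, atrophy_effect = 0.05,
                            phenotypes_only = FALSE) {
  if (n_patient < 2 || n_control < 2)
    stop("need at least 2 subjects per group")
  small <- names(which(lengths(atlas$regions[names(atlas$regions) %in%
    c(names(truth$networks), unlist(truth$networks))]) < 8))
  if (length(small))
    stop("atlas regions too small to host the requested effects: ",
         paste(small, collapse = ", "))
  set.seed(seed)
  subjects <- generate_phenotypes(n_patient, n_control, truth, calibrate)
  n <- nrow(subjects)
  subjects$bold_seed <- derive_seed(seed, seq_len(n))
  has_spike <- stats::runif(n) < spike_prob
  spike_vol <- sample(20:max(21, n_volumes - 20), n, replace = TRUE)
  spike_amp <- round(stats::runif(n, 0.6, 1.2), 3)
  motion_seeds <- derive_seed(seed, n + seq_len(n))
  gm_seeds <- derive_seed(seed, 2 * n + seq_len(n))
  motion <- gm <- NULL
  if (!phenotypes_only) {
    motion <- lapply(seq_len(n), function(i)
      generate_motion(n_volumes,
                      spike_times = if (has_spike[i]) spike_vol[i] else integer(0),
                      spike_mm = spike_amp[i], seed = motion_seeds[i]))
    gm <- lapply(seq_len(n), function(i)
      generate_gm_map(atlas, atrophy_effect, subjects$group[i], gm_seeds[i],
                      truth))
  }
  structure(
    list(subjects = subjects, motion = motion, gm = gm, atlas = atlas,
         truth = truth, n_volumes = n_volumes, tr_s = tr_s, seed = seed,
         calibrate = calibrate),
    class = "fc_cohort")
}

#' @export
print.fc_cohort <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat(sprintf("<fc_cohort> %d patients, %d controls, %d volumes at TR = %g s, seed %d\n",
              tab[["patient"]], tab[["control"]], x$n_volumes, x$tr_s,
              x$seed))
  invisible(x)
}

#' Generate one subject's 4D BOLD series
#'
#' @param subject one row of a cohort's `subjects` table (needs `group`,
#'   the planted `fc_*` couplings and `bold_seed` unless `seed` is given)
#' @param atlas an [atlas_spec()]
#' @param truth a [ground_truth()]
#' @param n_volumes number of volumes (>= 50)
#' @param tr_s repetition time (s); the 0.01-0.08 Hz band must be below the
#'   Nyquist frequency
#' @param seed RNG seed (defaults to the subject's `bold_seed`)
#' @return a [bold_series()]
#' @export
generate_bold <- function(subject, atlas, truth, n_volumes = 240, tr_s = 2,
                          seed = subject$bold_seed) {
  stopifnot(n_volumes >= 50)
  if (1 / (2 * tr_s) <= 0.08)
    stop("TR makes the 0.01-0.08 Hz band unrepresentable (Nyquist too low)")
  group <- as.character(subject$group)
  set.seed(seed)
  d <- atlas$grid_shape
  V <- prod(d)
  t <- n_volumes
  Y <- matrix(stats::rnorm(t * V), t, V)
  targets <- unique(unlist(truth$networks))
  lat <- band_limited_noise(t, length(truth$networks) + length(targets) + 3,
                            tr_s)
  colnames(lat) <- c(names(truth$networks), targets, "wm", "csf", "global")
  for (s in names(truth$networks)) {
    g <- truth$reho_hotspots[[group]][[s]]
    cols <- atlas$regions[[s]]
    Y[, cols] <- sqrt(g) * lat[, s] + sqrt(1 - g) * Y[, cols]
  }
  # voxel-private white noise amplitude implied by the region coherence:
  # shared (band-limited) variance is 1, private variance 1/h - 1, so the
  # shared fraction of total variance is h; spatial smoothing averages the
  # private part away and the planted correlation tanh(z) is recovered.
  sigma_v <- sqrt(1 / truth$region_coherence - 1)
  for (s in names(truth$networks)) for (tg in truth$networks[[s]]) {
    z <- subject[[paste0("fc_", sub("^target_", "", tg))]]
    rho <- tanh(z)
    cols <- atlas$regions[[tg]]
    Y[, cols] <- rho * lat[, s] + sqrt(1 - rho^2) * lat[, tg] +
      sigma_v * Y[, cols]
  }
  Y[, atlas$regions$wm] <- 0.8 * lat[, "wm"] + 0.6 * Y[, atlas$regions$wm]
  Y[, atlas$regions$csf] <- 0.8 * lat[, "csf"] + 0.6 * Y[, atlas$regions$csf]
  brain <- which(as.vector(atlas$brain_mask))
  Y[, brain] <- Y[, brain] + 0.4 * lat[, "global"]
  # slow per-voxel drift removed later by detrending
  drift <- stats::rnorm(V, 0, 0.3 / t)
  Y <- Y + outer(seq_len(t) - 1, drift)
  amp <- rep(2, V); amp[brain] <- 15
  off <- rep(100, V); off[brain] <- 1000
  Y <- sweep(sweep(Y, 2, amp, "*"), 2, off, "+")
  bold_series(array(t(Y), c(d, t)), tr_s, atlas$voxel_size_mm,
              atlas$brain_mask, atlas$affine)
}
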