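# Temporal preprocessing and head-motion quality assurance for a single
# subject. The canonical order, applied by preprocess_subject(), is
#   discard -> detrend -> band-pass -> nuisance regression
# with motion scrubbing applied afterwards on the connectivity branch only.
# All operations are mask-respecting: voxels outside the series mask are
# left untouched and excluded from statistics.

#' Discard initial volumes
#'
#' Drops the first `n_discard` volumes (T1-equilibration discard). The
#' caller is responsible for truncating the motion trace in lockstep, e.g.
#' via [truncate_motion()].
#'
#' @param series a [bold_series()]
#' @param n_discard number of leading volumes to drop (< number of volumes)
#' @return the shortened [bold_series()]
#' @export
discard_initial <- function(series, n_discard) {
  t <- n_volumes(series)
  if (n_discard >= t) stop("cannot discard ", n_discard, " of ", t,
                           " volumes")
  if (n_discard == 0) return(series)
  series$data <- series$data[, , , (n_discard + 1):t, drop = FALSE]
  series
}

#' Truncate a motion trace in lockstep with a volume discard
#'
#' @param motion a [motion_trace()]
#' @param n_discard number of leading rows to drop
#' @return the shortened [motion_trace()]
#' @export
truncate_motion <- function(motion, n_discard) {
  t <- nrow(motion$params)
  if (n_discard >= t) stop("cannot discard ", n_discard, " of ", t, " rows")
  if (n_discard == 0) return(motion)
  motion_trace(motion$params[(n_discard + 1):t, , drop = FALSE])
}

# Residual projection of a time x voxel matrix on a design (with intercept).
project_residuals <- function(Y, X) {
  qx <- qr(X)
  Y - qr.fitted(qx, Y)
}

#' Linear detrending
#'
#' Removes each in-mask voxel's least-squares line over time (intercept and
#' slope), leaving residuals orthogonal to the linear trend.
#'
#' @param series a [bold_series()]
#' @return the detrended [bold_series()]
#' @export
detrend_linear <- function(series) {
  t <- n_volumes(series)
  if (t < 3) stop("need at least 3 volumes to detrend")
  X <- cbind(1, seq_len(t))
  replace_in_mask(series, function(Y) project_residuals(Y, X))
}

# Zero-phase Butterworth band-pass applied in the frequency domain.
# Each series is demeaned, padded with odd (antisymmetric) reflections of
# itself at both ends to suppress edge transients, then multiplied by the
# squared magnitude response |H(f)|^2 of a digital Butterworth band-pass --
# the transfer function of forward-backward (zero-phase) filtering.
butter_bandpass_matrix <- function(Y, tr_s, low_hz, high_hz, order = 5) {
  t <- nrow(Y)
  fs <- 1 / tr_s
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  mu <- colMeans(Y)
  Y <- sweep(Y, 2, mu)
  np <- t - 1
  Yp <- rbind(2 * Y[rep(1, np), , drop = FALSE] - Y[(np + 1):2, , drop = FALSE],
              Y,
              2 * Y[rep(t, np), , drop = FALSE] - Y[(t - 1):(t - np), , drop = FALSE])
  N <- stats::nextn(nrow(Yp), c(2, 3, 5))
  if (N > nrow(Yp)) Yp <- rbind(Yp, matrix(0, N - nrow(Yp), ncol(Yp)))
  z <- exp(-1i * 2 * pi * (0:(N - 1)) / N)
  H <- (outer(z, seq_along(bf$b) - 1, `^`) %*% bf$b) /
       (outer(z, seq_along(bf$a) - 1, `^`) %*% bf$a)
  H2 <- as.vector(Mod(H)^2)
  out <- Re(stats::mvfft(stats::mvfft(Yp) * H2, inverse = TRUE)) / N
  out[(np + 1):(np + t), , drop = FALSE]
}

#' Temporal band-pass filter
#'
#' Zero-phase (forward-backward) Butterworth band-pass, order 5, applied in
#' the frequency domain with reflection padding. The default 0.01-0.08 Hz
#' band isolates the low-frequency spontaneous fluctuations of interest.
#'
#' @param series a [bold_series()]
#' @param low_hz,high_hz pass band edges; `high_hz` must be below Nyquist
#' @param order Butterworth order
#' @return the filtered [bold_series()]
#' @export
bandpass <- function(series, low_hz = 0.01, high_hz = 0.08, order = 5) {
  nyq <- 1 / (2 * series$tr_s)
  if (!(low_hz >= 0 && low_hz < high_hz))
    stop("need 0 <= low_hz < high_hz")
  if (high_hz >= nyq)
    stop(sprintf("high_hz (%g) must be below the Nyquist frequency (%g)",
                 high_hz, nyq))
  replace_in_mask(series, function(Y)
    butter_bandpass_matrix(Y, series$tr_s, low_hz, high_hz, order))
}

#' Nuisance regression
#'
#' Replaces every in-mask voxel series with its OLS residual against the
#' column space of `[intercept | regressors]` (six motion parameters, global
#' mean, WM and CSF signals in the standard pipeline). Collinear regressor
#' columns are dropped with a warning.
#'
#' @param series a [bold_series()]
#' @param regressors numeric matrix with one row per volume (may have zero
#'   columns, in which case only the mean is removed)
#' @return the residualized [bold_series()]
#' @export
regress_nuisance <- function(series, regressors) {
  t <- n_volumes(series)
  regressors <- as.matrix(regressors)
  if (length(regressors) == 0)
    regressors <- matrix(numeric(0), nrow = t, ncol = 0)
  stopifnot(nrow(regressors) == t, all(is.finite(regressors)))
  if (ncol(regressors) >= t) stop("more regressors than time points")
  X <- cbind(intercept = 1, regressors)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- setdiff(seq_len(ncol(X)), qx$pivot[seq_len(qx$rank)])
    warning("dropping ", length(drop),
            " collinear nuisance column(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  }
  replace_in_mask(series, function(Y) project_residuals(Y, X))
}

#' Mean signal over a tissue mask
#'
#' @param series a [bold_series()]
#' @param tissue_mask logical 3D array or integer voxel indices
#' @return numeric vector, one mean per volume
#' @export
extract_tissue_signal <- function(series, tissue_mask) {
  idx <- if (is.logical(tissue_mask)) which(tissue_mask) else
    as.integer(tissue_mask)
  if (length(idx) == 0) stop("tissue mask is empty")
  Y <- series_matrix(series)
  rowMeans(Y[, idx, drop = FALSE])
}

#' Framewise RMS head displacement (dRMS)
#'
#' For each transition between neighbouring volumes, the root mean square of
#' the six backward-differenced realignment parameters, with rotations first
#' converted to arc length on a sphere (radians x radius, default 50 mm).
#'
#' @param motion a [motion_trace()]
#' @param sphere_radius_mm rotation-to-arc-length radius
#' @return numeric vector of length t - 1 (mm)
#' @export
framewise_drms <- function(motion, sphere_radius_mm = 50) {
  p <- motion$params
  if (nrow(p) < 2) stop("need at least 2 volumes")
  p[, 4:6] <- p[, 4:6] * pi / 180 * sphere_radius_mm
  dp <- diff(p)
  sqrt(rowMeans(dp^2))
}

#' Scrub motion-contaminated volumes
#'
#' A transition whose dRMS exceeds the threshold is attributed to the later
#' volume of the pair; that volume, the one before it, and the two after it
#' are flagged (clipped to the series range). Flagged volumes are deleted;
#' retained volumes keep their temporal order.
#'
#' @param series a [bold_series()]
#' @param drms framewise dRMS vector of length t - 1 (see [framewise_drms()])
#' @param threshold_mm scrubbing threshold, default 0.5 mm
#' @return list with `series` (scrubbed [bold_series()]) and `report`, a
#'   `scrub_report` carrying `drms_per_transition`, `flagged_volumes`
#'   (1-based), `retained_volumes` and `excluded_subject`
#' @export
scrub <- function(series, drms, threshold_mm = 0.5) {
  t <- n_volumes(series)
  stopifnot(length(drms) == t - 1)
  later <- which(drms > threshold_mm) + 1L
  flagged <- sort(unique(as.vector(outer(later, -1:2, `+`))))
  flagged <- flagged[flagged >= 1 & flagged <= t]
  retained <- setdiff(seq_len(t), flagged)
  report <- structure(
    list(drms_per_transition = drms, flagged_volumes = flagged,
         retained_volumes = retained, excluded_subject = FALSE,
         threshold_mm = threshold_mm),
    class = "scrub_report")
  if (length(retained) == 0) {
    report$excluded_subject <- TRUE
    stop("all volumes flagged by scrubbing; subject unusable")
  }
  series$data <- series$data[, , , retained, drop = FALSE]
  list(series = series, report = report)
}

#' Gross head-motion exclusion rule
#'
#' A subject is excluded when any cumulative realignment parameter exceeds
#' `max_mm` (translations) or `max_deg` (rotations) at any time during the
#' scan.
#'
#' @param motion a [motion_trace()]
#' @param max_mm translation limit (mm), default 2
#' @param max_deg rotation limit (degrees), default 2
#' @return `TRUE` if the subject should be excluded
#' @export
exclusion_check <- function(motion, max_mm = 2, max_deg = 2) {
  p <- motion$params
  max(abs(p[, 1:3])) > max_mm || max(abs(p[, 4:6])) > max_deg
}

#' Standard temporal preprocessing for one subject
#'
#' Applies the fixed pipeline order: discard initial volumes, linear
#' detrend, band-pass, nuisance regression (six motion parameters, optional
#' global mean, WM and CSF signals). Scrubbing is not applied here; the
#' connectivity branch applies it via [scrub()], while ReHo runs on the
#' continuous (unscrubbed) output to preserve neighbourhood rank structure.
#'
#' @param series a [bold_series()]
#' @param motion a [motion_trace()] with one row per volume of `series`
#' @param wm_mask,csf_mask tissue masks for nuisance signal extraction
#' @param n_discard number of initial volumes to drop
#' @param low_hz,high_hz band-pass edges
#' @param global_signal include the global (whole-mask) mean as a nuisance
#'   regressor
#' @return list with `series` (preprocessed), `motion` (truncated), and
#'   `drms` (framewise displacement of the truncated trace)
#' @export
preprocess_subject <- function(series, motion, wm_mask, csf_mask,
                               n_discard = 10, low_hz = 0.01,
                               high_hz = 0.08, global_signal = TRUE) {
  stopifnot(nrow(motion$params) == n_volumes(series))
  series <- discard_initial(series, n_discard)
  motion <- truncate_motion(motion, n_discard)
  series <- detrend_linear(series)
  series <- bandpass(series, low_hz, high_hz)
  reg <- motion$params
  if (global_signal)
    reg <- cbind(reg, global = extract_tissue_signal(series, series$mask))
  reg <- cbind(reg,
               wm = extract_tissue_signal(series, wm_mask),
               csf = extract_tissue_signal(series, csf_mask))
  series <- regress_nuisance(series, reg)
  list(series = series, motion = motion, drms = framewise_drms(motion))
}

#' Group head-motion comparison
#'
#' Two-sample t-test on per-subject mean dRMS, the QA check that group FC
#' differences are not explained by differential head motion.
#'
#' @param mean_drms numeric vector of per-subject mean dRMS values
#' @param group character/factor vector (`"patient"`/`"control"`)
#' @return list with the group means, t statistic and p value
#' @export
motion_group_qa <- function(mean_drms, group) {
  tt <- stats::t.test(mean_drms[group == "patient"],
                      mean_drms[group == "control"])
  list(mean_patient = unname(tt$estimate[1]),
       mean_control = unname(tt$estimate[2]),
       t = unname(tt$statistic), p = tt$p.value)
}
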