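# Shared fixtures and independent oracles used across the suite.

# Brute-force Kendall's W: explicit rank sums, no vectorization. Kept
# deliberately naive so it stays an independent check on kendalls_w().
kcc_oracle <- function(block) {
  k <- nrow(block); n <- ncol(block)
  ranks <- matrix(0, k, n)
  for (i in seq_len(k)) ranks[i, ] <- rank(block[i, ], ties.method = "first")
  S <- 0
  rbar <- k * (n + 1) / 2
  for (tt in seq_len(n)) {
    Rt <- 0
    for (i in seq_len(k)) Rt <- Rt + ranks[i, tt]
    S <- S + (Rt - rbar)^2
  }
  12 * S / (k^2 * (n^3 - n))
}

# bold_series from a time x voxel matrix over a small fully-masked grid
toy_series <- function(Y, d = NULL, tr_s = 2) {
  t <- nrow(Y)
  if (is.null(d)) {
    v <- ncol(Y)
    d <- c(v, 1L, 1L)
  }
  stopifnot(prod(d) == ncol(Y))
  bold_series(array(t(Y), c(d, t)), tr_s = tr_s, voxel_size_mm = 3,
              mask = array(TRUE, d))
}

# tiny rectangular mask helpers
full_mask <- function(d) array(TRUE, d)

# small deterministic stat_map with a planted rectangular blob of t values
planted_stat_map <- function(atlas, region, t_in = 6, t_out = 0, df = 28) {
  stat <- array(t_out, atlas$grid_shape)
  stat[atlas$regions[[region]]] <- t_in
  stat_map(stat, df = df, mask = gm_mask(atlas), contrast = "planted")
}

# truth with a pure coupling difference in one target and no other planted
# group effects (equal ReHo gains, null mediation) -- the "alternative" and
# "null" study conditions for recovery checks
coupling_truth <- function(dz_mcc = 0.3, base = 0.25) {
  cpl <- c(target_MCC = base, target_caudate = base, target_ACG_SMA = base,
           target_IPL_L = base, target_IPL_R = base, target_PCC_PCu = base)
  cpl_pat <- cpl
  cpl_pat["target_MCC"] <- base + dz_mcc / 2
  cpl_ctl <- cpl
  cpl_ctl["target_MCC"] <- base - dz_mcc / 2
  ground_truth(a = 0, b = 0, c_prime = 0,
               group_coupling = list(patient = cpl_pat, control = cpl_ctl),
               reho_hotspots = list(
                 patient = c(seed_DLPFC = 0.5, seed_RSC = 0.5),
                 control = c(seed_DLPFC = 0.5, seed_RSC = 0.5)))
}

# full connectivity branch for one subject: preprocess, scrub, smooth,
# seed-based Fisher-z map
subject_zmap <- function(cohort, i, seed_region = "seed_DLPFC",
                         fwhm_mm = 8, global_signal = TRUE) {
  atlas <- cohort$atlas
  wm <- array(FALSE, atlas$grid_shape); wm[atlas$regions$wm] <- TRUE
  csf <- array(FALSE, atlas$grid_shape); csf[atlas$regions$csf] <- TRUE
  bold <- generate_bold(cohort$subjects[i, ], atlas, cohort$truth,
                        cohort$n_volumes, cohort$tr_s)
  pp <- preprocess_subject(bold, cohort$motion[[i]], wm, csf,
                           global_signal = global_signal)
  sc <- scrub(pp$series, pp$drms, 0.5)
  sm <- smooth_series(sc$series, fwhm_mm)
  fc_zmap(sm, seed_roi(seed_region, atlas$regions[[seed_region]], "sphere"),
          gm_mask(atlas))
}
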