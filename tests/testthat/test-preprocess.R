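test_that("initial-volume discard shortens the series and validates input", {
  Y <- matrix(rnorm(240 * 8), 240, 8)
  s <- toy_series(Y, c(2L, 2L, 2L))
  expect_equal(n_volumes(discard_initial(s, 10)), 230)
  expect_identical(discard_initial(s, 0), s)
  s5 <- toy_series(Y[1:5, ], c(2L, 2L, 2L))
  expect_error(discard_initial(s5, 10), "discard")
  mo <- motion_trace(matrix(0, 240, 6))
  expect_equal(nrow(truncate_motion(mo, 10)$params), 230)
})

test_that("linear detrending removes lines exactly and leaves residuals orthogonal", {
  t <- 50
  Y <- cbind(2 * seq_len(t),           # pure line
             rep(3.7, t),              # constant
             rnorm(t))                 # arbitrary
  out <- restfc:::series_matrix(detrend_linear(toy_series(Y, c(3L, 1L, 1L))))
  expect_lt(max(abs(out[, 1:2])), 1e-10)
  X <- cbind(1, seq_len(t))
  expect_lt(max(abs(crossprod(X, out[, 3]))), 1e-8)
  fit <- lm(out[, 3] ~ seq_len(t))
  expect_lt(abs(coef(fit)[2]), 1e-10)
})

test_that("band-pass keeps in-band and rejects out-of-band sinusoids", {
  t <- 230; tr <- 2
  tt <- (seq_len(t) - 1) * tr
  Y <- cbind(sin(2 * pi * 0.04 * tt), sin(2 * pi * 0.005 * tt), rep(0, t))
  out <- restfc:::series_matrix(bandpass(toy_series(Y, c(3L, 1L, 1L))))
  expect_gt(sd(out[, 1]) / sd(Y[, 1]), 0.95)
  expect_lt(sd(out[, 2]) / sd(Y[, 2]), 0.05)
  expect_true(all(out[, 3] == 0))
  expect_error(bandpass(toy_series(Y, c(3L, 1L, 1L)), 0.01, 0.3), "Nyquist")
})

test_that("nuisance regression projects out the design exactly", {
  set.seed(2)
  t <- 120
  reg <- matrix(rnorm(t * 9), t, 9)  # 6 motion + global + wm + csf
  Y <- cbind(reg[, 1], rnorm(t), rnorm(t) + 5)
  out <- restfc:::series_matrix(
    regress_nuisance(toy_series(Y, c(3L, 1L, 1L)), reg))
  expect_lt(max(abs(out[, 1])), 1e-8)
  expect_lt(max(abs(crossprod(reg, out))), 1e-8)

  # empty regressor set: mean centring only
  out0 <- restfc:::series_matrix(
    regress_nuisance(toy_series(Y, c(3L, 1L, 1L)),
                     matrix(numeric(0), t, 0)))
  expect_equal(out0, sweep(Y, 2, colMeans(Y)), tolerance = 1e-10)

  # collinear columns are dropped with a warning
  expect_warning(
    regress_nuisance(toy_series(Y, c(3L, 1L, 1L)),
                     cbind(reg[, 1], reg[, 1] * 2)),
    "collinear")
})

test_that("tissue signal extraction averages over the mask", {
  Y <- matrix(rnorm(20 * 8), 20, 8)
  s <- toy_series(Y, c(2L, 2L, 2L))
  m1 <- array(FALSE, c(2, 2, 2)); m1[1] <- TRUE
  expect_equal(extract_tissue_signal(s, m1), Y[, 1])
  m2 <- array(FALSE, c(2, 2, 2)); m2[c(2, 5)] <- TRUE
  expect_equal(extract_tissue_signal(s, m2), (Y[, 2] + Y[, 5]) / 2)
  su <- toy_series(matrix(4.2, 20, 8), c(2L, 2L, 2L))
  expect_equal(extract_tissue_signal(su, m2), rep(4.2, 20))
  expect_error(extract_tissue_signal(s, array(FALSE, c(2, 2, 2))), "empty")
})

test_that("framewise dRMS follows the six-parameter RMS convention", {
  p <- matrix(0, 3, 6)
  expect_equal(framewise_drms(motion_trace(p)), c(0, 0))

  p2 <- matrix(0, 2, 6); p2[2, 1] <- 0.3
  expect_equal(framewise_drms(motion_trace(p2)), sqrt(0.09 / 6),
               tolerance = 1e-12)
  expect_equal(round(framewise_drms(motion_trace(p2)), 4), 0.1225)

  # 1 degree rotation at 50 mm enters as an arc of ~0.8727 mm
  p3 <- matrix(0, 2, 6); p3[2, 4] <- 1
  arc <- 50 * pi / 180
  expect_equal(framewise_drms(motion_trace(p3)), sqrt(arc^2 / 6),
               tolerance = 1e-12)
  expect_equal(round(arc, 4), 0.8727)
})

test_that("scrubbing flags one back and two forward, clipped to range", {
  Y <- matrix(rnorm(5 * 4), 5, 4)
  s <- toy_series(Y, c(2L, 2L, 1L))
  # spike on the transition between volumes 2 and 3 (1-based)
  out <- scrub(s, c(0, 0.8, 0, 0), 0.5)
  expect_equal(out$report$flagged_volumes, 2:5)
  expect_equal(out$report$retained_volumes, 1L)
  expect_equal(n_volumes(out$series), 1)

  # no exceedance: identity
  out2 <- scrub(s, rep(0.1, 4), 0.5)
  expect_equal(out2$report$flagged_volumes, integer(0))
  expect_identical(out2$series$data, s$data)

  # overlapping spikes: union without double counting
  s8 <- toy_series(matrix(rnorm(8 * 4), 8, 4), c(2L, 2L, 1L))
  out3 <- scrub(s8, c(0, 0.8, 0.8, 0, 0, 0, 0), 0.5)
  expect_equal(out3$report$flagged_volumes, 2:6)
  expect_setequal(union(out3$report$flagged_volumes,
                        out3$report$retained_volumes), 1:8)

  # everything flagged: subject unusable
  expect_error(scrub(toy_series(matrix(rnorm(4 * 4), 4, 4), c(2L, 2L, 1L)),
                     c(0.9, 0.9, 0.9), 0.5), "unusable")
})

test_that("gross-motion exclusion uses cumulative parameter magnitudes", {
  p <- matrix(0, 10, 6); p[6, 2] <- 2.5
  expect_true(exclusion_check(motion_trace(p)))
  p2 <- matrix(runif(60, -1, 1), 10, 6)
  expect_false(exclusion_check(motion_trace(p2)))
  p3 <- matrix(0, 10, 6); p3[4, 5] <- 2.1
  expect_true(exclusion_check(motion_trace(p3)))
})

test_that("group motion QA reports a two-sample comparison", {
  set.seed(4)
  drms <- c(rnorm(20, 0.1, 0.02), rnorm(20, 0.1, 0.02))
  qa <- motion_group_qa(drms, rep(c("patient", "control"), each = 20))
  expect_true(qa$p > 0.05)
  expect_true(is.finite(qa$t))
})

test_that("preprocessing wrapper applies the fixed order and is mask-respecting", {
  atlas <- default_atlas()
  co <- generate_cohort(2, 2, atlas, seed = 21, n_volumes = 60)
  bold <- generate_bold(co$subjects[1, ], atlas, co$truth, 60, 2)
  outside <- which(!atlas$brain_mask)[1:50]
  before <- restfc:::series_matrix(bold)[11:60, outside]
  wm <- array(FALSE, atlas$grid_shape); wm[atlas$regions$wm] <- TRUE
  csf <- array(FALSE, atlas$grid_shape); csf[atlas$regions$csf] <- TRUE
  pp <- preprocess_subject(bold, co$motion[[1]], wm, csf)
  expect_equal(n_volumes(pp$series), 50)
  expect_equal(nrow(pp$motion$params), 50)
  # voxels outside the mask are untouched (only the discard applies)
  after <- restfc:::series_matrix(pp$series)[, outside]
  expect_identical(after, before)
  # in-mask residuals are orthogonal to the motion regressors
  vox <- which(as.vector(pp$series$mask))[1:20]
  Y <- restfc:::series_matrix(pp$series)[, vox]
  expect_lt(max(abs(crossprod(pp$motion$params, Y))) /
              max(abs(crossprod(pp$motion$params,
                                restfc:::series_matrix(bold)[11:60, vox]))),
            1e-6)
})
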