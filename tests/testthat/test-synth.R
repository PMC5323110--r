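test_that("atlas regions are disjoint, nonempty and inside the brain", {
  atlas <- default_atlas()
  idx <- unlist(atlas$regions)
  expect_false(any(duplicated(idx)))
  expect_true(all(lengths(atlas$regions) > 0))
  gm_regions <- grep("^seed_|^target_", names(atlas$regions), value = TRUE)
  inside <- which(atlas$brain_mask)
  for (nm in gm_regions)
    expect_true(all(atlas$regions[[nm]] %in% inside))
  expect_false(any(atlas$regions$background %in% inside))
})

test_that("cohort generation is deterministic for a fixed seed", {
  atlas <- default_atlas()
  co1 <- generate_cohort(3, 3, atlas, seed = 7, n_volumes = 60)
  co2 <- generate_cohort(3, 3, atlas, seed = 7, n_volumes = 60)
  expect_identical(co1$subjects, co2$subjects)
  expect_identical(co1$motion, co2$motion)
  expect_identical(co1$gm, co2$gm)
  b1 <- generate_bold(co1$subjects[1, ], atlas, co1$truth, 60, 2)
  b2 <- generate_bold(co2$subjects[1, ], atlas, co2$truth, 60, 2)
  expect_identical(b1$data, b2$data)
})

test_that("cohort generation validates its configuration", {
  expect_error(generate_cohort(1, 5), "at least 2")
  expect_error(generate_bold(list(group = "patient"), default_atlas(),
                             ground_truth(), n_volumes = 60, tr_s = 7,
                             seed = 1),
               "Nyquist")
  expect_error(generate_bold(list(group = "patient"), default_atlas(),
                             ground_truth(), n_volumes = 10, tr_s = 2,
                             seed = 1))
})

test_that("motion traces: clean walks scrub nothing, a spike flags 4 volumes", {
  mo <- generate_motion(100, seed = 3)
  expect_true(all(framewise_drms(mo) < 0.5))

  mo2 <- generate_motion(100, spike_times = 51, spike_mm = 1.0, seed = 3)
  drms <- framewise_drms(mo2)
  expect_equal(which(drms > 0.5), 50)   # transition into volume 51
  dummy <- toy_series(matrix(rnorm(100 * 4), 100, 4))
  out <- scrub(dummy, drms, 0.5)
  expect_equal(out$report$flagged_volumes, c(50L, 51L, 52L, 53L))
  expect_equal(n_volumes(out$series), 96)

  mo3 <- generate_motion(100, spike_times = 50, spike_mm = 3.0, seed = 3)
  expect_true(exclusion_check(mo3, 2, 2))
  expect_false(exclusion_check(mo, 2, 2))
})

test_that("GM maps stay strictly inside (0,1) and atrophy is detectable", {
  atlas <- default_atlas()
  g <- generate_gm_map(atlas, 0.1, "patient", seed = 1)
  expect_true(all(g > 0 & g < 1))
  expect_true(all(is.finite(logit_gm(g, fwhm_mm = 0))))

  # atrophy_effect = 0: group means agree in expectation
  m0 <- replicate(6, {
    s <- sample.int(1e6, 1)
    mean(generate_gm_map(atlas, 0, "patient", s)[atlas$regions$seed_DLPFC]) -
      mean(generate_gm_map(atlas, 0, "control", s + 1)[atlas$regions$seed_DLPFC])
  })
  expect_lt(abs(mean(m0)), 0.05)

  # atrophy_effect = 0.1 detected by a two-sample t-test at n = 40/group
  set.seed(11)
  pat <- replicate(40, mean(generate_gm_map(atlas, 0.1, "patient",
                     sample.int(1e6, 1))[atlas$regions$seed_DLPFC]))
  ctl <- replicate(40, mean(generate_gm_map(atlas, 0.1, "control",
                     sample.int(1e6, 1))[atlas$regions$seed_DLPFC]))
  tt <- t.test(pat, ctl, alternative = "less")
  expect_lt(tt$p.value, 0.001)
})

test_that("phenotype calibration reproduces the cohort profile", {
  # large cohort: composite group means/SDs close to the calibration targets
  co <- generate_cohort(2000, 3000, seed = 5, n_volumes = 60,
                        phenotypes_only = TRUE)
  ph <- add_composites(co$subjects)
  em <- tapply(ph$EM, ph$group, mean)
  ef <- tapply(ph$EF, ph$group, mean)
  # targets are reachable up to the (~0.01) nonzero weighted mean of the
  # printed values, which pooled centring removes
  expect_lt(abs(em[["patient"]] - -0.74), 0.05)
  expect_lt(abs(em[["control"]] - 0.50), 0.05)
  expect_lt(abs(ef[["patient"]] - 0.44), 0.05)
  expect_lt(abs(ef[["control"]] - -0.27), 0.05)
  expect_lt(abs(tapply(ph$EM, ph$group, sd)[["patient"]] - 0.71), 0.06)
  expect_lt(cor(ph$EM, ph$EF), -0.3)
})

test_that("null generative model leaves phenotypes independent of FC", {
  truth0 <- ground_truth(a = 0, b = 0, c_prime = 0)
  co <- generate_cohort(2000, 2000, truth = truth0, seed = 9,
                        n_volumes = 60, phenotypes_only = TRUE)
  ph <- add_composites(co$subjects)
  pat <- ph$group == "patient"
  expect_lt(abs(cor(ph$EM[pat], ph$fc_MCC[pat])), 0.05)
  expect_lt(abs(cor(ph$EF[pat], ph$fc_MCC[pat])), 0.05)
})

test_that("atlas region error surfaces as a configuration error", {
  atlas <- default_atlas()
  small <- atlas
  small$regions$target_MCC <- small$regions$target_MCC[1:4]
  expect_error(generate_cohort(3, 3, small), "too small")
})
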