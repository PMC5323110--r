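test_that("seed time course is the ROI mean", {
  Y <- matrix(rnorm(30 * 8), 30, 8)
  s <- toy_series(Y, c(2L, 2L, 2L))
  expect_equal(seed_timeseries(s, 3L), Y[, 3])
  expect_equal(seed_timeseries(s, c(2L, 6L)), rowMeans(Y[, c(2, 6)]))
  # mean of two orthogonal unit-variance series has variance 1/2
  a <- sin(2 * pi * (1:400) / 50); b <- cos(2 * pi * (1:400) / 50)
  a <- a / sd(a); b <- b / sd(b)
  s2 <- toy_series(cbind(a, b, a, b, a, b, a, b), c(2L, 2L, 2L))
  expect_equal(var(seed_timeseries(s2, c(1L, 2L))), 0.5, tolerance = 0.01)
  expect_error(seed_timeseries(s, integer(0)), "empty")
})

test_that("fc_map recovers exact and null correlations", {
  set.seed(5)
  t <- 220
  ref <- rnorm(t)
  Y <- cbind(ref, -ref, 2 * ref + 3, matrix(rnorm(t * 5), t, 5))
  s <- toy_series(Y, c(8L, 1L, 1L))
  fm <- fc_map(s, ref)
  expect_equal(fm$r[1], 1, tolerance = 1e-12)
  expect_equal(fm$r[2], -1, tolerance = 1e-12)
  expect_equal(fm$r[3], 1, tolerance = 1e-12)  # affine invariance
  expect_true(all(abs(fm$r[4:8]) < 0.2))       # null correlations
  # zero-variance voxel flagged as r = 0
  Y2 <- Y; Y2[, 5] <- 7
  fm2 <- fc_map(toy_series(Y2, c(8L, 1L, 1L)), ref)
  expect_equal(fm2$r[5], 0)
  expect_equal(fm2$flagged, 5L)
})

test_that("Fisher z: closed form, oddness, clamping", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(1.5 / 0.5), tolerance = 1e-12)
  expect_equal(round(fisher_z(0.5), 4), 0.5493)
  r <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(fisher_z(-r), -fisher_z(r), tolerance = 1e-12)
  expect_warning(z1 <- fisher_z(1), "clamped")
  expect_true(is.finite(z1))
})

test_that("positive-connectivity mask keeps only significant positive voxels", {
  atlas <- default_atlas()
  mask <- gm_mask(atlas)
  d <- atlas$grid_shape
  set.seed(6)
  network <- atlas$regions$target_MCC
  make_map <- function(mu) {
    m <- array(0, d)
    m[mask] <- rnorm(sum(mask), 0, 0.15)
    m[network] <- mu + rnorm(length(network), 0, 0.15)
    m
  }
  maps <- lapply(rep(0.4, 40), make_map)
  os <- one_sample_map(maps, mask, alpha_fwe = 0.01)
  pos <- positive_mask(os)
  expect_gte(mean(pos[network]), 0.95)   # planted network recovered
  # negative-mean maps give an empty set
  neg <- lapply(1:5, function(i) { m <- array(0, d); m[mask] <- -0.5; m })
  osn <- one_sample_map(neg, mask)
  expect_warning(pn <- positive_mask(osn), "empty")
  expect_false(any(pn))
  # mixed maps: no voxel with a negative group mean survives
  mixed <- lapply(1:20, function(i) {
    m <- array(0, d)
    m[mask] <- rep(c(0.5, -0.5), length.out = sum(mask)) +
      rnorm(sum(mask), 0, 0.1)
    m
  })
  osm <- one_sample_map(mixed, mask)
  pm <- positive_mask(osm)
  expect_true(any(pm))
  expect_true(all(osm$map$beta[pm] > 0))
})

test_that("planted subject couplings are recovered without systematic distortion", {
  # wide coupling spread for slope identifiability; region-mean time courses
  # remove voxel-private noise, isolating the generator-to-correlation map
  atlas <- default_atlas()
  cpl <- c(target_MCC = 0.2, target_caudate = 0.2, target_ACG_SMA = 0.2,
           target_IPL_L = 0.2, target_IPL_R = 0.2, target_PCC_PCu = 0.2)
  truth <- ground_truth(a = 0, b = 0, c_prime = 0, sd_fc = 0.45,
                        group_coupling = list(patient = cpl, control = cpl))
  co <- generate_cohort(4, 4, atlas, truth, seed = 31, n_volumes = 240)
  wm <- array(FALSE, atlas$grid_shape); wm[atlas$regions$wm] <- TRUE
  csf <- array(FALSE, atlas$grid_shape); csf[atlas$regions$csf] <- TRUE
  rec <- vapply(1:8, function(i) {
    bold <- generate_bold(co$subjects[i, ], atlas, truth, 240, 2)
    pp <- preprocess_subject(bold, co$motion[[i]], wm, csf,
                             global_signal = FALSE)
    atanh(cor(extract_tissue_signal(pp$series, atlas$regions$seed_DLPFC),
              extract_tissue_signal(pp$series, atlas$regions$target_MCC)))
  }, numeric(1))
  planted <- co$subjects$fc_MCC
  expect_gt(cor(rec, planted), 0.7)
  slope <- unname(coef(lm(rec ~ planted))[2])
  expect_gt(slope, 0.7)
  expect_lt(slope, 1.3)
  # the shared global fluctuation inflates raw correlations slightly
  expect_lt(abs(mean(rec - planted)), 0.25)
})
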