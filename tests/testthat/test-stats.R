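test_that("half-logit GM transform matches closed forms", {
  expect_equal(logit_gm(array(0.5, c(2, 2, 2)), fwhm_mm = 0),
               array(0, c(2, 2, 2)))
  a <- exp(1) / (1 + exp(1))
  expect_equal(logit_gm(array(a, c(2, 2, 2)), fwhm_mm = 0)[1], 0.5,
               tolerance = 1e-12)
  clamped <- logit_gm(array(1, c(2, 2, 2)), fwhm_mm = 0)[1]
  expect_equal(clamped, 0.5 * log((1 - 1e-6) / 1e-6), tolerance = 1e-9)
  expect_equal(round(clamped, 3), 6.908)
})

test_that("one-sample t map equals the hand computation", {
  d <- c(3L, 3L, 3L)
  mask <- full_mask(d)
  set.seed(7)
  maps <- lapply(1:5, function(i) array(rnorm(27), d))
  os <- one_sample_map(maps, mask, alpha_fwe = 0.01)
  v <- 13
  xs <- vapply(maps, `[`, numeric(1), v)
  expect_equal(os$map$stat[v], mean(xs) / (sd(xs) / sqrt(5)),
               tolerance = 1e-12)
  expect_equal(os$map$df, 4)
  # null maps: at most stray voxels survive the Bonferroni rule
  null <- lapply(1:8, function(i) array(rnorm(27, 0, 0.01), d))
  osn <- one_sample_map(null, mask)
  expect_lte(sum(osn$significant), 1)
})

test_that("voxelwise regressions agree with a per-voxel lm() oracle", {
  atlas <- default_atlas()
  d <- atlas$grid_shape
  mask <- array(FALSE, d); mask[8:12, 8:12, 8:12] <- TRUE
  n <- 24
  set.seed(9)
  group <- rep(c("patient", "control"), each = n / 2)
  cov <- data.frame(age = runif(n, 54, 80), gender = rbinom(n, 1, 0.5),
                    education = sample(6:20, n, TRUE))
  maps <- lapply(1:n, function(i) array(rnorm(prod(d)), d))
  gms <- lapply(1:n, function(i) array(runif(prod(d), 0.3, 0.9), d))
  score <- rnorm(n)

  gg <- group_glm(maps, group, cov, gms, mask)
  br <- behavior_regression(maps, score, cov, mask)
  vox <- sample(which(mask), 12)
  for (v in vox) {
    y <- vapply(maps, `[`, numeric(1), v)
    g <- vapply(gms, `[`, numeric(1), v)
    f1 <- lm(y ~ I(group == "patient") + age + gender + education + g,
             data = cov)
    expect_equal(gg$stat[v], summary(f1)$coefficients[2, 3],
                 tolerance = 1e-10)
    expect_equal(gg$beta[v], unname(coef(f1)[2]), tolerance = 1e-10)
    f2 <- lm(y ~ score + age + gender + education, data = cov)
    expect_equal(br$stat[v], summary(f2)$coefficients[2, 3],
                 tolerance = 1e-10)
  }
  expect_equal(gg$df, n - 6)
  expect_equal(br$df, n - 5)
})

test_that("behaviour regression recovers a planted score effect and is sign-symmetric", {
  atlas <- default_atlas()
  mask <- gm_mask(atlas)
  d <- atlas$grid_shape
  region <- atlas$regions$target_MCC
  n <- 30
  set.seed(12)
  score <- rnorm(n)
  maps <- lapply(1:n, function(i) {
    m <- array(0, d)
    m[mask] <- rnorm(sum(mask), 0, 0.2)
    m[region] <- m[region] + 0.4 * score[i]
    m
  })
  br <- behavior_regression(maps, score, NULL, mask)
  ct <- cluster_table(br, voxel_p = 0.001, min_extent_voxels = 50,
                      atlas = atlas)
  expect_gt(nrow(ct$table), 0)
  expect_equal(ct$table$region_label[1], "target_MCC")
  # sign flip of the score negates the t map exactly
  br2 <- behavior_regression(maps, -score, NULL, mask)
  expect_equal(br2$stat, -br$stat, tolerance = 1e-10)
  # independent score: nothing at a strict threshold
  brn <- behavior_regression(maps, rnorm(n), NULL, mask)
  ctn <- cluster_table(brn, voxel_p = 0.001, min_extent_voxels = 50,
                       atlas = atlas)
  expect_equal(nrow(ctn$table), 0)
  expect_error(behavior_regression(maps, rep(1, n), NULL, mask), "constant")
})

test_that("GM covariate absorbs GM-driven group differences", {
  # connectivity difference induced ONLY through GM differences: including
  # the voxelwise GM covariate must attenuate the group effect toward zero
  d <- c(6L, 6L, 6L); mask <- full_mask(d)
  n <- 40
  set.seed(14)
  group <- rep(c("patient", "control"), each = n / 2)
  cov <- data.frame(age = runif(n, 54, 80), gender = rbinom(n, 1, 0.5),
                    education = sample(6:20, n, TRUE))
  gms <- lapply(seq_len(n), function(i)
    array(0.6 - 0.15 * (group[i] == "patient") + rnorm(prod(d), 0, 0.03), d))
  maps <- lapply(seq_len(n), function(i)
    2 * gms[[i]] + array(rnorm(prod(d), 0, 0.05), d))
  with_gm <- group_glm(maps, group, cov, gms, mask)
  without_gm <- group_glm(maps, group, cov, NULL, mask)
  expect_lt(mean(abs(with_gm$stat[mask])), 0.5 * mean(abs(without_gm$stat[mask])))

  # and when GM is independent of group, the group estimate is unchanged
  # in expectation
  gms2 <- lapply(seq_len(n), function(i)
    array(0.6 + rnorm(prod(d), 0, 0.05), d))
  maps2 <- lapply(seq_len(n), function(i)
    array(0.2 * (group[i] == "patient") + rnorm(prod(d), 0, 0.2), d))
  b_with <- group_glm(maps2, group, cov, gms2, mask)$beta[mask]
  b_without <- group_glm(maps2, group, cov, NULL, mask)$beta[mask]
  expect_lt(abs(mean(b_with - b_without)), 0.02)
  expect_error(group_glm(maps2, group, transform(cov, gender = 1),
                         NULL, mask), "collinear")
})

test_that("partial correlation reduces to Pearson and respects covariates", {
  set.seed(20)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  pc <- partial_correlation(x, y)
  expect_equal(pc$r_partial, cor(x, y), tolerance = 1e-12)
  expect_equal(pc$df, 38)
  ct <- cor.test(x, y)
  expect_equal(pc$p, ct$p.value, tolerance = 1e-10)

  z <- rnorm(40)
  pc2 <- partial_correlation(x, z, covariates = data.frame(z = z))
  expect_lt(abs(pc2$r_partial), 1e-10)

  # 6-point example against an explicit residual-correlation computation
  xs <- c(1, 2, 3, 5, 8, 13); ys <- c(2, 1, 4, 3, 7, 9)
  cv <- data.frame(c1 = c(0, 1, 0, 1, 1, 0))
  rx <- resid(lm(xs ~ c1, cv)); ry <- resid(lm(ys ~ c1, cv))
  pc3 <- partial_correlation(xs, ys, cv)
  expect_equal(pc3$r_partial, cor(rx, ry), tolerance = 1e-12)
  expect_equal(pc3$df, 3)
})

test_that("cluster tables: arithmetic, sorting, conjunction behaviour", {
  atlas <- default_atlas()
  # a planted blob of known size
  blob <- restfc:::box_indices(atlas$grid_shape, 10:14, 12:17, 15:18)
  stat <- array(0, atlas$grid_shape); stat[blob] <- 5
  sm <- stat_map(stat, df = 28, mask = gm_mask(atlas))
  ct <- cluster_table(sm, voxel_p = 0.005, min_extent_voxels = 10,
                      atlas = atlas)
  expect_equal(nrow(ct$table), 1)
  expect_equal(ct$table$extent_voxels, 120)
  expect_equal(ct$table$extent_mm3, 3240)
  # empty suprathreshold set
  ct0 <- cluster_table(stat_map(array(0, atlas$grid_shape), 28,
                                gm_mask(atlas)), atlas = atlas)
  expect_equal(nrow(ct0$table), 0)

  # conjunction: disjoint empty, identical is itself
  a <- array(FALSE, atlas$grid_shape); a[atlas$regions$target_MCC] <- TRUE
  b <- array(FALSE, atlas$grid_shape); b[atlas$regions$target_IPL_L] <- TRUE
  expect_false(any(conjunction(a, b, atlas)$mask))
  cj <- conjunction(a, a, atlas)
  expect_identical(cj$mask, a)
  expect_equal(sum(cj$table$extent_voxels), sum(a))
  expect_equal(cj$table$region_label[1], "target_MCC")
})
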