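test_that("a field in the shim span is cancelled exactly", {
  g <- tiny_grid(10)
  b <- build_basis(g, 2)
  f <- field_map(-2.5 * array(b$B[, "XZ"], g$shape), g)
  msk <- array(TRUE, g$shape)
  sh <- compute_shim(f, b, msk, max_order = 2)
  expect_equal(unname(sh$coefficients["XZ"]), 2.5, tolerance = 1e-10)
  expect_lt(residual_std(f, sh, b, msk), 1e-9)
})

test_that("compute_shim matches the pseudo-inverse oracle", {
  g <- voxel_grid(c(12, 12, 12), 4)
  b <- build_basis(g, 2)
  for (seed in 1:5) {
    f <- random_field(g, seed)
    msk <- fieldshim:::with_seed(seed, array(runif(prod(g$shape)) < 0.6,
                                             g$shape))
    sh <- compute_shim(f, b, msk, max_order = 2)
    oracle <- -oracle_lsq(b$B[, 1:9], as.vector(f$values), which(msk))
    expect_lt(max(abs(sh$coefficients - oracle)), 1e-8)
  }
})

test_that("residual_std uses the population convention", {
  g <- tiny_grid(6)
  b <- build_basis(g, 1)
  f <- field_map(array(7, g$shape), g)  # constant residual
  expect_equal(residual_std(f, zero_shim(1), b, array(TRUE, g$shape)), 0)
  two <- array(FALSE, g$shape); two[1:2, 1, 1] <- TRUE
  fv <- array(0, g$shape); fv[1, 1, 1] <- -1; fv[2, 1, 1] <- 1
  expect_equal(residual_std(field_map(fv, g), zero_shim(1), b, two), 1.0)
  expect_error(residual_std(f, zero_shim(1), b, array(FALSE, g$shape)),
               class = "fs_empty_mask")
})

test_that("the least-squares shim beats every random shim", {
  g <- voxel_grid(c(12, 12, 12), 4)
  b <- build_basis(g, 2)
  f <- random_field(g, 77)
  msk <- ellipsoid_fraction(g, c(0, 0, 0), rep(18, 3)) > 0.5
  best <- compute_shim(f, b, msk, 2)
  r_best <- residual_std(f, best, b, msk)
  rng <- rbind(min = -abs(best$coefficients) * 3 - 1,
               max = abs(best$coefficients) * 3 + 1)
  colnames(rng) <- names(best$coefficients)
  for (s in random_shims(100, rng, seed = 5))
    expect_lte(r_best, residual_std(f, s, b, msk))
})

test_that("residual std is non-increasing in shim order", {
  g <- voxel_grid(c(12, 12, 12), 4)
  b <- build_basis(g, 3)
  msk <- ellipsoid_fraction(g, c(0, 0, 0), rep(18, 3)) > 0.5
  for (seed in 1:5) {
    f <- random_field(g, seed + 30)
    res <- vapply(1:3, function(k) {
      sh <- compute_shim(f, b, msk, k)
      residual_std(f, sh, b, msk)
    }, 0)
    expect_true(all(diff(res) <= 1e-9))
  }
})

test_that("minimizing RMS with a DC term equals minimizing the std", {
  g <- tiny_grid(10)
  b <- build_basis(g, 2)
  f <- random_field(g, 12)
  msk <- ellipsoid_fraction(g, c(0, 0, 0), rep(16, 3)) > 0.5
  sh <- compute_shim(f, b, msk, 2)
  # mean-subtracted fit without DC gives the same non-DC coefficients
  fc <- f$values
  fc[msk] <- fc[msk] - mean(fc[msk])
  Bc <- b$B[which(msk), -1]
  Bc <- sweep(Bc, 2, colMeans(Bc))
  oracle <- -solve(crossprod(Bc), crossprod(Bc, fc[msk]))[, 1]
  expect_lt(max(abs(sh$coefficients[-1] - oracle)), 1e-8)
})

test_that("random shims are uniform within the per-term bounds", {
  rng <- rbind(min = c(Z = -2, Z2 = 0.01), max = c(Z = 1, Z2 = 0.01))
  draws <- random_shims(500, rng, seed = 9)
  M <- fieldshim:::shim_matrix(draws)
  expect_true(all(M[, "Z"] >= -2 & M[, "Z"] <= 1))
  expect_true(all(M[, "Z2"] == 0.01))  # min == max collapses
  expect_identical(fieldshim:::shim_matrix(random_shims(500, rng, seed = 9)),
                   M)
  big <- fieldshim:::shim_matrix(random_shims(10000, rng, seed = 10))
  u <- (big[, "Z"] + 2) / 3
  ks <- max(abs(sort(u) - (seq_along(u) - 0.5) / length(u))) +
    0.5 / length(u)
  expect_lt(ks, 1.6276 / sqrt(length(u)))  # KS critical value, alpha 0.01
  expect_error(random_shims(0, rng), class = "fs_invalid_argument")
})

test_that("averaged fixed shims are termwise means", {
  s1 <- shim_setting(c(Z = 1)); s3 <- shim_setting(c(Z = 3))
  expect_equal(averaged_fixed_shim(list(s1))$coefficients, c(Z = 1))
  expect_equal(averaged_fixed_shim(list(s1, s3))$coefficients, c(Z = 2))
  sets <- fieldshim:::with_seed(3, replicate(50, shim_setting(
    c(Z = rnorm(1), Z2 = rnorm(1), XY = rnorm(1))), simplify = FALSE))
  avg <- averaged_fixed_shim(sets)
  M <- fieldshim:::shim_matrix(sets)
  expect_lt(max(abs(avg$coefficients - colMeans(M))), 1e-12)
  expect_error(averaged_fixed_shim(list(s1, shim_setting(c(X = 1)))),
               class = "fs_term_mismatch")
})

test_that("signed-rank test matches exact enumeration", {
  expect_equal(wilcoxon_paired(1:6, 1:6)$p_value, 1)
  # six uniformly positive differences: p = 2 / 2^6
  w6 <- wilcoxon_paired(c(2, 3, 4, 5, 6, 7), c(1, 1, 1, 1, 1, 1))
  expect_equal(w6$p_value, 0.03125)
  fieldshim:::with_seed(17, for (rep in 1:10) {
    n <- sample(5:10, 1)
    a <- rnorm(n); bb <- a + rnorm(n, 0.3)
    got <- wilcoxon_paired(a, bb)
    want <- oracle_signed_rank(a, bb)
    expect_equal(got$statistic, want$statistic)
    expect_equal(got$p_value, want$p_value)
  })
  # large-sample branch stays close to the exact tail
  a <- rnorm(30); bb <- a + 0.8
  fieldshim:::with_seed(1, a <- rnorm(30))
  p_norm <- wilcoxon_paired(a, a + 0.8)$p_value
  expect_lt(p_norm, 0.001)
})

test_that("leave-one-out evaluation respects optimality and no leakage", {
  cfg <- coarse_cfg(n_subjects = 4, seed = 31)
  coh <- sample_cohort(cfg)
  ev <- loocv_evaluate(coh, n_random = 25)
  expect_s3_class(ev, "shim_evaluation")
  expect_setequal(unique(ev$results$strategy), shim_strategies())
  meas <- ev$results[ev$results$strategy == "measured", ]
  for (s in setdiff(shim_strategies(),
                    c("measured", "individual_registered",
                      "individual_fixed", "random"))) {
    other <- ev$results[ev$results$strategy == s, ]
    expect_true(all(meas$residual_std_Hz <=
                      other$residual_std_Hz + 1e-9), label = s)
  }
  # distributions: every single donor/draw is also bounded below
  for (id in meas$subject) {
    dd <- ev$distributions[ev$distributions$subject == id, ]
    expect_true(all(meas$residual_std_Hz[meas$subject == id] <=
                      dd$residual_std_Hz + 1e-9))
  }
  # no leakage: subject 1's fold reproduced by hand from subjects 2..4
  grid <- coh$standard$grid
  basis <- build_basis(grid, 2)
  train <- coh$subjects[-1]
  tpl <- build_template(lapply(train, function(s)
    list(field = s$field_true, transform = s$transform)), grid)
  s1 <- coh$subjects[[1]]
  pred <- predict_fieldmap(tpl, s1$structural, subject_grid = grid,
                           transform = s1$transform)
  sh <- compute_shim(pred, basis, s1$brain_mask & pred$brain_mask, 2)
  by_hand <- residual_std(s1$field_true, sh, basis, s1$brain_mask)
  got <- ev$results$residual_std_Hz[ev$results$subject == s1$id &
                                    ev$results$strategy ==
                                      "averaged_registered"]
  expect_equal(got, by_hand, tolerance = 1e-12)
  expect_error(loocv_evaluate(coh$subjects[1:2]),
               class = "fs_invalid_argument")
})

test_that("identical subjects make registered prediction equal measurement", {
  cfg <- coarse_cfg(n_subjects = 3, seed = 6, rotation_sd_deg = 0,
                    translation_sd_mm = 0, scale_sd = 0,
                    cavity_scale_range = c(1, 1), noise_sigma_Hz = 0)
  coh <- sample_cohort(cfg)
  ev <- loocv_evaluate(coh, strategies = c("measured",
                                           "averaged_registered"),
                       n_random = 10)
  m <- ev$results[ev$results$strategy == "measured", "residual_std_Hz"]
  a <- ev$results[ev$results$strategy == "averaged_registered",
                  "residual_std_Hz"]
  expect_equal(a, m, tolerance = 1e-6)
})
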