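test_that("transform algebra: composition, inversion, label bookkeeping", {
  a <- fieldshim:::with_seed(1, affine_transform(
    fieldshim:::affine_from_params(c(rnorm(6), rnorm(6, 0, 0.05))),
    "subject", "structural"))
  b <- fieldshim:::with_seed(2, affine_transform(
    fieldshim:::affine_from_params(c(rnorm(6), rnorm(6, 0, 0.05))),
    "structural", "standard"))
  cc <- fieldshim:::with_seed(3, affine_transform(
    fieldshim:::affine_from_params(c(rnorm(6), rnorm(6, 0, 0.05))),
    "standard", "atlas"))
  expect_lt(max(abs(compose(a, invert(a))$matrix - diag(4))), 1e-10)
  chain <- compose(a, b)
  expect_identical(c(chain$source, chain$target),
                   c("subject", "standard"))
  expect_error(compose(b, a), class = "fs_chain_error")
  # associativity
  m1 <- compose(compose(a, b), cc)$matrix
  m2 <- compose(a, compose(b, cc))$matrix
  expect_lt(max(abs(m1 - m2)), 1e-10)
  # rigid validation rejects a scaled matrix
  expect_error(affine_transform(diag(c(1.1, 1, 1, 1)), dof = 6L),
               class = "fs_bad_transform")
})

test_that("resampling is exact where trilinear can be exact", {
  g <- tiny_grid(12)
  f <- random_field(g, 5)
  idt <- identity_transform("a", "b")
  same <- resample(f, idt, g, "trilinear")
  expect_equal(same$values, f$values, tolerance = 1e-12)
  # affine-linear fields are reproduced exactly at interior voxels
  co <- fieldshim:::grid_coords(g)
  lin <- 2 + 0.3 * co[, 1] - 0.7 * co[, 2] + 0.11 * co[, 3]
  dim(lin) <- g$shape
  trf <- affine_transform(fieldshim:::affine_from_params(
    c(4, -3, 7, 2.5, -1.5, 3, 0.03, -0.02, 0.01, 0.01, 0, -0.02)),
    "a", "b")
  warped <- resample(volume(lin, g), trf, g, "trilinear")
  M <- solve(trf$matrix)
  co_src <- co %*% t(M[1:3, 1:3]) + matrix(M[1:3, 4], nrow(co), 3,
                                           byrow = TRUE)
  expected <- 2 + 0.3 * co_src[, 1] - 0.7 * co_src[, 2] +
    0.11 * co_src[, 3]
  dim(expected) <- g$shape
  ok <- !is.na(warped$values)
  expect_gt(sum(ok), 100)
  expect_lt(max(abs(warped$values[ok] - expected[ok])), 1e-6)
  # nearest-neighbour keeps masks binary
  msk <- array(runif(prod(g$shape)) > 0.5, g$shape)
  wm <- resample(volume(msk, g), trf, g, "nearest")
  expect_type(wm$values, "logical")
})

test_that("registering an image to itself yields the identity", {
  cfg <- coarse_cfg()
  std <- fieldshim:::standard_anatomy(cfg)
  rec <- register(std$structural, std$structural, dof = 6L)
  p <- affine_params(rec)
  expect_lt(max(abs(p$rotation_deg)), 0.1)
  expect_lt(max(abs(p$translation_mm)), 0.1)
})

test_that("known rigid and scaling transforms are recovered", {
  cfg <- coarse_cfg()
  std <- fieldshim:::standard_anatomy(cfg)
  par6 <- c(4, -2, 3, 2, -1.5, 2.5)
  trf <- affine_transform(
    fieldshim:::affine_from_params(c(par6, rep(0, 6)), dof = 6L),
    "subject", "standard", dof = 6L)
  mv <- fieldshim:::structural_proxy(
    make_head_model(std$grid, cfg, transform = trf))
  rec <- register(mv, std$structural, dof = 6L)
  p <- affine_params(rec)
  expect_lt(max(abs(p$rotation_deg - par6[1:3])), 0.5)
  expect_lt(max(abs(p$translation_mm - par6[4:6])), 0.5)
  # 12 dof on an anisotropically scaled copy recovers the scales
  scales <- c(1.08, 0.94, 1.04)
  trf12 <- affine_transform(fieldshim:::affine_from_params(
    c(rep(0, 6), log(scales), rep(0, 3)), dof = 12L),
    "subject", "standard", dof = 12L)
  mv12 <- fieldshim:::structural_proxy(
    make_head_model(std$grid, cfg, transform = trf12))
  rec12 <- register(mv12, std$structural, dof = 12L)
  expect_lt(max(abs(affine_params(rec12)$scale - scales)), 0.01)
  expect_error(register(volume(array(1, std$grid$shape), std$grid),
                        std$structural),
               class = "fs_registration_failure")
})

test_that("templates average registered maps and localize variation", {
  g <- tiny_grid(12)
  f <- random_field(g, 8)
  msk <- ellipsoid_fraction(g, c(0, 0, 0), rep(18, 3)) > 0.5
  fm <- field_map(f$values, g, brain_mask = msk)
  idt <- identity_transform("subject", "standard")
  tpl <- build_template(list(list(field = fm, transform = idt),
                             list(field = fm, transform = idt),
                             list(field = fm, transform = idt)), g)
  expect_equal(tpl$mean$values[msk], f$values[msk], tolerance = 1e-10)
  expect_lt(max(tpl$std), 1e-5)  # floating cancellation only
  expect_true(all(tpl$count[msk] == 3))
  expect_true(all(tpl$count <= 3))
  expect_error(build_template(list(), g), class = "fs_no_subjects")
  # permutation invariance and linearity in the fields
  f2 <- random_field(g, 9)
  fm2 <- field_map(f2$values, g, brain_mask = msk)
  t12 <- build_template(list(list(field = fm, transform = idt),
                             list(field = fm2, transform = idt)), g)
  t21 <- build_template(list(list(field = fm2, transform = idt),
                             list(field = fm, transform = idt)), g)
  expect_equal(t12$mean$values, t21$mean$values)
  expect_equal(t12$mean$values[msk],
               (f$values[msk] + f2$values[msk]) / 2, tolerance = 1e-12)
})

test_that("prediction reduces to the template for an identity subject", {
  cfg <- coarse_cfg(n_subjects = 4, seed = 2, field_mode = "warp_template",
                    noise_sigma_Hz = 0)
  coh <- sample_cohort(cfg)
  std <- coh$standard
  tpl <- build_template(lapply(coh$subjects, function(s)
    list(field = s$field_true, transform = s$transform)),
    std$grid, structural = std$structural, brain_mask = std$brain_mask)
  pred <- predict_fieldmap(tpl, std$structural, subject_grid = std$grid,
                           transform = identity_transform("subject",
                                                          "standard"))
  expect_equal(pred$provenance, "predicted")
  m <- pred$brain_mask & std$brain_mask
  expect_gt(sum(m), 1000)
  expect_equal(pred$values[m], tpl$mean$values[m], tolerance = 1e-10)
})
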