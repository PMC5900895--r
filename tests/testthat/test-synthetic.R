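test_that("head model is deterministic and geometrically plausible", {
  cfg <- coarse_cfg()
  g <- voxel_grid(cfg$grid_shape, cfg$voxel_size_mm)
  m1 <- make_head_model(g, cfg)
  m2 <- make_head_model(g, cfg)
  expect_identical(m1$chi, m2$chi)
  # brain inside head; cavities disjoint from brain
  expect_true(all(m1$head[m1$brain]))
  expect_false(any(m1$brain & m1$frontal_sinus))
  expect_false(any(m1$brain & m1$ear_canals))
  # sinus centroid anterior (+y) and inferior (-z) to the brain centroid
  co <- fieldshim:::grid_coords(g)
  cen <- function(msk) colMeans(co[as.vector(msk), , drop = FALSE])
  expect_gt(cen(m1$frontal_sinus)[2], cen(m1$brain)[2])
  expect_lt(cen(m1$frontal_sinus)[3], cen(m1$brain)[3])
  # too-small grid is refused
  expect_error(make_head_model(voxel_grid(c(16, 16, 16), 2), cfg),
               class = "fs_bad_config")
})

test_that("zero perturbation amplitudes leave chi constant inside the head", {
  cfg <- coarse_cfg(sinus_amplitude_Hz = 0, ear_amplitude_Hz = 0)
  g <- voxel_grid(cfg$grid_shape, cfg$voxel_size_mm)
  m <- make_head_model(g, cfg)
  # constant away from the air boundary (partial-volume ramp excluded)
  interior <- ellipsoid_fraction(g, c(0, 0, 8), c(46, 56, 49)) > 0.999
  expect_equal(max(abs(m$chi[interior])), 0)
  expect_equal(max(abs(m$chi[m$brain])), 0)
})

test_that("dipole field is zero for zero chi and exactly linear", {
  g <- tiny_grid(16, vox = 4)
  zero <- dipole_field(array(0, g$shape), grid = g)
  expect_true(all(zero$values == 0))
  f1 <- fieldshim:::with_seed(1, array(rnorm(prod(g$shape)), g$shape))
  f2 <- fieldshim:::with_seed(2, array(rnorm(prod(g$shape)), g$shape))
  d1 <- dipole_field(f1, grid = g)$values
  d2 <- dipole_field(f2, grid = g)$values
  d12 <- dipole_field(f1 + f2, grid = g)$values
  expect_lt(max(abs(d12 - d1 - d2)), 1e-8 * max(abs(d12)))
})

test_that("uniform sphere has a field-free interior (Lorentz convention)", {
  g <- voxel_grid(c(48, 48, 48), 2)
  a <- 12
  chi <- ellipsoid_fraction(g, c(0, 0, 0), rep(a, 3))
  fm <- dipole_field(chi, B0_Hz_per_ppm = 297.2, grid = g)
  co <- fieldshim:::grid_coords(g)
  r <- sqrt(rowSums(co^2)); dim(r) <- g$shape
  scale <- 2 / 3 * 297.2  # pole amplitude just outside the sphere
  expect_lt(mean(abs(fm$values[r < a - 4])), 0.01 * scale)
})

test_that("cohorts are seeded-reproducible and degenerate configs collapse", {
  cfg <- coarse_cfg(n_subjects = 2, seed = 9)
  c1 <- sample_cohort(cfg)
  c2 <- sample_cohort(cfg)
  expect_identical(c1$subjects[[2]]$field_true$values,
                   c2$subjects[[2]]$field_true$values)
  expect_identical(c1$subjects[[1]]$baseline_shim$coefficients,
                   c2$subjects[[1]]$baseline_shim$coefficients)
  # all variation off: the subject *is* the template anatomy
  cfg0 <- coarse_cfg(n_subjects = 1, seed = 4, rotation_sd_deg = 0,
                     translation_sd_mm = 0, scale_sd = 0,
                     cavity_scale_range = c(1, 1), noise_sigma_Hz = 0)
  c0 <- sample_cohort(cfg0)
  expect_equal(c0$subjects[[1]]$field_true$values,
               c0$standard$field$values, tolerance = 1e-10)
  expect_equal(max(abs(c0$subjects[[1]]$transform$matrix - diag(4))), 0)
})

test_that("sampled rotation angles have the configured distribution", {
  cfg <- coarse_cfg(n_subjects = 50, seed = 21, rotation_sd_deg = 5,
                    field_mode = "warp_template", noise_sigma_Hz = 0)
  coh <- sample_cohort(cfg)
  rot <- t(vapply(coh$subjects, function(s) s$params[1:3], numeric(3)))
  # mean of n=50 draws from N(0, 5^2) stays within 3 sigma/sqrt(n)
  expect_true(all(abs(colMeans(rot)) < 3 * 5 / sqrt(50)))
})

test_that("intersubject field variation concentrates near the cavities", {
  cfg <- coarse_cfg(n_subjects = 8, seed = 13, rotation_sd_deg = 0,
                    translation_sd_mm = 0, scale_sd = 0,
                    cavity_scale_range = c(0.5, 1.5), noise_sigma_Hz = 0)
  coh <- sample_cohort(cfg)
  tpl <- build_template(lapply(coh$subjects, function(s)
    list(field = field_map(s$field_true$values, s$field_true$grid),
         transform = s$transform)), coh$standard$grid)
  m <- coh$standard$model
  near_cavity <- m$frontal_sinus | m$ear_canals
  peak <- which.max(tpl$std)
  d <- fieldshim:::grid_coords(coh$standard$grid)[peak, ]
  co <- fieldshim:::grid_coords(coh$standard$grid)
  cav_idx <- which(as.vector(near_cavity))
  mind <- min(sqrt(colSums((t(co[cav_idx, , drop = FALSE]) - d)^2)))
  expect_lt(mind, 2 * mean(coh$standard$grid$voxel_size_mm))
})

test_that("dual-echo simulation matches hand-computed phase evolution", {
  g <- tiny_grid(6)
  zero <- simulate_dual_echo(field_map(array(0, g$shape), g))
  expect_true(all(zero$phase1$values == 0) && all(zero$phase2$values == 0))
  f100 <- field_map(array(100, g$shape), g)
  ph <- simulate_dual_echo(f100, TE1_ms = 4.08, dTE_ms = 1.02)
  dphi <- wrap_phase(ph$phase2$values - ph$phase1$values)
  expect_equal(dphi[1], 2 * pi * 100 * 0.00102, tolerance = 1e-12)
  expect_equal(dphi[1], 0.6409, tolerance = 1e-4)
  expect_error(simulate_dual_echo(f100, dTE_ms = 0),
               class = "fs_invalid_dTE")
})
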