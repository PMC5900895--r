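test_that("dual-echo field computation follows wrap arithmetic", {
  g <- tiny_grid(6)
  p0 <- phase_volume(array(0.5, g$shape), g)
  expect_true(all(fieldmap_from_dual_echo(p0, p0, 1.02)$values == 0))
  # alias-free range is 1/(2 dTE): +/- 490.2 Hz at dTE = 1.02 ms
  expect_equal(1000 / (2 * 1.02), 490.196, tolerance = 1e-3)
  # a 600 Hz field aliases to -380.4 Hz
  f600 <- field_map(array(600, g$shape), g)
  ph <- simulate_dual_echo(f600, dTE_ms = 1.02)
  fhat <- fieldmap_from_dual_echo(ph$phase1, ph$phase2, 1.02)
  expect_equal(fhat$values[1], 600 - 1000 / 1.02, tolerance = 1e-6)
  expect_equal(fhat$values[1], -380.4, tolerance = 0.01)
  g2 <- tiny_grid(7)
  expect_error(
    fieldmap_from_dual_echo(p0, phase_volume(array(0, g2$shape), g2), 1),
    class = "fs_grid_mismatch")
  expect_error(fieldmap_from_dual_echo(p0, p0, -1),
               class = "fs_invalid_dTE")
})

test_that("dual-echo roundtrip is the identity below the aliasing limit", {
  g <- tiny_grid(12)
  co <- fieldshim:::grid_coords(g)
  f <- 400 * sin(co[, 3] / 20) * cos(co[, 1] / 30)  # |f| < 400 Hz
  dim(f) <- g$shape
  fm <- field_map(f, g)
  ph <- simulate_dual_echo(fm, TE1_ms = 4.08, dTE_ms = 1.02)
  rec <- fieldmap_from_dual_echo(ph$phase1, ph$phase2, 1.02)
  expect_lt(max(abs(rec$values - f)), 1e-6)
})

test_that("unwrapping restores smooth phase modulo one global 2*pi", {
  g <- tiny_grid(16, vox = 2)
  co <- fieldshim:::grid_coords(g)
  mask <- array(TRUE, g$shape)
  # smooth phase with range < 2*pi passes through (up to a global 2*pi)
  small <- 2.5 * sin(co[, 3] / 20); dim(small) <- g$shape
  u1 <- unwrap_phase(phase_volume(wrap_phase(small), g), mask = mask)
  k <- (u1$values - small) / (2 * pi)
  expect_equal(max(abs(k - round(mean(k)))), 0, tolerance = 1e-9)
  # 6*pi linear ramp: unwrapped gradient equals the true gradient
  ramp <- 6 * pi * (co[, 3] + 15) / 30; dim(ramp) <- g$shape
  w <- phase_volume(wrap_phase(ramp), g)
  u2 <- unwrap_phase(w, mask = mask)
  gz_true <- diff(ramp[1, 1, 1:2])
  expect_equal(max(abs(apply(u2$values, c(1, 2), diff) - gz_true)), 0,
               tolerance = 1e-9)
  # modular identity: wrap(unwrap(w)) == w everywhere in the mask
  expect_lt(max(abs(wrap_phase(u2$values) - w$values)), 1e-9)
  expect_error(unwrap_phase(w, mask = array(FALSE, g$shape)),
               class = "fs_empty_mask")
})

test_that("unwrapping is shift-invariant up to the 2*pi convention", {
  g <- tiny_grid(12, vox = 2)
  co <- fieldshim:::grid_coords(g)
  mask <- array(TRUE, g$shape)
  ph <- 4 * pi * (co[, 2] + 11) / 22 + 0.7 * sin(co[, 1] / 8)
  dim(ph) <- g$shape
  u0 <- unwrap_phase(phase_volume(wrap_phase(ph), g), mask = mask)
  shift <- 1.3
  us <- unwrap_phase(phase_volume(wrap_phase(ph + shift), g), mask = mask)
  d <- us$values - u0$values - shift
  expect_equal(max(abs(d - 2 * pi * round(mean(d) / (2 * pi)))), 0,
               tolerance = 1e-9)
})

test_that("baseline shim removal is exact, linear and not idempotent", {
  g <- tiny_grid(10)
  b <- build_basis(g, 2)
  f <- random_field(g, 3)
  zero <- zero_shim(2)
  expect_equal(remove_baseline_shim(f, zero, b)$values, f$values)
  set_a <- shim_setting(c(Z = 0.9, Z2 = -0.01, DC = 12))
  set_b <- shim_setting(c(X = -0.4, XY = 0.003))
  # add then remove roundtrips
  contaminated <- field_map(f$values + synthesize_shim_field(set_a, b), g)
  clean <- remove_baseline_shim(contaminated, set_a, b)
  expect_lt(max(abs(clean$values - f$values)), 1e-6)
  expect_equal(clean$shim_state, "baseline-removed")
  # removing twice shifts the field by the shim field again
  twice <- remove_baseline_shim(clean, set_a, b)
  expect_equal(clean$values - twice$values,
               synthesize_shim_field(set_a, b), tolerance = 1e-10)
  # removing a then b equals removing a + b
  ab <- remove_baseline_shim(remove_baseline_shim(f, set_a, b), set_b, b)
  sum_ab <- shim_setting(c(Z = 0.9, Z2 = -0.01, DC = 12, X = -0.4,
                           XY = 0.003))
  expect_equal(ab$values, remove_baseline_shim(f, sum_ab, b)$values,
               tolerance = 1e-10)
  # unknown terms are named
  b1 <- build_basis(g, 1)
  err <- tryCatch(remove_baseline_shim(f, set_a, b1),
                  fs_unknown_term = function(e) conditionMessage(e))
  expect_match(err, "Z2")
})

test_that("coverage QC applies the 90% brain-content rule", {
  g <- tiny_grid(12)
  brain <- ellipsoid_fraction(g, c(0, 0, 0), rep(18, 3)) > 0.5
  full <- array(TRUE, g$shape)
  qc1 <- qc_coverage(volume(full, g), volume(brain, g))
  expect_equal(qc1$coverage, 1.0)
  expect_true(qc1$accept)
  crop_to <- function(frac) {
    idx <- which(brain)
    ord <- order(fieldshim:::grid_coords(g)[idx, 3])  # crop inferior slices
    fp <- array(FALSE, g$shape)
    fp[idx[ord][seq_len(ceiling(frac * length(idx)))]] <- TRUE
    fp
  }
  expect_false(qc_coverage(volume(crop_to(0.85), g),
                           volume(brain, g))$accept)
  expect_true(qc_coverage(volume(crop_to(0.95), g),
                          volume(brain, g))$accept)
  expect_error(qc_coverage(volume(full, g),
                           volume(array(FALSE, g$shape), g)),
               class = "fs_empty_mask")
})
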