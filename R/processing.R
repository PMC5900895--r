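#' Compute a (wrapped) field map from a dual-echo phase pair
#'
#' \eqn{f = wrap(\phi_2 - \phi_1) / (2\pi \Delta TE)} in Hz. The result is
#' alias-free only for \eqn{|f| < 1/(2\Delta TE)} (about +/- 490 Hz at
#' \eqn{\Delta TE} = 1.02 ms); stronger fields alias by multiples of
#' \eqn{1/\Delta TE}.
#'
#' @param phase1,phase2 [phase_volume()]s on the same grid.
#' @param dTE_ms Echo-time difference in ms (> 0).
#' @param brain_mask Optional mask attached to the result.
#' @return A [field_map()] (provenance `"measured"`).
#' @export
fieldmap_from_dual_echo <- function(phase1, phase2, dTE_ms,
                                    brain_mask = NULL) {
  if (!(is.numeric(dTE_ms) && length(dTE_ms) == 1L && dTE_ms > 0))
    stop_fieldshim("dTE_ms must be a positive scalar", "fs_invalid_dTE")
  if (!grids_equal(phase1$grid, phase2$grid) ||
      !all(dim(phase1$values) == dim(phase2$values)))
    stop_fieldshim("phase volumes are on different grids",
                   "fs_grid_mismatch")
  f <- wrap_phase(phase2$values - phase1$values) / (2 * pi * dTE_ms / 1000)
  field_map(f, phase1$grid, brain_mask = brain_mask,
            provenance = "measured", shim_state = "none")
}

# Quality map for unwrapping: magnitude-weighted inverse local variance of
# the wrapped phase gradients (6-neighbour wrapped differences).
phase_quality <- function(wrapped, magnitude = NULL) {
  v <- wrapped
  d <- dim(v)
  acc <- array(0, d); acc2 <- array(0, d); nn <- array(0, d)
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  for (s in shifts) {
    src <- list(seq_len(d[1]) + s[1], seq_len(d[2]) + s[2],
                seq_len(d[3]) + s[3])
    keep <- mapply(function(ix, n) ix >= 1 & ix <= n, src, d,
                   SIMPLIFY = FALSE)
    dst <- lapply(seq_len(3), function(a) seq_len(d[a])[keep[[a]]])
    srcc <- lapply(seq_len(3), function(a) src[[a]][keep[[a]]])
    g <- wrap_phase(v[srcc[[1]], srcc[[2]], srcc[[3]], drop = FALSE] -
                    v[dst[[1]], dst[[2]], dst[[3]], drop = FALSE])
    acc[dst[[1]], dst[[2]], dst[[3]]] <-
      acc[dst[[1]], dst[[2]], dst[[3]]] + g
    acc2[dst[[1]], dst[[2]], dst[[3]]] <-
      acc2[dst[[1]], dst[[2]], dst[[3]]] + g * g
    nn[dst[[1]], dst[[2]], dst[[3]]] <-
      nn[dst[[1]], dst[[2]], dst[[3]]] + 1
  }
  gvar <- acc2 / pmax(nn, 1) - (acc / pmax(nn, 1))^2
  q <- 1 / (1 + gvar)
  if (!is.null(magnitude)) q <- q * magnitude
  q
}

#' Unwrap a 3D phase volume
#'
#' Quality-guided region-growing unwrapper (same contract as established
#' region-expanding unwrappers): within each 6-connected component of the
#' mask the result equals the input modulo \eqn{2\pi} at every voxel and,
#' for phases whose true neighbour differences stay below \eqn{\pi},
#' differs from the true smooth phase only by one global \eqn{2\pi}
#' multiple per component. That residual constant is fixed by bringing
#' each component's median phase as close to zero as a \eqn{2\pi} shift
#' allows (shimming is DC-invariant, so this is safe).
#'
#' @param wrapped A [phase_volume()] (wrapped).
#' @param quality Optional quality/magnitude 3D array; by default the
#'   inverse local wrapped-gradient variance is used, multiplied by this
#'   array when given.
#' @param mask Logical array of voxels to unwrap (required, nonempty).
#' @return A [phase_volume()] with `wrapped = FALSE` (`NA` outside the
#'   mask); component labels in attribute `component`.
#' @export
unwrap_phase <- function(wrapped, quality = NULL, mask) {
  mask <- as_mask(mask)
  if (is.null(mask) || !any(mask))
    stop_fieldshim("empty mask", "fs_empty_mask")
  stopifnot(all(dim(mask) == dim(wrapped$values)))
  q <- phase_quality(wrapped$values, quality)
  res <- .unwrap_rg_cpp(wrapped$values, q, mask, dim(mask))
  u <- res$unwrapped
  dim(u) <- dim(mask)
  lab <- res$label
  dim(lab) <- dim(mask)
  for (cc in seq_len(res$n_components)) {
    sel <- lab == cc
    u[sel] <- u[sel] - 2 * pi * round(median(u[sel]) / (2 * pi))
  }
  out <- phase_volume(u, wrapped$grid, wrapped = FALSE)
  attr(out, "component") <- lab
  out
}

#' Remove a recorded baseline shim field from a field map
#'
#' Subtracts the field generated by the given shim setting (synthesized
#' from the harmonic basis or from a coil calibration) from the field map
#' and marks the result baseline-removed. The operation is exactly
#' linear: removing setting a then b equals removing a + b; applying it
#' twice shifts the field by the shim field again, so callers must track
#' `shim_state`.
#'
#' @param field A [field_map()] (unwrapped, Hz).
#' @param setting A [shim_setting()].
#' @param basis A [build_basis()] result on the field's grid.
#' @return The corrected [field_map()] with `shim_state =
#'   "baseline-removed"`.
#' @export
remove_baseline_shim <- function(field, setting, basis) {
  if (!grids_equal(field$grid, basis$grid))
    stop_fieldshim("field and basis grids differ", "fs_grid_mismatch")
  corr <- field$values - synthesize_shim_field(setting, basis)
  field_map(corr, field$grid, brain_mask = field$brain_mask,
            provenance = field$provenance,
            shim_state = "baseline-removed")
}

#' Brain-coverage quality control for a field-map acquisition
#'
#' Coverage is the fraction of the structural brain mask that falls inside
#' the field-map footprint after mapping the footprint into structural
#' space. Acquisitions covering less than the threshold (default 90%) of
#' the brain are rejected.
#'
#' @param fieldmap_footprint Logical array (or `fs_volume`) marking voxels
#'   actually acquired in the field map, with `fieldmap_grid` when a bare
#'   array.
#' @param structural_brain_mask Logical array (or `fs_volume`) of the
#'   brain in structural space, with `structural_grid` when a bare array.
#' @param transform [affine_transform()] from field-map space to
#'   structural space (identity by default).
#' @param threshold Acceptance threshold in (0, 1]; accepted iff coverage
#'   >= threshold.
#' @param fieldmap_grid,structural_grid Grids for bare-array input.
#' @return List with `coverage` and `accept`.
#' @export
qc_coverage <- function(fieldmap_footprint, structural_brain_mask,
                        transform = NULL, threshold = 0.90,
                        fieldmap_grid = NULL, structural_grid = NULL) {
  stopifnot(threshold > 0, threshold <= 1)
  if (inherits(fieldmap_footprint, "fs_volume")) {
    fgrid <- fieldmap_footprint$grid
    fmask <- as_mask(fieldmap_footprint$values)
  } else {
    fgrid <- fieldmap_grid
    fmask <- as_mask(fieldmap_footprint)
  }
  if (inherits(structural_brain_mask, "fs_volume")) {
    sgrid <- structural_brain_mask$grid
    smask <- as_mask(structural_brain_mask$values)
  } else {
    sgrid <- structural_grid
    smask <- as_mask(structural_brain_mask)
  }
  if (is.null(fgrid) || is.null(sgrid))
    stop_fieldshim("grids required for bare-array masks", "fs_bad_grid")
  if (!any(smask))
    stop_fieldshim("structural brain mask is empty", "fs_empty_mask")
  transform <- transform %||%
    affine_transform(diag(4), "fieldmap", "structural", dof = 6L)
  fp <- resample(volume(fmask, fgrid), transform, sgrid, "nearest")$values
  coverage <- sum(smask & fp) / sum(smask)
  list(coverage = coverage, accept = coverage >= threshold)
}
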