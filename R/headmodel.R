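ellipsoid_fraction_at <- function(coords, center_mm, semiaxes_mm,
                                  edge_mm) {
  rho <- sqrt(((coords[, 1] - center_mm[1]) / semiaxes_mm[1])^2 +
              ((coords[, 2] - center_mm[2]) / semiaxes_mm[2])^2 +
              ((coords[, 3] - center_mm[3]) / semiaxes_mm[3])^2)
  # approximate signed distance (exact for spheres)
  dist_mm <- (1 - rho) * exp(mean(log(semiaxes_mm)))
  pmin(1, pmax(0, 0.5 + dist_mm / edge_mm))
}

#' Fractional ellipsoid membership on a grid
#'
#' Approximate partial-volume fraction of each voxel inside an ellipsoid,
#' via a linear ramp of the (approximate) signed distance across
#' `edge_mm`. Used to build smooth susceptibility models that avoid
#' staircase ringing in the Fourier dipole convolution.
#'
#' @param grid A [voxel_grid()].
#' @param center_mm Ellipsoid centre in world mm.
#' @param semiaxes_mm Semi-axis lengths in mm.
#' @param edge_mm Width of the linear edge ramp in mm.
#' @return 3D array of fractions in \[0, 1\].
#' @export
ellipsoid_fraction <- function(grid, center_mm, semiaxes_mm,
                               edge_mm = mean(grid$voxel_size_mm)) {
  f <- ellipsoid_fraction_at(grid_coords(grid), center_mm, semiaxes_mm,
                             edge_mm)
  dim(f) <- grid$shape
  f
}

head_geometry <- function() {
  list(
    head_center  = c(0, 0, 8),   head_ax  = c(52, 62, 55),
    brain_center = c(0, 2, 18),  brain_ax = c(40, 48, 38),
    sinus_center = c(0, 45, -12), sinus_r = 9,
    ear_centers  = rbind(c(44, 0, -10), c(-44, 0, -10)), ear_r = 7,
    neck_center  = c(0, 8, -58), neck_ax = c(34, 38, 30))
}

#' Build a synthetic head susceptibility model
#'
#' An ellipsoidal head (plus a neck stub) of tissue surrounded by air,
#' with air cavities at anatomically plausible locations: a frontal sinus
#' anterior and inferior to the brain, and ear canals laterally. The
#' susceptibility contrasts of the cavities are derived from the requested
#' field-perturbation amplitudes (the peak field just outside a sphere of
#' contrast \eqn{\Delta\chi} is \eqn{2 \Delta\chi B_0 / 3}). World axes:
#' +x right, +y anterior, +z superior; the isocenter is the grid centre.
#'
#' When `transform` (subject to standard) is given, the model is
#' evaluated analytically at the transformed coordinates — i.e. the
#' standard-space anatomy is warped into subject space exactly, with no
#' interpolation.
#'
#' @param grid A [voxel_grid()]; the head geometry requires a field of
#'   view of at least about 120 mm per axis (>= 32 voxels recommended).
#' @param config A [cohort_config()].
#' @param cavity_scale Named numeric multipliers for the sinus and ear
#'   perturbation amplitudes (per-subject variation).
#' @param transform Optional [affine_transform()] mapping the model grid's
#'   coordinates into the canonical (standard) anatomy frame.
#' @return Object of class `susceptibility_model` with the chi volume
#'   (ppm) and logical masks `brain`, `head`, `frontal_sinus`,
#'   `ear_canals`, `neck`.
#' @export
make_head_model <- function(grid, config = cohort_config(),
                            cavity_scale = c(sinus = 1, ear = 1),
                            transform = NULL) {
  fov <- grid$shape * grid$voxel_size_mm
  if (any(fov < 120))
    stop_fieldshim(sprintf(
      "grid field of view %s mm too small to contain the head model",
      paste(round(fov), collapse = "x")), "fs_bad_config")
  geo <- head_geometry()
  co <- grid_coords(grid)
  if (!is.null(transform)) {
    M <- transform$matrix
    co <- co %*% t(M[1:3, 1:3]) +
      matrix(M[1:3, 4], nrow(co), 3, byrow = TRUE)
  }
  edge <- mean(grid$voxel_size_mm)
  f_head <- ellipsoid_fraction_at(co, geo$head_center, geo$head_ax, edge)
  f_brain <- ellipsoid_fraction_at(co, geo$brain_center, geo$brain_ax,
                                   edge)
  f_neck <- ellipsoid_fraction_at(co, geo$neck_center, geo$neck_ax, edge)
  f_sinus <- ellipsoid_fraction_at(co, geo$sinus_center,
                                   rep(geo$sinus_r, 3), edge)
  f_ear <- pmin(1,
    ellipsoid_fraction_at(co, geo$ear_centers[1, ], rep(geo$ear_r, 3),
                          edge) +
    ellipsoid_fraction_at(co, geo$ear_centers[2, ], rep(geo$ear_r, 3),
                          edge))
  f_tissue <- pmin(f_head + f_neck, 1)

  B0 <- config$B0_Hz_per_ppm
  chi_sinus <- 3 * config$sinus_amplitude_Hz * cavity_scale[["sinus"]] /
    (2 * B0)
  chi_ear <- 3 * config$ear_amplitude_Hz * cavity_scale[["ear"]] / (2 * B0)
  # susceptibility relative to tissue: surrounding air positive, cavities
  # positive inside tissue
  chi <- config$air_tissue_ppm * (1 - f_tissue) +
    chi_sinus * f_sinus + chi_ear * f_ear
  as_vol <- function(v) { dim(v) <- grid$shape; v }
  structure(list(
    chi = as_vol(chi), grid = grid,
    brain = as_vol(f_brain > 0.5), head = as_vol(f_head > 0.5),
    frontal_sinus = as_vol(f_sinus > 0.5), ear_canals = as_vol(f_ear > 0.5),
    neck = as_vol(f_neck > 0.5 & !(f_head > 0.5)),
    geometry = geo, coords_std = co, edge_mm = edge),
    class = "susceptibility_model")
}

#' @export
print.susceptibility_model <- function(x, ...) {
  cat(sprintf(
    "<susceptibility_model> %s grid; brain %d, sinus %d, ear %d voxels\n",
    paste(x$grid$shape, collapse = "x"), sum(x$brain),
    sum(x$frontal_sinus), sum(x$ear_canals)))
  invisible(x)
}

# Structural proxy image for a head model: piecewise tissue intensities
# plus internal features (ventricle-like hollows, a cerebellum-like lobe,
# one strongly lateralized blob) that break every axis symmetry, so that
# all rotations, translations and scales are observable to
# intensity-based registration. Evaluated analytically at the model's
# (possibly transformed) coordinates.
structural_proxy <- function(model) {
  g <- model$grid
  geo <- model$geometry
  co <- model$coords_std
  edge <- model$edge_mm
  f_head <- ellipsoid_fraction_at(co, geo$head_center, geo$head_ax, edge)
  f_brain <- ellipsoid_fraction_at(co, geo$brain_center, geo$brain_ax,
                                   edge)
  mod <- 1 + 0.2 * cos(pi * co[, 1] / 70) * cos(pi * co[, 2] / 90) +
    0.15 * sin(pi * co[, 3] / 80)
  v <- (0.45 * f_head + 0.55 * f_brain) * mod
  blob <- function(center, ax, w)
    w * ellipsoid_fraction_at(co, center, ax, edge_mm = 6)
  v <- v - blob(c(12, 12, 28), c(6, 14, 8), 0.5) -
    blob(c(-12, 12, 28), c(6, 14, 8), 0.5) +
    blob(c(0, -32, -10), c(22, 14, 14), 0.35) +
    blob(c(20, 28, 26), c(8, 8, 8), 0.45) -
    blob(c(-16, -20, 34), c(7, 7, 7), 0.3)
  dim(v) <- g$shape
  v[model$frontal_sinus | model$ear_canals] <- 0.05
  volume(v, g)
}
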