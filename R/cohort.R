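#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: a population of
#' heads sharing one mean anatomy, differing by a random affine (position,
#' rotation, size — subjects were positioned with no special instruction),
#' by the strength of the localized field perturbations at the
#' frontal-sinus and ear-canal air cavities, and by an unknown baseline
#' shim state to be removed downstream.
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param grid_shape,voxel_size_mm Standard-space grid (default 64^3 at
#'   2 mm isotropic, the resolution of typical brain field maps).
#' @param rotation_sd_deg,translation_sd_mm,scale_sd Per-axis standard
#'   deviations of the normal distributions for subject pose (degrees, mm)
#'   and log-scale (head size, as a fraction).
#' @param sinus_amplitude_Hz,ear_amplitude_Hz Peak field perturbation near
#'   each cavity at the nominal cavity size, in Hz.
#' @param cavity_scale_range Per-subject uniform multiplier range for the
#'   cavity amplitudes (intersubject variation of the high-order field).
#' @param gradient_y_Hz_per_mm,gradient_z_Hz_per_mm Global field gradients
#'   (scanner frame) emulating the body-induced field: dominant along
#'   superior-inferior z, secondary along anterior-posterior y.
#' @param noise_sigma_Hz Additive Gaussian field noise per voxel.
#' @param baseline_shim_range Named numeric half-widths; each subject's
#'   baseline shim term is drawn uniformly in +/- the half-width
#'   (Hz/mm^n).
#' @param B0_Hz_per_ppm Field strength scale (297.2 = 7 T).
#' @param air_tissue_ppm Susceptibility offset of air vs tissue (ppm).
#' @param field_mode `"dipole"` simulates each subject's field physically
#'   from its warped susceptibility model (the scanner z axis stays
#'   fixed); `"warp_template"` warps the template-anatomy field itself,
#'   producing a cohort whose fields are exactly affinely related (useful
#'   for validating the registration/prediction chain in isolation).
#' @param make_phases If `TRUE`, also simulate wrapped dual-echo phase
#'   pairs (baseline shim included) per subject.
#' @param TE1_ms,dTE_ms Dual-echo timing.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 20L, seed = 1L,
                          grid_shape = c(64L, 64L, 64L),
                          voxel_size_mm = 2,
                          rotation_sd_deg = c(5, 3, 3),
                          translation_sd_mm = c(2, 2, 4),
                          scale_sd = c(0.04, 0.04, 0.04),
                          sinus_amplitude_Hz = 300,
                          ear_amplitude_Hz = 200,
                          cavity_scale_range = c(0.6, 1.4),
                          gradient_y_Hz_per_mm = 0.6,
                          gradient_z_Hz_per_mm = 1.5,
                          noise_sigma_Hz = 1,
                          baseline_shim_range = c(
                            DC = 30, X = 0.8, Y = 0.8, Z = 1.2,
                            Z2 = 0.015, XZ = 0.008, YZ = 0.008,
                            `X2-Y2` = 0.008, XY = 0.008),
                          B0_Hz_per_ppm = 297.2,
                          air_tissue_ppm = 0.36,
                          field_mode = c("dipole", "warp_template"),
                          make_phases = FALSE,
                          TE1_ms = 4.08, dTE_ms = 1.02) {
  field_mode <- match.arg(field_mode)
  stopifnot(n_subjects >= 1, all(scale_sd >= 0), voxel_size_mm > 0,
            dTE_ms > 0, length(cavity_scale_range) == 2,
            cavity_scale_range[1] <= cavity_scale_range[2],
            all(cavity_scale_range > 0))
  cfg <- list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
              grid_shape = as.integer(rep_len(grid_shape, 3L)),
              voxel_size_mm = voxel_size_mm,
              rotation_sd_deg = rep_len(rotation_sd_deg, 3L),
              translation_sd_mm = rep_len(translation_sd_mm, 3L),
              scale_sd = rep_len(scale_sd, 3L),
              sinus_amplitude_Hz = sinus_amplitude_Hz,
              ear_amplitude_Hz = ear_amplitude_Hz,
              cavity_scale_range = cavity_scale_range,
              gradient_y_Hz_per_mm = gradient_y_Hz_per_mm,
              gradient_z_Hz_per_mm = gradient_z_Hz_per_mm,
              noise_sigma_Hz = noise_sigma_Hz,
              baseline_shim_range = baseline_shim_range,
              B0_Hz_per_ppm = B0_Hz_per_ppm,
              air_tissue_ppm = air_tissue_ppm,
              field_mode = field_mode, make_phases = make_phases,
              TE1_ms = TE1_ms, dTE_ms = dTE_ms)
  class(cfg) <- "cohort_config"
  cfg
}

# Scanner-frame background gradient field (Hz) on a grid.
background_gradient <- function(grid, config) {
  co <- grid_coords(grid)
  g <- config$gradient_y_Hz_per_mm * co[, 2] +
    config$gradient_z_Hz_per_mm * co[, 3]
  dim(g) <- grid$shape
  g
}

# Template anatomy and its noise-free field on the standard grid.
standard_anatomy <- function(config) {
  grid <- voxel_grid(config$grid_shape, config$voxel_size_mm)
  model <- make_head_model(grid, config)
  fld <- dipole_field(model, config$B0_Hz_per_ppm)
  values <- fld$values + background_gradient(grid, config)
  list(grid = grid, model = model,
       field = field_map(values, grid, brain_mask = model$brain,
                         provenance = "synthetic",
                         shim_state = "baseline-removed"),
       structural = structural_proxy(model),
       brain_mask = model$brain)
}

#' Generate a synthetic cohort of subjects
#'
#' Each subject is the shared mean anatomy warped by a random affine, with
#' per-subject cavity-strength variation, a field computed by Fourier
#' dipole convolution (or by warping the template field, see
#' [cohort_config()]), additive noise, a recorded true
#' subject-to-standard transform, and a random baseline shim.
#'
#' @param config A [cohort_config()].
#' @return Object of class `fs_cohort`: `subjects` (list; each with `id`,
#'   `field_true`, `structural`, `brain_mask`, `transform`,
#'   `baseline_shim`, `params`, optional `phases`), `standard` (template
#'   anatomy bundle) and `config`.
#' @export
sample_cohort <- function(config = cohort_config()) {
  std <- standard_anatomy(config)
  grid <- std$grid
  subjects <- with_seed(config$seed, lapply(seq_len(config$n_subjects),
                                            function(i) {
    par <- c(rnorm(3, 0, config$rotation_sd_deg),
             rnorm(3, 0, config$translation_sd_mm),
             rnorm(3, 0, config$scale_sd), 0, 0, 0)
    trf <- affine_transform(affine_from_params(par, dof = 12L),
                            source = "subject", target = "standard",
                            dof = 12L)
    cav <- runif(2, config$cavity_scale_range[1],
                 config$cavity_scale_range[2])
    names(cav) <- c("sinus", "ear")
    # subject anatomy: the canonical head evaluated analytically at
    # affinely transformed coordinates (no interpolation)
    model_i <- make_head_model(grid, config, cavity_scale = cav,
                               transform = trf)
    if (config$field_mode == "dipole") {
      f <- dipole_field(model_i, config$B0_Hz_per_ppm)$values +
        background_gradient(grid, config)
    } else {
      f <- resample(std$field, invert(trf), grid,
                    interp = "trilinear")$values
      f[is.na(f)] <- 0
    }
    if (config$noise_sigma_Hz > 0)
      f <- f + rnorm(length(f), 0, config$noise_sigma_Hz)
    msk <- model_i$brain
    structural <- structural_proxy(model_i)
    bs_range <- config$baseline_shim_range
    baseline <- shim_setting(
      structure(runif(length(bs_range), -bs_range, bs_range),
                names = names(bs_range)))
    subj <- list(
      id = sprintf("sub-%03d", i),
      field_true = field_map(f, grid, brain_mask = msk,
                             provenance = "synthetic",
                             shim_state = "baseline-removed"),
      structural = structural, brain_mask = msk, transform = trf,
      baseline_shim = baseline, cavity_scale = cav, params = par)
    if (config$make_phases) {
      basis2 <- build_basis(grid, 2L)
      raw <- f + synthesize_shim_field(baseline, basis2)
      subj$phases <- simulate_dual_echo(
        field_map(raw, grid, brain_mask = msk),
        TE1_ms = config$TE1_ms, dTE_ms = config$dTE_ms)
    }
    subj
  }))
  structure(list(subjects = subjects, standard = std, config = config),
            class = "fs_cohort")
}

#' @export
print.fs_cohort <- function(x, ...) {
  cat(sprintf("<fs_cohort> %d subjects on %s grid (%s field mode)\n",
              length(x$subjects),
              paste(x$standard$grid$shape, collapse = "x"),
              x$config$field_mode))
  invisible(x)
}

#' Simulate wrapped dual-echo phase images for a field map
#'
#' Phase at echo i is \eqn{wrap(2\pi f TE_i / 1000 + \phi_0)}; optional
#' complex Gaussian noise is added to a unit (or supplied) magnitude
#' signal before taking the argument.
#'
#' @param field A [field_map()] in Hz.
#' @param TE1_ms,dTE_ms First echo time and echo spacing in ms
#'   (`dTE_ms > 0`).
#' @param magnitude Optional 3D magnitude array (default 1 everywhere).
#' @param noise_sigma Standard deviation of the complex noise (same units
#'   as the magnitude).
#' @param phi0 Receiver phase offset in radians.
#' @return List with `phase1`, `phase2` ([phase_volume()]s, wrapped),
#'   `magnitude`, `TE1_ms`, `dTE_ms`.
#' @export
simulate_dual_echo <- function(field, TE1_ms = 4.08, dTE_ms = 1.02,
                               magnitude = NULL, noise_sigma = 0,
                               phi0 = 0) {
  if (!(is.numeric(dTE_ms) && length(dTE_ms) == 1L && dTE_ms > 0))
    stop_fieldshim("dTE_ms must be a positive scalar", "fs_invalid_dTE")
  grid <- field$grid
  magnitude <- magnitude %||% array(1, grid$shape)
  one_echo <- function(TE_ms) {
    ph <- 2 * pi * field$values * TE_ms / 1000 + phi0
    if (noise_sigma > 0) {
      sig <- magnitude * exp(1i * ph) +
        complex(real = rnorm(length(ph), 0, noise_sigma),
                imaginary = rnorm(length(ph), 0, noise_sigma))
      ph <- Arg(sig)
      dim(ph) <- grid$shape
      # Arg returns (-pi, pi]; keep convention explicit
      ph <- wrap_phase(ph)
    } else ph <- wrap_phase(ph)
    phase_volume(ph, grid, wrapped = TRUE)
  }
  list(phase1 = one_echo(TE1_ms), phase2 = one_echo(TE1_ms + dTE_ms),
       magnitude = magnitude, TE1_ms = TE1_ms, dTE_ms = dTE_ms)
}
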