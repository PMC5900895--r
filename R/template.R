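#' Build a field-map template in standard space
#'
#' Warps every accepted subject's field map into the standard grid with
#' its subject-to-standard transform and takes the voxelwise mean; the
#' voxelwise standard deviation and the per-voxel count of contributing
#' subjects are retained. Only voxels that are inside the subject's
#' footprint and brain mask contribute.
#'
#' @param subjects List; each element a list with `field` (a
#'   [field_map()], whose `brain_mask` is used) and `transform` (an
#'   [affine_transform()] to standard space).
#' @param standard_grid A [voxel_grid()].
#' @param structural,brain_mask Optional standard-space anatomy carried
#'   along for later registration-based prediction.
#' @return Object of class `template_result`: `mean` (a [field_map()]),
#'   `std`, `count` (3D arrays), `n`, `grid`, plus any anatomy supplied.
#' @export
build_template <- function(subjects, standard_grid, structural = NULL,
                           brain_mask = NULL) {
  if (length(subjects) < 1L)
    stop_fieldshim("no accepted subjects to average", "fs_no_subjects")
  s1 <- array(0, standard_grid$shape)
  s2 <- array(0, standard_grid$shape)
  cnt <- array(0L, standard_grid$shape)
  for (s in subjects) {
    fld <- s$field
    stopifnot(inherits(fld, "field_map"),
              inherits(s$transform, "affine_transform"))
    w <- resample(fld, s$transform, standard_grid, "trilinear")$values
    valid <- !is.na(w)
    if (!is.null(fld$brain_mask)) {
      m <- resample(volume(fld$brain_mask, fld$grid), s$transform,
                    standard_grid, "nearest")$values
      valid <- valid & m
    }
    w[!valid] <- 0
    s1 <- s1 + w
    s2 <- s2 + w * w
    cnt <- cnt + valid
  }
  seen <- cnt > 0
  mu <- array(NA_real_, standard_grid$shape)
  mu[seen] <- s1[seen] / cnt[seen]
  vv <- array(0, standard_grid$shape)
  vv[seen] <- pmax(0, s2[seen] / cnt[seen] - mu[seen]^2)
  mu_f <- mu; mu_f[!seen] <- 0
  structure(list(
    mean = field_map(mu_f, standard_grid, brain_mask = seen,
                     provenance = "synthetic",
                     shim_state = "baseline-removed"),
    std = sqrt(vv), count = cnt, n = length(subjects),
    grid = standard_grid, structural = structural,
    brain_mask = as_mask(brain_mask)),
    class = "template_result")
}

#' @export
print.template_result <- function(x, ...) {
  cat(sprintf("<template_result> n = %d on %s grid, max voxel std %.3g Hz\n",
              x$n, paste(x$grid$shape, collapse = "x"), max(x$std)))
  invisible(x)
}

#' Predict a subject's field map from the template
#'
#' Registers the subject's localizer to the standard-space structural
#' (12 dof), inverts the transform, and resamples the template mean field
#' into subject space, masked by the transformed standard brain mask.
#' Supplying `transform` (subject to standard) skips the registration.
#'
#' @param template A [build_template()] result (with `structural` unless
#'   `transform` is given).
#' @param localizer An `fs_volume` structural scan of the subject.
#' @param subject_grid Target grid (defaults to the localizer grid).
#' @param transform Optional known subject-to-standard
#'   [affine_transform()].
#' @param ... Passed to [register()].
#' @return A [field_map()] with provenance `"predicted"`; the transform
#'   used is attached as attribute `transform`.
#' @export
predict_fieldmap <- function(template, localizer,
                             subject_grid = localizer$grid,
                             transform = NULL, ...) {
  if (is.null(transform)) {
    if (is.null(template$structural))
      stop_fieldshim(
        "template carries no structural; supply a transform or anatomy",
        "fs_registration_failure")
    transform <- register(localizer, template$structural, dof = 12L,
                          source_space = "subject",
                          target_space = "standard", ...)
  }
  back <- invert(transform)
  pred <- resample(template$mean, back, subject_grid, "trilinear")$values
  mask_src <- template$brain_mask %||% (template$count > 0)
  msk <- resample(volume(mask_src, template$grid), back, subject_grid,
                  "nearest")$values
  msk <- as_mask(msk) & !is.na(pred)
  pred[is.na(pred)] <- 0
  out <- field_map(pred, subject_grid, brain_mask = msk,
                   provenance = "predicted",
                   shim_state = "baseline-removed")
  attr(out, "transform") <- transform
  out
}
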