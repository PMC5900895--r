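#' Construct a field map
#'
#' The central currency of the pipeline: a scalar off-resonance field in Hz
#' on a voxel grid, with an optional brain mask, a provenance tag and a
#' record of its shim state.
#'
#' @param values 3D numeric array of field values in Hz.
#' @param grid A [voxel_grid()].
#' @param brain_mask Optional logical array of the same shape.
#' @param provenance One of `"measured"`, `"predicted"`, `"synthetic"`.
#' @param shim_state `"none"`, `"baseline-removed"`, or `"shimmed"`.
#' @return Object of class `field_map` (also an `fs_volume`).
#' @export
field_map <- function(values, grid, brain_mask = NULL,
                      provenance = c("synthetic", "measured", "predicted"),
                      shim_state = "none") {
  provenance <- match.arg(provenance)
  values <- as.array(values)
  stopifnot(length(dim(values)) == 3L, all(dim(values) == grid$shape))
  brain_mask <- as_mask(brain_mask)
  if (!is.null(brain_mask)) {
    stopifnot(all(dim(brain_mask) == grid$shape))
    if (!any(brain_mask))
      stop_fieldshim("brain mask is empty", "fs_empty_mask")
    if (any(!is.finite(values[brain_mask])))
      stop_fieldshim("field map has non-finite values within the mask",
                     "fs_invalid_field")
  }
  structure(list(values = values, grid = grid, brain_mask = brain_mask,
                 provenance = provenance, shim_state = shim_state),
            class = c("field_map", "fs_volume"))
}

#' @export
print.field_map <- function(x, ...) {
  nv <- if (is.null(x$brain_mask)) prod(x$grid$shape) else sum(x$brain_mask)
  rng <- if (is.null(x$brain_mask)) range(x$values, finite = TRUE)
         else range(x$values[x$brain_mask], finite = TRUE)
  cat(sprintf(
    "<field_map> %s, %s, shim: %s, %d masked voxels, [%.1f, %.1f] Hz\n",
    paste(x$grid$shape, collapse = "x"), x$provenance,
    paste(x$shim_state, collapse = " "), nv, rng[1], rng[2]))
  invisible(x)
}

#' Construct a phase volume
#'
#' @param values 3D numeric array of phase values in radians.
#' @param grid A [voxel_grid()].
#' @param wrapped Logical; wrapped values must lie in \eqn{(-\pi, \pi]}.
#' @return Object of class `phase_volume` (also an `fs_volume`).
#' @export
phase_volume <- function(values, grid, wrapped = TRUE) {
  values <- as.array(values)
  stopifnot(length(dim(values)) == 3L, all(dim(values) == grid$shape))
  if (wrapped) {
    v <- values[is.finite(values)]
    if (length(v) && (min(v) <= -pi - 1e-9 || max(v) > pi + 1e-9))
      stop_fieldshim("wrapped phase must lie in (-pi, pi]",
                     "fs_invalid_phase")
  }
  structure(list(values = values, grid = grid, wrapped = isTRUE(wrapped)),
            class = c("phase_volume", "fs_volume"))
}
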