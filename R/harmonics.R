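#' Solid spherical-harmonic shim terms
#'
#' The shim hardware model: each coil produces a field shaped as a real
#' solid spherical harmonic, expressed in unnormalized Cartesian polynomial
#' form (1; x; y; z; z^2 - (x^2+y^2)/2; xz; ...). Coordinates are world mm
#' about the magnet isocenter, so an order-n coefficient carries units
#' Hz/mm^n. Through order N there are (N+1)^2 terms.
#'
#' @param max_order Integer 0-4, highest harmonic order.
#' @return A data frame with columns `name` and `order`.
#' @export
#' @examples
#' harmonic_terms(2)$name
harmonic_terms <- function(max_order = 4L) {
  check_order(max_order)
  tab <- data.frame(
    name = c("DC", "X", "Y", "Z",
             "Z2", "XZ", "YZ", "X2-Y2", "XY",
             "Z3", "Z2X", "Z2Y", "Z(X2-Y2)", "XYZ", "X3", "Y3",
             "Z4", "Z3X", "Z3Y", "Z2(X2-Y2)", "Z2XY", "ZX3", "ZY3",
             "X4", "Y4"),
    order = c(0L, rep(1L, 3), rep(2L, 5), rep(3L, 7), rep(4L, 9)),
    stringsAsFactors = FALSE)
  tab[tab$order <= max_order, , drop = FALSE]
}

check_order <- function(max_order) {
  if (length(max_order) != 1L || is.na(max_order) ||
      max_order != round(max_order) || max_order < 0 || max_order > 4)
    stop_fieldshim("max_order must be an integer in [0, 4]",
                   "fs_invalid_order")
  invisible(as.integer(max_order))
}

# Evaluate the named harmonic terms at world coordinates (n x 3 matrix of
# mm). Every polynomial below satisfies Laplace's equation exactly.
harmonic_design <- function(coords, names) {
  x <- coords[, 1]; y <- coords[, 2]; z <- coords[, 3]
  u <- NULL  # x^2 + y^2, computed lazily
  need_u <- any(names %in% c("Z2", "Z3", "Z2X", "Z2Y", "Z4", "Z3X", "Z3Y",
                             "Z2(X2-Y2)", "Z2XY"))
  if (need_u) u <- x * x + y * y
  one_term <- function(nm) {
    switch(nm,
      "DC"        = rep.int(1, length(x)),
      "X"         = x,
      "Y"         = y,
      "Z"         = z,
      "Z2"        = z * z - u / 2,
      "XZ"        = x * z,
      "YZ"        = y * z,
      "X2-Y2"     = x * x - y * y,
      "XY"        = x * y,
      "Z3"        = z^3 - 1.5 * z * u,
      "Z2X"       = x * (z * z - u / 4),
      "Z2Y"       = y * (z * z - u / 4),
      "Z(X2-Y2)"  = z * (x * x - y * y),
      "XYZ"       = x * y * z,
      "X3"        = x^3 - 3 * x * y * y,
      "Y3"        = 3 * x * x * y - y^3,
      "Z4"        = z^4 - 3 * z * z * u + 0.375 * u * u,
      "Z3X"       = x * z * (z * z - 0.75 * u),
      "Z3Y"       = y * z * (z * z - 0.75 * u),
      "Z2(X2-Y2)" = (x * x - y * y) * (z * z - u / 6),
      "Z2XY"      = x * y * (z * z - u / 6),
      "ZX3"       = z * (x^3 - 3 * x * y * y),
      "ZY3"       = z * (3 * x * x * y - y^3),
      "X4"        = x^4 - 6 * x * x * y * y + y^4,
      "Y4"        = 4 * (x^3 * y - x * y^3),
      stop_fieldshim(sprintf("unknown harmonic term '%s'", nm),
                     "fs_unknown_term"))
  }
  out <- vapply(names, one_term, numeric(length(x)))
  dim(out) <- c(length(x), length(names))
  colnames(out) <- names
  out
}

#' Build a spherical-harmonic basis on a voxel grid
#'
#' Evaluates all (max_order+1)^2 solid-harmonic terms at the world
#' coordinates of every voxel. Basis volumes are mask-independent; the DC
#' term is identically 1.
#'
#' @param grid A [voxel_grid()].
#' @param max_order Integer 0-4.
#' @return Object of class `harmonic_basis` with fields `grid`,
#'   `max_order`, `terms` (data frame) and `B` (voxels x terms design
#'   matrix in Hz per unit coefficient).
#' @export
#' @examples
#' b <- build_basis(voxel_grid(c(8, 8, 8), 2), 2)
#' nrow(b$terms)  # (2+1)^2 = 9
build_basis <- function(grid, max_order) {
  max_order <- check_order(max_order)
  terms <- harmonic_terms(max_order)
  B <- harmonic_design(grid_coords(grid), terms$name)
  structure(list(grid = grid, max_order = max_order, terms = terms, B = B),
            class = "harmonic_basis")
}

#' @export
print.harmonic_basis <- function(x, ...) {
  cat(sprintf("<harmonic_basis> order %d (%d terms) on %s grid\n",
              x$max_order, nrow(x$terms),
              paste(x$grid$shape, collapse = "x")))
  invisible(x)
}

basis_volume <- function(basis, term) {
  v <- basis$B[, term]
  dim(v) <- basis$grid$shape
  v
}

#' Create a shim setting
#'
#' Per-term shim coefficients in Hz/mm^n for an order-n term. The sign
#' convention throughout the package is that the shim field is *added* to
#' the subject field.
#'
#' @param coefficients Named numeric vector; names must be harmonic term
#'   names (see [harmonic_terms()]).
#' @param max_order Highest order; inferred from the terms when `NULL`.
#' @return Object of class `shim_setting`.
#' @export
#' @examples
#' shim_setting(c(Z = 1.2, Z2 = -0.01))
shim_setting <- function(coefficients, max_order = NULL) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)))
  tab <- harmonic_terms(4L)
  unknown <- setdiff(names(coefficients), tab$name)
  if (length(unknown))
    stop_fieldshim(paste0("unknown shim terms: ",
                          paste(unknown, collapse = ", ")),
                   "fs_unknown_term")
  if (any(!is.finite(coefficients)))
    stop_fieldshim("shim coefficients must be finite", "fs_invalid_setting")
  orders <- tab$order[match(names(coefficients), tab$name)]
  if (is.null(max_order)) max_order <- max(orders, 0L)
  check_order(max_order)
  if (any(orders > max_order))
    stop_fieldshim("coefficients contain terms above max_order",
                   "fs_invalid_setting")
  structure(list(coefficients = coefficients,
                 max_order = as.integer(max_order)),
            class = "shim_setting")
}

#' Zero shim setting (used for the tune-up comparison on synthetic data)
#' @param max_order Highest order of the (all-zero) setting.
#' @return A `shim_setting` with every term zero.
#' @export
zero_shim <- function(max_order = 2L) {
  terms <- harmonic_terms(max_order)
  shim_setting(structure(numeric(nrow(terms)), names = terms$name),
               max_order)
}

#' @export
print.shim_setting <- function(x, ...) {
  cat(sprintf("<shim_setting> order %d\n", x$max_order))
  print(signif(x$coefficients, 5))
  invisible(x)
}

#' Synthesize the field generated by a shim setting
#'
#' @param setting A [shim_setting()].
#' @param basis A [build_basis()] result on the target grid.
#' @return 3D array of field values in Hz.
#' @export
synthesize_shim_field <- function(setting, basis) {
  nm <- names(setting$coefficients)
  missing_terms <- setdiff(nm, colnames(basis$B))
  if (length(missing_terms))
    stop_fieldshim(paste0("basis lacks terms: ",
                          paste(missing_terms, collapse = ", ")),
                   "fs_unknown_term")
  v <- as.vector(basis$B[, nm, drop = FALSE] %*% setting$coefficients)
  dim(v) <- basis$grid$shape
  v
}

# Masked least squares with column equilibration and an explicit rank
# check: a rank-deficient design aborts (naming the offending terms)
# rather than silently truncating, which would corrupt shim comparisons.
solve_harmonic_lsq <- function(X, y, term_names) {
  stopifnot(nrow(X) == length(y))
  if (nrow(X) < ncol(X))
    stop_fieldshim(sprintf(
      "mask has %d voxels but the design has %d terms", nrow(X), ncol(X)),
      "fs_singular_fit")
  sc <- sqrt(colSums(X^2))
  if (any(sc == 0))
    stop_fieldshim(paste0("singular fit; degenerate terms: ",
                          paste(term_names[sc == 0], collapse = ", ")),
                   "fs_singular_fit")
  Xs <- sweep(X, 2, sc, "/")
  qx <- qr(Xs)
  if (qx$rank < ncol(X)) {
    bad <- term_names[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop_fieldshim(paste0("singular fit; rank-deficient terms: ",
                          paste(bad, collapse = ", ")),
                   "fs_singular_fit")
  }
  beta <- qr.coef(qx, y) / sc
  names(beta) <- term_names
  res <- y - X %*% beta
  list(coefficients = beta, residuals = as.vector(res))
}

#' Decompose a field into spherical-harmonic coefficients
#'
#' Least-squares projection of a field map onto the harmonic basis over the
#' masked voxels. The DC term is part of the design, so minimizing the
#' residual RMS equals minimizing its standard deviation.
#'
#' @param field A [field_map()] (or `fs_volume`) on the basis grid.
#' @param basis A [build_basis()] result.
#' @param mask Logical array; defaults to the field's brain mask.
#' @return Object of class `shim_fit`: `setting` (the coefficients as a
#'   [shim_setting()]), `residual_norm_Hz`, `residual_std_Hz`, `n_voxels`.
#' @export
decompose_field <- function(field, basis, mask = NULL) {
  mask <- as_mask(mask %||% field$brain_mask)
  if (is.null(mask)) stop_fieldshim("a mask is required", "fs_empty_mask")
  if (!grids_equal(field$grid, basis$grid))
    stop_fieldshim("field and basis grids differ", "fs_grid_mismatch")
  idx <- which(mask)
  if (length(idx) == 0L) stop_fieldshim("empty mask", "fs_empty_mask")
  y <- field$values[idx]
  if (any(!is.finite(y)))
    stop_fieldshim("field contains non-finite values within the mask",
                   "fs_invalid_field")
  fit <- solve_harmonic_lsq(basis$B[idx, , drop = FALSE], y,
                            basis$terms$name)
  structure(list(
    setting = shim_setting(fit$coefficients, basis$max_order),
    residual_norm_Hz = sqrt(sum(fit$residuals^2)),
    residual_std_Hz = pop_sd(fit$residuals),
    n_voxels = length(idx)),
    class = "shim_fit")
}

#' @export
print.shim_fit <- function(x, ...) {
  cat(sprintf("<shim_fit> %d voxels, residual std %.4g Hz\n",
              x$n_voxels, x$residual_std_Hz))
  print(x$setting)
  invisible(x)
}

#' Calibrate one shim coil from measured fields
#'
#' Fits the harmonic decomposition of fields measured at a range of
#' hardware settings linearly against the setting value (through the
#' origin after subtracting the zero-setting field, via a straight-line
#' fit with intercept). The slopes are the per-unit harmonic coefficients
#' of the coil (Hz/mm^n per hardware unit); hardware units are treated as
#' opaque.
#'
#' @param measured_fields List of [field_map()]s, one per setting.
#' @param settings Numeric hardware setting per field; at least two
#'   distinct values.
#' @param basis A [build_basis()] result.
#' @param mask Logical array over which to decompose.
#' @return Object of class `coil_calibration`: `coefficients_per_unit`
#'   (named numeric), `residual` (RMS of the linear fit across settings
#'   and terms, nonnegative), `n_settings`.
#' @export
calibrate_coil <- function(measured_fields, settings, basis, mask) {
  stopifnot(length(measured_fields) == length(settings))
  if (length(unique(settings)) < 2L)
    stop_fieldshim("need at least two distinct settings per coil",
                   "fs_degenerate_calibration")
  C <- t(vapply(measured_fields, function(f)
    decompose_field(f, basis, mask)$setting$coefficients,
    numeric(nrow(basis$terms))))
  s <- settings - mean(settings)
  slope <- colSums(C * s) / sum(s^2)
  intercept <- colMeans(C) - slope * mean(settings)
  pred <- outer(settings, slope) + rep(intercept, each = length(settings))
  structure(list(coefficients_per_unit = slope,
                 residual = sqrt(mean((C - pred)^2)),
                 n_settings = length(settings)),
            class = "coil_calibration")
}

#' Calibrate several shim coils at once
#'
#' @param coils Named list; each element a list with `fields` (list of
#'   field maps) and `settings` (numeric vector).
#' @param basis,mask As in [calibrate_coil()].
#' @return Named list of `coil_calibration` objects, class
#'   `coil_calibration_set`.
#' @export
calibrate_coils <- function(coils, basis, mask) {
  stopifnot(is.list(coils), !is.null(names(coils)))
  out <- lapply(coils, function(cc)
    calibrate_coil(cc$fields, cc$settings, basis, mask))
  class(out) <- "coil_calibration_set"
  out
}
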