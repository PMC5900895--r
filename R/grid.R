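#' Define a voxel grid
#'
#' A voxel grid couples an array shape to world (scanner) coordinates in mm
#' through a 4x4 affine. By default the world origin — taken to be the
#' magnet isocenter, where all shim fields are centred — sits at the grid
#' centre, and axes follow the scanner convention: x = left-right,
#' y = anterior-posterior, z = superior-inferior.
#'
#' @param shape Integer vector of length 3, voxels per axis.
#' @param voxel_size_mm Numeric length 3 (or 1, recycled), voxel edge in mm.
#' @param index_to_world Optional 4x4 affine mapping 0-based voxel indices
#'   to world mm. Default places the world origin at the grid centre with
#'   axis-aligned voxels.
#' @return An object of class `voxel_grid`.
#' @export
#' @examples
#' g <- voxel_grid(c(64, 64, 64), 2)
#' g$index_to_world
voxel_grid <- function(shape, voxel_size_mm = 1, index_to_world = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  stopifnot(all(voxel_size_mm > 0))
  if (is.null(index_to_world)) {
    index_to_world <- diag(4)
    diag(index_to_world)[1:3] <- voxel_size_mm
    index_to_world[1:3, 4] <- -(shape - 1) / 2 * voxel_size_mm
  }
  index_to_world <- as.matrix(index_to_world)
  stopifnot(all(dim(index_to_world) == c(4L, 4L)))
  if (abs(det(index_to_world[1:3, 1:3])) < .Machine$double.eps)
    stop_fieldshim("index_to_world upper-left 3x3 must be invertible",
                   "fs_bad_grid")
  structure(list(shape = shape, voxel_size_mm = voxel_size_mm,
                 index_to_world = index_to_world),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s voxels, %s mm\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$voxel_size_mm, 4), collapse = "x")))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-8) {
  all(a$shape == b$shape) &&
    max(abs(a$index_to_world - b$index_to_world)) < tol
}

n_voxels <- function(grid) prod(grid$shape)

# World-mm coordinates of every voxel (0-based indices), as an n x 3 matrix
# in column-major voxel order.
grid_coords <- function(grid) {
  s <- grid$shape
  i <- rep.int(seq_len(s[1]) - 1, s[2] * s[3])
  j <- rep.int(rep(seq_len(s[2]) - 1, each = s[1]), s[3])
  k <- rep(seq_len(s[3]) - 1, each = s[1] * s[2])
  A <- grid$index_to_world
  cbind(A[1, 1] * i + A[1, 2] * j + A[1, 3] * k + A[1, 4],
        A[2, 1] * i + A[2, 2] * j + A[2, 3] * k + A[2, 4],
        A[3, 1] * i + A[3, 2] * j + A[3, 3] * k + A[3, 4])
}

#' Construct a volume (array + grid)
#'
#' Light container pairing a 3D numeric or logical array with its
#' [voxel_grid()].
#'
#' @param values 3D array matching `grid$shape`.
#' @param grid A [voxel_grid()].
#' @return An object of class `fs_volume`.
#' @export
volume <- function(values, grid) {
  values <- as.array(values)
  stopifnot(length(dim(values)) == 3L, all(dim(values) == grid$shape))
  structure(list(values = values, grid = grid), class = "fs_volume")
}

#' @export
print.fs_volume <- function(x, ...) {
  cat(sprintf("<fs_volume> %s, range [%.3g, %.3g]\n",
              paste(dim(x$values), collapse = "x"),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

# Halve a volume by 2x2x2 block averaging (used by the registration
# pyramid). Trailing odd slabs are dropped.
halve_volume <- function(vol) {
  v <- vol$values
  d <- dim(v) %/% 2L
  stopifnot(all(d >= 1L))
  v <- v[seq_len(2 * d[1]), seq_len(2 * d[2]), seq_len(2 * d[3]), drop = FALSE]
  v <- (v[c(TRUE, FALSE), , , drop = FALSE] +
        v[c(FALSE, TRUE), , , drop = FALSE])
  v <- (v[, c(TRUE, FALSE), , drop = FALSE] +
        v[, c(FALSE, TRUE), , drop = FALSE])
  v <- (v[, , c(TRUE, FALSE), drop = FALSE] +
        v[, , c(FALSE, TRUE), drop = FALSE]) / 8
  A <- vol$grid$index_to_world %*%
    rbind(cbind(diag(3) * 2, rep(0.5, 3)), c(0, 0, 0, 1))
  g <- voxel_grid(d, vol$grid$voxel_size_mm * 2, index_to_world = A)
  volume(v, g)
}
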