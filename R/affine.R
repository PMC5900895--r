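#' Construct an affine transform between world spaces
#'
#' A 4x4 matrix mapping world-mm coordinates of a source space to world-mm
#' coordinates of a target space, with explicit space labels so that
#' composition chains (subject -> structural -> standard) are checked.
#'
#' @param matrix 4x4 numeric matrix, last row (0, 0, 0, 1).
#' @param source,target Space labels (character scalars).
#' @param dof 6 (rigid) or 12 (full affine).
#' @return Object of class `affine_transform`.
#' @export
#' @examples
#' a <- affine_transform(diag(4), "subject", "standard")
affine_transform <- function(matrix, source = "source", target = "target",
                             dof = 12L) {
  matrix <- as.matrix(matrix)
  stopifnot(all(dim(matrix) == c(4L, 4L)),
            max(abs(matrix[4, ] - c(0, 0, 0, 1))) < 1e-9,
            dof %in% c(6L, 12L))
  if (abs(det(matrix[1:3, 1:3])) < 1e-12)
    stop_fieldshim("affine transform is not invertible", "fs_bad_transform")
  if (dof == 6L) {
    R <- matrix[1:3, 1:3]
    if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
      stop_fieldshim(
        "rigid (6 dof) transforms need an orthonormal, det +1 rotation",
        "fs_bad_transform")
  }
  structure(list(matrix = matrix, source = source, target = target,
                 dof = as.integer(dof)),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat(sprintf("<affine_transform> %s -> %s (%d dof)\n",
              x$source, x$target, x$dof))
  print(signif(x$matrix, 5))
  invisible(x)
}

#' Identity transform
#' @param source,target Space labels.
#' @return An `affine_transform`.
#' @export
identity_transform <- function(source = "source", target = "target") {
  affine_transform(diag(4), source, target, dof = 6L)
}

#' Compose two affine transforms
#'
#' `compose(a, b)` applies `a` first, then `b`; `a`'s target space must be
#' `b`'s source space.
#'
#' @param a,b `affine_transform` objects.
#' @return The composed `affine_transform` from `a$source` to `b$target`.
#' @export
compose <- function(a, b) {
  stopifnot(inherits(a, "affine_transform"), inherits(b, "affine_transform"))
  if (!identical(a$target, b$source))
    stop_fieldshim(sprintf(
      "cannot chain %s->%s with %s->%s: space labels do not match",
      a$source, a$target, b$source, b$target), "fs_chain_error")
  affine_transform(b$matrix %*% a$matrix, a$source, b$target,
                   dof = max(a$dof, b$dof))
}

#' Invert an affine transform
#' @param a An `affine_transform`.
#' @return The inverse transform, with source/target labels swapped.
#' @export
invert <- function(a) {
  stopifnot(inherits(a, "affine_transform"))
  affine_transform(solve(a$matrix), a$target, a$source, dof = a$dof)
}

# Build a 4x4 affine from parameters: rotations (deg, applied as
# Rz Ry Rx), translations (mm), log-scales, shears. Rotation/scaling are
# about the world origin (isocenter).
affine_from_params <- function(par, dof = 12L) {
  r <- par[1:3] * pi / 180
  ca <- cos(r[1]); sa <- sin(r[1])
  cb <- cos(r[2]); sb <- sin(r[2])
  cc <- cos(r[3]); sc <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, ca, -sa), c(0, sa, ca))
  Ry <- rbind(c(cb, 0, sb), c(0, 1, 0), c(-sb, 0, cb))
  Rz <- rbind(c(cc, -sc, 0), c(sc, cc, 0), c(0, 0, 1))
  A <- Rz %*% Ry %*% Rx
  if (dof == 12L) {
    sh <- diag(3)
    sh[1, 2] <- par[10]; sh[1, 3] <- par[11]; sh[2, 3] <- par[12]
    A <- A %*% sh %*% diag(exp(par[7:9]))
  }
  M <- diag(4)
  M[1:3, 1:3] <- A
  M[1:3, 4] <- par[4:6]
  M
}

#' Decompose an affine transform into interpretable parameters
#'
#' Splits the linear part as rotation x shear x scale (matching the
#' parameterization used by [register()]) and reports rotations in
#' degrees, translations in mm, scales and shears.
#'
#' @param a An `affine_transform` or 4x4 matrix.
#' @return List with `rotation_deg`, `translation_mm`, `scale`, `shear`.
#' @export
affine_params <- function(a) {
  M <- if (inherits(a, "affine_transform")) a$matrix else as.matrix(a)
  A <- M[1:3, 1:3]
  qd <- qr(A)
  Q <- qr.Q(qd); R <- qr.R(qd)
  sgn <- sign(diag(R)); sgn[sgn == 0] <- 1
  Q <- Q %*% diag(sgn); R <- diag(sgn) %*% R
  if (det(Q) < 0) { Q <- -Q; R <- -R }
  scl <- diag(R)
  shear <- c(R[1, 2] / scl[2], R[1, 3] / scl[3], R[2, 3] / scl[3])
  rot <- c(atan2(Q[3, 2], Q[3, 3]),
           -asin(max(-1, min(1, Q[3, 1]))),
           atan2(Q[2, 1], Q[1, 1])) * 180 / pi
  list(rotation_deg = rot, translation_mm = M[1:3, 4],
       scale = scl, shear = shear)
}
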