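#' Susceptibility-induced field by Fourier dipole-kernel convolution
#'
#' Computes the B0 field shift induced by a susceptibility distribution by
#' multiplying its 3D FFT with the k-space dipole kernel
#' \eqn{D(k) = 1/3 - k_z^2/|k|^2} and inverting. This is the
#' Lorentz-sphere-corrected convention: the interior of a uniform sphere
#' shifts by zero. `D(0)` is set to 0 (the mean field is a convention;
#' shimming is invariant to the DC term). The volume is zero-padded (factor
#' >= 2, susceptibility centred) to suppress circular-convolution
#' wrap-around.
#'
#' @param model A `susceptibility_model` (see [make_head_model()]), an
#'   `fs_volume`, or a 3D array of susceptibility in ppm (then `grid` is
#'   required).
#' @param B0_Hz_per_ppm Field strength expressed as Hz of off-resonance per
#'   ppm of susceptibility (297.2 at 7 T for protons).
#' @param grid Required when `model` is a bare array.
#' @param pad_factor Zero-padding factor, >= 2.
#' @return A [field_map()] in Hz (provenance `"synthetic"`).
#' @export
dipole_field <- function(model, B0_Hz_per_ppm = 297.2, grid = NULL,
                         pad_factor = 2) {
  if (inherits(model, "susceptibility_model")) {
    chi <- model$chi; grid <- model$grid
  } else if (inherits(model, "fs_volume")) {
    chi <- model$values; grid <- model$grid
  } else {
    chi <- as.array(model)
    if (is.null(grid)) stop_fieldshim("grid required for a bare array",
                                      "fs_bad_grid")
  }
  stopifnot(all(is.finite(chi)), pad_factor >= 2)
  A3 <- grid$index_to_world[1:3, 1:3]
  if (max(abs(A3 - diag(diag(A3)))) > 1e-8)
    stop_fieldshim("dipole_field requires an axis-aligned grid",
                   "fs_bad_grid")
  d <- dim(chi)
  dp <- 2L * ceiling(d * pad_factor / 2)
  off <- (dp - d) %/% 2L
  chip <- array(0, dp)
  chip[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]),
       off[3] + seq_len(d[3])] <- chi
  D <- dipole_kernel(dp, abs(diag(A3)))
  fp <- Re(fft(fft(chip) * D, inverse = TRUE)) / prod(dp)
  f <- fp[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]),
          off[3] + seq_len(d[3])]
  field_map(f * B0_Hz_per_ppm, grid, provenance = "synthetic")
}

# k-space dipole kernel 1/3 - kz^2/|k|^2 with D(0) = 0, on an FFT grid of
# the given dimensions and voxel size (mm).
dipole_kernel <- function(dims, voxel_mm) {
  freq <- function(n, d) {
    f <- seq.int(0L, n - 1L)
    f[f >= n / 2] <- f[f >= n / 2] - n
    f / (n * d)
  }
  kx <- freq(dims[1], voxel_mm[1])
  ky <- freq(dims[2], voxel_mm[2])
  kz <- freq(dims[3], voxel_mm[3])
  kx2 <- kx^2; ky2 <- ky^2; kz2 <- kz^2
  k2 <- outer(outer(kx2, ky2, "+"), kz2, "+")
  kzz <- outer(outer(rep(0, dims[1]), rep(0, dims[2]), "+"), kz2, "+")
  D <- 1 / 3 - kzz / k2
  D[k2 == 0] <- 0
  D
}
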