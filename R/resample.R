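#' Resample a volume through an affine transform
#'
#' Pull-based resampling: each target voxel is mapped through the inverse
#' of the source-to-target transform into the source volume and
#' interpolated there. Voxels falling outside the source footprint are
#' `NA` (and excluded when resampling masks).
#'
#' @param vol An `fs_volume`, [field_map()], or 3D array with attribute-free
#'   grid passed via `source_grid`.
#' @param transform An [affine_transform()] mapping source world
#'   coordinates to target world coordinates.
#' @param target A [voxel_grid()] to resample onto.
#' @param interp `"trilinear"` (fields, images) or `"nearest"` (masks,
#'   labels).
#' @param source_grid Grid of `vol` when `vol` is a bare array.
#' @return An `fs_volume` on `target` (`NA` outside the footprint).
#' @export
resample <- function(vol, transform, target,
                     interp = c("trilinear", "nearest"),
                     source_grid = NULL) {
  interp <- match.arg(interp)
  if (inherits(vol, "fs_volume")) {
    src <- vol$values; sgrid <- vol$grid
  } else {
    src <- as.array(vol); sgrid <- source_grid
    if (is.null(sgrid)) stop_fieldshim("source_grid required",
                                       "fs_bad_grid")
  }
  stopifnot(inherits(transform, "affine_transform"),
            inherits(target, "voxel_grid"))
  is_logical <- is.logical(src)
  storage.mode(src) <- "double"
  # 0-based target index -> source index
  M <- solve(sgrid$index_to_world) %*% solve(transform$matrix) %*%
    target$index_to_world
  out <- .resample_affine_cpp(src, dim(src), M, target$shape,
                              interp == "nearest")
  dim(out) <- target$shape
  if (is_logical && interp == "nearest") {
    out[is.na(out)] <- 0
    storage.mode(out) <- "logical"
  }
  volume(out, target)
}
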