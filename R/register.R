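# Correlation ratio between fixed intensities (binned) and moving
# intensities: fraction of moving variance explained by the fixed bins.
# Returned as a cost (1 - eta^2) to minimize.
cr_cost <- function(fixed_vals, moving_vals, nbins = 32L) {
  ok <- !is.na(moving_vals)
  f <- fixed_vals[ok]; m <- moving_vals[ok]
  if (length(m) < 100L) return(2)  # barely any overlap: poor
  vt <- var(m)
  if (vt == 0) return(2)
  br <- range(f)
  if (br[1] == br[2]) return(2)
  bin <- pmin(nbins, 1L + as.integer((f - br[1]) / (br[2] - br[1]) * nbins))
  S <- rowsum(cbind(m, m * m, 1), bin)
  within <- sum(S[, 2] - S[, 1]^2 / S[, 3])
  within / (vt * (length(m) - 1))
}

ssd_cost <- function(fixed_vals, moving_vals) {
  ok <- !is.na(moving_vals)
  if (sum(ok) < 100L) return(Inf)
  mean((fixed_vals[ok] - moving_vals[ok])^2)
}

#' Register one volume to another (rigid or affine)
#'
#' Intensity-based registration by multi-resolution local optimization
#' (Nelder-Mead over pose parameters, coarse-to-fine block-averaged
#' pyramid) of a similarity cost between the fixed image and the
#' resampled moving image. Correlation ratio is the default cost.
#' Deterministic given fixed initialization. Registration here is a means
#' to an end — externally computed transforms can be supplied anywhere one
#' is accepted.
#'
#' @param moving,fixed `fs_volume`s (or field maps) with overlapping
#'   fields of view; must be nonconstant.
#' @param dof 6 (rigid) or 12 (affine: adds log-scales and shears).
#' @param cost `"cr"` (correlation ratio), `"ssd"`, or `"ncc"`.
#' @param init Optional initial parameter vector (length 12).
#' @param source_space,target_space Space labels for the result.
#' @param maxit Nelder-Mead iteration budget per pass.
#' @return An [affine_transform()] mapping moving world coordinates to
#'   fixed world coordinates; attribute `cost` holds the final cost.
#' @export
register <- function(moving, fixed, dof = 6L,
                     cost = c("cr", "ssd", "ncc"), init = NULL,
                     source_space = "moving", target_space = "fixed",
                     maxit = 400L) {
  cost <- match.arg(cost)
  stopifnot(dof %in% c(6L, 12L))
  if (var(as.vector(fixed$values), na.rm = TRUE) == 0 ||
      var(as.vector(moving$values), na.rm = TRUE) == 0)
    stop_fieldshim("registration failure: constant image(s)",
                   "fs_registration_failure")
  # pyramid: halve until the smallest axis would drop below ~16 voxels
  pyr_f <- list(fixed); pyr_m <- list(moving)
  while (min(dim(pyr_f[[1]]$values)) >= 32 &&
         min(dim(pyr_m[[1]]$values)) >= 32) {
    pyr_f <- c(list(halve_volume(pyr_f[[1]])), pyr_f)
    pyr_m <- c(list(halve_volume(pyr_m[[1]])), pyr_m)
  }
  npar <- 12L
  par <- init %||% numeric(npar)
  parscale <- c(rep(10, 3), rep(10, 3), rep(0.1, 3), rep(0.1, 3))
  active <- if (dof == 6L) 1:6 else 1:12

  cost_fun_factory <- function(fx, mv) {
    fvals <- as.vector(fx$values)
    # evaluate similarity on fixed-image foreground only: the large
    # empty background otherwise both dilutes and biases the optimum
    fg <- abs(fvals) > 0.02 * max(abs(fvals))
    if (sum(fg) < 200L) fg <- rep(TRUE, length(fvals))
    fvals <- fvals[fg]
    d <- fx$grid$shape
    idx0 <- which(fg) - 1L
    pts <- cbind(idx0 %% d[1],
                 (idx0 %/% d[1]) %% d[2],
                 idx0 %/% (d[1] * d[2])) + 0
    src <- mv$values
    storage.mode(src) <- "double"
    A_src_inv <- solve(mv$grid$index_to_world)
    A_tgt <- fx$grid$index_to_world
    function(p_active) {
      p <- par; p[active] <- p_active
      M <- A_src_inv %*% solve(affine_from_params(p, dof = dof)) %*% A_tgt
      mvals <- .interp_points_cpp(src, dim(src), M, pts)
      switch(cost,
             cr = cr_cost(fvals, mvals),
             ssd = ssd_cost(fvals, mvals),
             ncc = {
               ok <- !is.na(mvals)
               if (sum(ok) < 100L) 2
               else 1 - suppressWarnings(
                 stats::cor(fvals[ok], mvals[ok]))^2
             })
    }
  }
  for (lev in seq_along(pyr_f)) {
    fn <- cost_fun_factory(pyr_f[[lev]], pyr_m[[lev]])
    nm_iter <- if (lev == 1L) maxit else maxit %/% 2L
    opt <- optim(par[active], fn, method = "Nelder-Mead",
                 control = list(maxit = nm_iter, reltol = 1e-9,
                                parscale = parscale[active]))
    par[active] <- opt$par
    # gradient-based polish (numeric central differences)
    opt <- optim(par[active], fn, method = "BFGS",
                 control = list(maxit = 15L, reltol = 1e-10,
                                parscale = parscale[active],
                                ndeps = rep(1e-3, length(active))))
    par[active] <- opt$par
  }
  final <- affine_transform(affine_from_params(par, dof = dof),
                            source_space, target_space, dof = dof)
  attr(final, "cost") <- opt$value
  attr(final, "params") <- par
  final
}
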