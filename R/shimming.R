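#' Compute the optimal static shim for a field map
#'
#' Finds the shim setting s minimizing the sum of squared values of
#' `field + synthesize(s)` over the masked voxels — the masked linear
#' least-squares shim. The DC term is always in the design, so minimizing
#' the residual RMS is the same as minimizing its standard deviation. The
#' optimal coefficients are the negated harmonic projection of the field.
#'
#' @param field A [field_map()] in Hz.
#' @param basis A [build_basis()] result of order >= `max_order`.
#' @param mask Logical array (defaults to the field's brain mask); must
#'   contain at least as many voxels as terms.
#' @param max_order Shim order to use: 1, 2 (typical hardware) or 3.
#' @return A [shim_setting()]; attribute `residual_std_Hz` holds the
#'   achieved residual.
#' @export
compute_shim <- function(field, basis, mask = NULL, max_order = 2L) {
  if (!max_order %in% 1:3)
    stop_fieldshim("max_order must be 1, 2 or 3", "fs_invalid_order")
  if (basis$max_order < max_order)
    stop_fieldshim("basis order too low for requested shim order",
                   "fs_invalid_order")
  mask <- as_mask(mask %||% field$brain_mask)
  if (is.null(mask) || !any(mask))
    stop_fieldshim("empty mask", "fs_empty_mask")
  keep <- basis$terms$order <= max_order
  idx <- which(mask)
  y <- field$values[idx]
  X <- basis$B[idx, keep, drop = FALSE]
  fit <- solve_harmonic_lsq(X, -y, basis$terms$name[keep])
  setting <- shim_setting(fit$coefficients, as.integer(max_order))
  attr(setting, "residual_std_Hz") <- pop_sd(-fit$residuals)
  setting
}

#' Residual field standard deviation after applying a shim
#'
#' Population (divisor N) standard deviation of `field + synthesize(shim)`
#' over the masked voxels — the figure of merit for all strategy
#' comparisons.
#'
#' @param field A [field_map()].
#' @param shim A [shim_setting()].
#' @param basis A [build_basis()] result on the field grid.
#' @param mask Logical array (defaults to the field's brain mask).
#' @return Residual standard deviation in Hz.
#' @export
residual_std <- function(field, shim, basis, mask = NULL) {
  mask <- as_mask(mask %||% field$brain_mask)
  if (is.null(mask) || !any(mask))
    stop_fieldshim("empty mask", "fs_empty_mask")
  res <- field$values[mask] +
    as.vector(basis$B[which(mask), names(shim$coefficients),
                      drop = FALSE] %*% shim$coefficients)
  pop_sd(res)
}

# Residual stds for many settings at once (rows of `S` are term
# coefficients); used for the random-shim Monte Carlo.
residual_std_many <- function(field, S, term_names, basis, mask) {
  idx <- which(mask)
  R <- field$values[idx] +
    basis$B[idx, term_names, drop = FALSE] %*% t(S)
  apply(R, 2, pop_sd)
}

#' Draw random shim settings within per-term bounds
#'
#' Monte-Carlo shims: each term is drawn uniformly and independently
#' between the minimum and maximum of the individual fixed shim values
#' observed across a database of subjects.
#'
#' @param n Number of settings (> 0).
#' @param per_term_range Two-row matrix (rows `min`, `max`) with one named
#'   column per term, or a list with `min`/`max` named vectors.
#' @param seed Optional integer seed.
#' @return List of [shim_setting()]s.
#' @export
random_shims <- function(n, per_term_range, seed = NULL) {
  if (!(length(n) == 1L && n >= 1))
    stop_fieldshim("n must be a positive integer", "fs_invalid_argument")
  if (is.list(per_term_range) && !is.matrix(per_term_range))
    per_term_range <- rbind(min = per_term_range$min,
                            max = per_term_range$max)
  lo <- per_term_range["min", ]; hi <- per_term_range["max", ]
  stopifnot(all(lo <= hi))
  terms <- colnames(per_term_range)
  draw <- function() shim_setting(structure(runif(length(lo), lo, hi),
                                            names = terms))
  if (is.null(seed)) replicate(n, draw(), simplify = FALSE)
  else with_seed(seed, replicate(n, draw(), simplify = FALSE))
}

#' Per-term range of a set of shim settings
#'
#' @param shims List of [shim_setting()]s sharing a term set.
#' @return Two-row matrix (`min`, `max`) with one column per term.
#' @export
shim_range <- function(shims) {
  M <- shim_matrix(shims)
  rbind(min = apply(M, 2, min), max = apply(M, 2, max))
}

shim_matrix <- function(shims) {
  nm <- names(shims[[1]]$coefficients)
  for (s in shims)
    if (!identical(sort(names(s$coefficients)), sort(nm)))
      stop_fieldshim("shim settings have mismatched term sets",
                     "fs_term_mismatch")
  M <- vapply(shims, function(s) s$coefficients[nm], numeric(length(nm)))
  M <- t(matrix(M, nrow = length(nm)))
  colnames(M) <- nm
  M
}

#' Termwise average of shim settings
#'
#' The "averaged fixed shim": the arithmetic mean, term by term, of the
#' individual optimal shims across a database.
#'
#' @param individual_shims Nonempty list of [shim_setting()]s with a
#'   common term set.
#' @return A [shim_setting()].
#' @export
averaged_fixed_shim <- function(individual_shims) {
  if (length(individual_shims) < 1L)
    stop_fieldshim("need at least one shim", "fs_invalid_argument")
  M <- shim_matrix(individual_shims)
  shim_setting(colMeans(M), individual_shims[[1]]$max_order)
}

#' Paired Wilcoxon signed-rank test
#'
#' Signed-rank test on paired residuals. Zero differences are dropped
#' (Wilcoxon's original treatment); tied absolute differences share
#' mid-ranks. For n <= 12 retained pairs the null distribution is
#' enumerated exactly over all 2^n sign patterns; above that a normal
#' approximation with tie correction and continuity correction is used.
#' If every difference is zero the result is defined as p = 1.
#'
#' @param a,b Equal-length (>= 5) paired numeric vectors.
#' @return List with `statistic` (V, sum of positive ranks), `p_value`
#'   (two-sided), `n_used`, `method`.
#' @export
wilcoxon_paired <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 5L)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = 0, p_value = 1, n_used = 0L,
                method = "all differences zero"))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= 12L) {
    # exact: distribution of the positive-rank sum over all sign patterns
    dist <- 0
    for (ri in r) dist <- c(dist, dist + ri)  # sums over subsets
    p_le <- mean(dist <= V + 1e-9)
    p_ge <- mean(dist >= V - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation with tie correction"
  }
  list(statistic = V, p_value = p, n_used = n, method = method)
}
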