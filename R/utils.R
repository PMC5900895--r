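`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrap phase values to the principal interval
#'
#' Maps arbitrary phase values (radians) to the half-open interval
#' \eqn{(-\pi, \pi]}.
#'
#' @param x Numeric vector or array of phase values in radians.
#' @return Object of the same shape with values in \eqn{(-\pi, \pi]}.
#' @export
#' @examples
#' wrap_phase(c(0, pi, -pi, 3 * pi))
wrap_phase <- function(x) {
  x - 2 * pi * ceiling((x - pi) / (2 * pi))
}

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_fieldshim <- function(msg, class) {
  stop(structure(class = c(class, "fieldshim_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# population (divisor N) standard deviation
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop_fieldshim("no finite values", "fs_empty_mask")
  sqrt(mean((x - mean(x))^2))
}

as_mask <- function(m) {
  if (is.null(m)) return(NULL)
  if (inherits(m, "fs_volume")) m <- m$values
  storage.mode(m) <- "logical"
  m & !is.na(m)
}
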