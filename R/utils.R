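# Internal helpers shared across modules.

# Vacuum permeability, T m / A
MU0 <- 4e-7 * pi

#' Evaluate code with a temporary RNG seed
#'
#' Runs \code{code} under \code{set.seed(seed)} and restores the caller's RNG
#' state afterwards, so seeded generators do not disturb the global stream.
#' A \code{NULL} seed evaluates \code{code} with the current stream.
#'
#' @param seed integer seed or \code{NULL}.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

check_scalar <- function(x, name, lower = -Inf, strict = FALSE,
                         finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single non-missing number", name),
         call. = FALSE)
  if (finite && !is.finite(x))
    stop(sprintf("'%s' must be finite", name), call. = FALSE)
  if (strict && x <= lower)
    stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  if (!strict && x < lower)
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  invisible(x)
}

check_unit_axis <- function(axis, tol = 1e-8) {
  if (!is.numeric(axis) || length(axis) != 3L || anyNA(axis))
    stop("'axis' must be a numeric 3-vector", call. = FALSE)
  if (abs(sqrt(sum(axis^2)) - 1) > tol)
    stop("'axis' must be a unit vector (|axis| = 1)", call. = FALSE)
  invisible(axis)
}
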