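#' Normalised sinc function
#'
#' `sinc(x) = sin(pi*x)/(pi*x)` with `sinc(0) = 1`. This is the convention used
#' throughout the closed-form spectra of finite oscillatory Poisson processes.
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length.
#' @examples
#' sinc(0)    # 1
#' sinc(1:3)  # exactly 0 at the integers
#' @export
sinc <- function(x) {
  out <- rep(1, length(x))
  nz <- x != 0
  out[nz] <- sin(pi * x[nz]) / (pi * x[nz])
  out
}

# Run `expr` under a given seed without disturbing the caller's RNG stream.
# seed = NULL means "use the current stream" (no save/restore).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}
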