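# internal helpers: argument checking and seed management

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stopf("'%s' must be a number, not NULL", name)
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (x < lower || x > upper)
    stopf("'%s' = %g is outside [%g, %g]", name, x, lower, upper)
  invisible(x)
}

check_positive <- function(x, name) check_number(x, name, lower = 0)

#' Derive a reproducible sub-seed from a master seed
#'
#' All stochastic generators in the package draw their randomness from a
#' single integer seed through this counter-based splitter, so that
#' independent simulation stages (traces, ensembles, decays) can be
#' reproduced in isolation without sharing R's global RNG stream.
#'
#' @param seed Master integer seed.
#' @param stream Non-negative integer stream counter.
#' @return An integer in `[0, 2^31 - 2]`, suitable for [set.seed()].
#' @examples
#' split_seed(1, 0)
#' split_seed(1, 1)
#' @export
split_seed <- function(seed, stream = 0L) {
  check_number(seed, "seed")
  check_number(stream, "stream", lower = 0)
  # affine congruential mix over the Mersenne prime 2^31 - 1; keeps every
  # derived seed a valid 32-bit R seed and distinct across small streams
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m)
  s <- (s * 48271 + 1) %% m
  s <- (s + as.numeric(stream) * 1000003) %% m
  as.integer(s)
}

# evaluate `code` under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}
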