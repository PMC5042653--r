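#' Equilibrium complex concentration under mass action
#'
#' Solves the bimolecular binding equilibrium `A + B <-> AB` for the complex
#' concentration given the total concentrations of both partners and the
#' dissociation constant, i.e. the root of
#' \deqn{(A_{tot} - x)(B_{tot} - x) = K_d \, x}
#' that satisfies `0 <= x <= min(A_tot, B_tot)`. This is the ground truth
#' used by the binding-ensemble simulator.
#'
#' The root is evaluated in the numerically stable form
#' `x = 2ab / (s + sqrt(s^2 - 4ab))` with `s = a + b + kd`, which avoids the
#' catastrophic cancellation of the textbook quadratic formula when
#' `kd << a, b`.
#'
#' @param total_a,total_b Total concentrations of the two partners (nM).
#'   Vectorised; recycled to a common length.
#' @param kd Dissociation constant (nM); `kd = 0` forces full complexation.
#' @return Complex concentration(s) in nM.
#' @examples
#' solve_equilibrium(100, 100, 15)
#' solve_equilibrium(100, 100, 0)   # == 100
#' @export
solve_equilibrium <- function(total_a, total_b, kd) {
  if (!is.numeric(total_a) || !is.numeric(total_b) || !is.numeric(kd))
    stopf("all arguments must be numeric")
  if (any(!is.finite(total_a)) || any(!is.finite(total_b)) || !all(is.finite(kd)))
    stopf("all arguments must be finite")
  if (any(total_a < 0) || any(total_b < 0))
    stopf("total concentrations must be non-negative")
  if (any(kd < 0)) stopf("'kd' must be non-negative")
  n <- max(length(total_a), length(total_b), length(kd))
  a <- rep_len(total_a, n); b <- rep_len(total_b, n); k <- rep_len(kd, n)
  s <- a + b + k
  disc <- s^2 - 4 * a * b
  disc[disc < 0] <- 0  # guard rounding at kd = 0, a = b
  x <- ifelse(s > 0, 2 * a * b / (s + sqrt(disc)), 0)
  pmin(x, pmin(a, b))
}
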