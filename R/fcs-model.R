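#' Parameters of the anomalous-diffusion correlation model
#'
#' Bundles the parameters of the one/two-component anomalous-diffusion FCS
#' model (see [eval_acf_model()]): mean occupancy `N` of the focal volume,
#' slow-component fraction `F2` (the DNA-bound fraction in transcription
#' factor measurements; `F1 = 1 - F2`), diffusion times `tauD1 < tauD2`,
#' anomaly exponents `alpha1`, `alpha2`, baseline offset `G_inf`, and the
#' structure parameter `kappa` (axial/lateral focus ratio).
#'
#' @param N Mean number of molecules in the focus (> 0).
#' @param F2 Slow-component fraction in `[0, 1]`; 0 gives the one-component
#'   model.
#' @param tauD1,tauD2 Diffusion times in seconds (fast, slow); the
#'   convention `tauD1 < tauD2` is enforced by relabelling after fits.
#' @param alpha1,alpha2 Anomaly exponents in `(0.2, 2]`; 1 is free
#'   diffusion, < 1 subdiffusion.
#' @param G_inf Baseline offset of the correlation function.
#' @param kappa Structure parameter `z0/w0` (>= 1).
#' @return An object of class `fcs_model_params`.
#' @examples
#' fcs_model_params(N = 6, F2 = 0.27, tauD1 = 3.03e-3, tauD2 = 0.1)
#' @export
fcs_model_params <- function(N, F2 = 0, tauD1, tauD2 = NA_real_,
                             alpha1 = 1, alpha2 = 1, G_inf = 0, kappa = 5) {
  check_number(N, "N", lower = 1e-12)
  check_number(F2, "F2", lower = 0, upper = 1)
  check_number(tauD1, "tauD1", lower = 1e-12)
  if (F2 > 0) check_number(tauD2, "tauD2", lower = 1e-12)
  check_number(alpha1, "alpha1", lower = 0.2, upper = 2)
  check_number(alpha2, "alpha2", lower = 0.2, upper = 2)
  check_number(G_inf, "G_inf")
  check_number(kappa, "kappa", lower = 1)
  structure(list(N = N, F1 = 1 - F2, F2 = F2, tauD1 = tauD1, tauD2 = tauD2,
                 alpha1 = alpha1, alpha2 = alpha2, G_inf = G_inf,
                 kappa = kappa),
            class = "fcs_model_params")
}

#' @export
print.fcs_model_params <- function(x, ...) {
  cat(sprintf("FCS model: N = %.4g, F2 = %.3f, tauD1 = %.4g s", x$N, x$F2,
              x$tauD1))
  if (x$F2 > 0) cat(sprintf(", tauD2 = %.4g s", x$tauD2))
  cat(sprintf("\n  alpha = (%.3g, %.3g), G_inf = %.3g, kappa = %.3g\n",
              x$alpha1, x$alpha2, x$G_inf, x$kappa))
  invisible(x)
}

#' Evaluate the anomalous-diffusion correlation model
#'
#' The two-component anomalous-diffusion model for a 3D Gaussian focus:
#' \deqn{G(\tau) = G_\infty + \frac{1}{N}\sum_{i=1}^{2} F_i
#'   \left[1 + \left(\frac{\tau}{\tau_{D,i}}\right)^{\alpha_i}\right]^{-1}
#'   \left[1 + \frac{(\tau/\tau_{D,i})^{\alpha_i}}{\kappa^2}\right]^{-1/2}}
#' With `F2 = 0` this reduces to the one-component model. The zero-lag
#' amplitude is `G_inf + 1/N`, which links the fit to absolute
#' concentration via the calibrated focal volume.
#'
#' @param params An [fcs_model_params()].
#' @param lags Positive lag times in seconds.
#' @return Model values `G(lags)`.
#' @export
eval_acf_model <- function(params, lags) {
  stopifnot(inherits(params, "fcs_model_params"))
  if (any(lags <= 0)) stopf("lags must be positive")
  comp <- function(tauD, alpha) {
    u <- (lags / tauD)^alpha
    1 / ((1 + u) * sqrt(1 + u / params$kappa^2))
  }
  g <- params$F1 * comp(params$tauD1, params$alpha1)
  if (params$F2 > 0) g <- g + params$F2 * comp(params$tauD2, params$alpha2)
  params$G_inf + g / params$N
}
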