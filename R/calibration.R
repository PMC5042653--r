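#' Calibrate the confocal focal volume from a reference-dye curve
#'
#' Converts the fitted diffusion time of a reference dye with known
#' diffusion coefficient into the lateral focus radius and effective
#' detection volume:
#' \deqn{w_0 = \sqrt{4 D_{dye} \tau_{D,dye}}, \qquad
#'   V_{eff} = \pi^{3/2} \kappa w_0^3}
#' Calibration is the step that turns fitted molecule numbers into absolute
#' concentrations and diffusion times into coefficients; it is performed per
#' detection channel (e.g. Atto 488 for the green channel, Rhodamine 6G for
#' the red one).
#'
#' The dye curve is fit with the one-component model. If a two-component fit
#' finds appreciable slow structure (`F2 >= 0.05` and `tauD2/tauD1 >= 3`),
#' a warning is issued — aggregates or dirt in the calibration solution —
#' and the one-component result is used regardless.
#'
#' @param dye_curve A [correlation_curve()] of the calibration dye, or a
#'   number interpreted directly as the dye diffusion time in seconds.
#' @param known_D Dye diffusion coefficient in µm²/s (e.g. 400 for
#'   Atto 488 at room temperature).
#' @param kappa Structure parameter (fixed).
#' @param channel `"green"` or `"red"`.
#' @param fix_alpha Fit the dye with the anomaly exponent pinned to 1
#'   (default). A free dye diffuses normally, and at the short diffusion
#'   times of calibration dyes a free exponent is degenerate with `tauD`,
#'   destabilising the volume estimate.
#' @return An object of class `focus_calibration`: `w0` (µm), `z0` (µm),
#'   `V_eff` (fl), `tauD_dye` (s), `dye_D` (µm²/s), `channel`.
#' @examples
#' calibrate_focus(25e-6, known_D = 400)  # w0 = 0.2 um
#' @export
calibrate_focus <- function(dye_curve, known_D, kappa = 5,
                            channel = c("green", "red"), fix_alpha = TRUE) {
  channel <- match.arg(channel)
  check_number(known_D, "known_D", lower = 1e-9)
  check_number(kappa, "kappa", lower = 1)
  if (is.numeric(dye_curve) && length(dye_curve) == 1L) {
    tauD <- dye_curve
    fit <- NULL
  } else {
    stopifnot(inherits(dye_curve, "correlation_curve"))
    two <- fit_acf(dye_curve, model = "two", kappa = kappa)
    if (is.null(two$failure) && two$n_components_effective == 2L)
      warnf(paste("calibration dye curve shows two-component structure",
                  "(F2 = %.2f); using the one-component fit"), two$params$F2)
    fit <- fit_acf(dye_curve, model = "one", kappa = kappa,
                   fixed = if (fix_alpha) list(alpha1 = 1) else NULL)
    if (!is.null(fit$failure)) stopf("dye curve fit failed: %s", fit$failure)
    tauD <- fit$params$tauD1
  }
  check_number(tauD, "tauD_dye", lower = 1e-12)
  w0 <- sqrt(4 * known_D * tauD)           # µm
  z0 <- kappa * w0
  v_eff <- pi^1.5 * kappa * w0^3           # µm³ == fl
  structure(list(w0 = w0, z0 = z0, V_eff = v_eff, tauD_dye = tauD,
                 dye_D = known_D, kappa = kappa, channel = channel,
                 fit = fit),
            class = "focus_calibration")
}

#' @export
print.focus_calibration <- function(x, ...) {
  cat(sprintf(
    "Focal volume calibration (%s): w0 = %.4g um, z0 = %.4g um, V_eff = %.4g fl\n",
    x$channel, x$w0, x$z0, x$V_eff))
  cat(sprintf("  dye: D = %g um^2/s, tauD = %.4g s\n", x$dye_D, x$tauD_dye))
  invisible(x)
}

#' Convert fitted model parameters to physical quantities
#'
#' Uses a focal-volume calibration to express an anomalous-diffusion fit in
#' absolute units: concentration `C = N / (N_A V_eff)` (nM) and diffusion
#' coefficients `D_i = w0^2 / (4 tauD_i)` (µm²/s).
#'
#' @param fit An [fit_acf()] result or an [fcs_model_params()].
#' @param calib A [calibrate_focus()] result.
#' @return A list with `concentration_nM`, `D1`, `D2` (µm²/s; `D2 = NA`
#'   for one-component fits) and the calibration used.
#' @export
derive_physical <- function(fit, calib) {
  stopifnot(inherits(calib, "focus_calibration"))
  params <- if (inherits(fit, "fcs_fit")) {
    if (!is.null(fit$failure)) stopf("cannot derive physics from a failed fit")
    fit$params
  } else if (inherits(fit, "fcs_model_params")) fit
  else stopf("'fit' must be an fcs_fit or fcs_model_params")
  conc <- params$N / calib$V_eff * .NM_PER_MOLECULE_FL
  d1 <- calib$w0^2 / (4 * params$tauD1)
  d2 <- if (is.finite(params$tauD2 %||% NA_real_))
    calib$w0^2 / (4 * params$tauD2) else NA_real_
  list(concentration_nM = conc, D1 = d1, D2 = d2, calibration = calib)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Molecular-brightness quality control
#'
#' The molecular brightness — mean detected intensity divided by the fitted
#' mean number of molecules in the focus — is robust in the intensity but
#' highly sensitive to optical aberrations through `N`. Measurements whose
#' brightness falls outside a ±10% window around a reference value (the
#' free-fluorophore brightness in unaberrated nuclei) are flagged, which
#' guards the derived concentrations and diffusion coefficients against
#' refractive-index mismatch deep in the specimen.
#'
#' @param mean_intensity Mean detected intensity, counts/s.
#' @param N Fitted mean number of molecules in the focus (> 0).
#' @param reference Reference brightness, counts/s/molecule (> 0).
#' @param window Acceptance half-width on the brightness ratio (default
#'   0.10, i.e. ±10%).
#' @return A list of class `brightness_qc`: `brightness`, `reference`,
#'   `ratio` and the boolean `pass`.
#' @export
brightness_qc <- function(mean_intensity, N, reference, window = 0.10) {
  check_number(mean_intensity, "mean_intensity", lower = 0)
  check_number(N, "N", lower = 1e-12)
  if (!is.numeric(reference) || length(reference) != 1L || reference <= 0)
    stopf("'reference' brightness must be a positive number")
  check_number(window, "window", lower = 0)
  b <- mean_intensity / N
  ratio <- b / reference
  structure(list(brightness = b, reference = reference, ratio = ratio,
                 window = window, pass = abs(ratio - 1) <= window),
            class = "brightness_qc")
}

#' @export
print.brightness_qc <- function(x, ...) {
  cat(sprintf("Brightness QC: %.4g counts/s/molecule (ratio %.3f vs reference) — %s\n",
              x$brightness, x$ratio, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}
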