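#' Correct spectral bleed-through in dual-color correlation amplitudes
#'
#' Removes the contamination of the red autocorrelation and of the
#' cross-correlation caused by green fluorophore emission leaking into the
#' red detection channel. With bleed-through coefficient `beta` (the
#' red/green detected-intensity ratio of a green-only control) and measured
#' intensities, the measured red signal is `r_m = r + beta g`, and the
#' amplitude relations invert to
#' \deqn{G_x = (G_{x,m} I_{r,m} - \beta G_g I_g) / I_r}
#' \deqn{G_r = (G_{r,m} I_{r,m}^2 - 2\beta G_x I_g I_r -
#'   \beta^2 G_g I_g^2) / I_r^2}
#' with `I_r = I_{r,m} - beta I_g`. The green channel is unaffected.
#'
#' @param G_g0 Green ACF amplitude (uncontaminated).
#' @param G_r0 Measured red ACF amplitude.
#' @param G_x0 Measured cross-correlation amplitude.
#' @param bleedthrough Coefficient `beta` in `[0, 1)`.
#' @param intensities Named numeric `c(g = ..., r = ...)`: mean detected
#'   intensities (the red one as measured, i.e. contaminated).
#' @return List with corrected `G_g0`, `G_r0`, `G_x0` and true intensities.
#' @export
correct_crosstalk <- function(G_g0, G_r0, G_x0, bleedthrough, intensities) {
  check_number(bleedthrough, "bleedthrough", lower = 0, upper = 1 - 1e-12)
  check_number(G_g0, "G_g0"); check_number(G_r0, "G_r0")
  check_number(G_x0, "G_x0")
  if (bleedthrough == 0)
    return(list(G_g0 = G_g0, G_r0 = G_r0, G_x0 = G_x0,
                intensities = intensities))
  ig <- intensities[["g"]]; irm <- intensities[["r"]]
  check_number(ig, "intensities['g']", lower = 0)
  check_number(irm, "intensities['r']", lower = 0)
  ir <- irm - bleedthrough * ig
  if (ir <= 0)
    stopf("bleed-through correction leaves no red signal (I_r <= 0)")
  gx <- (G_x0 * irm - bleedthrough * G_g0 * ig) / ir
  gr <- (G_r0 * irm^2 - 2 * bleedthrough * gx * ig * ir -
           bleedthrough^2 * G_g0 * ig^2) / ir^2
  list(G_g0 = G_g0, G_r0 = gr, G_x0 = gx,
       intensities = c(g = ig, r = ir))
}

#' Convert dual-color correlation amplitudes to concentrations
#'
#' With offset-subtracted, cross-talk-corrected zero-lag amplitudes and
#' per-channel focal calibrations, total concentrations and the complex
#' concentration follow from
#' \deqn{C_{tot,g} = 1/(G_{g0} N_A V_g), \quad
#'   C_{tot,r} = 1/(G_{r0} N_A V_r), \quad
#'   C_{complex} = G_{x0}/(G_{g0} G_{r0} N_A V_x)}
#' Free concentrations are totals minus complex, floored at zero with a QC
#' flag when flooring occurred (amplitude noise near full association can
#' push free estimates below zero). Cells with non-positive ACF amplitudes
#' are rejected with a reason instead of producing concentrations.
#'
#' @param G_g0,G_r0 Green / red ACF amplitudes (> 0 for a usable cell).
#' @param G_x0 Cross-correlation amplitude (may be 0 or slightly negative
#'   for unassociated proteins; clipped to 0 for the complex estimate).
#' @param calib_g,calib_r [calibrate_focus()] results for each channel.
#' @param V_x Overlap volume in fl; defaults to the green-channel `V_eff`.
#' @param cell_id Identifier carried through to the result.
#' @return An object of class `dual_color_result`: free and complex
#'   concentrations (nM), totals, `association_pct`, flags `floored`,
#'   `rejected`, `qc_pass`.
#' @export
amplitudes_to_concentrations <- function(G_g0, G_r0, G_x0, calib_g, calib_r,
                                         V_x = NULL, cell_id = NA_character_) {
  stopifnot(inherits(calib_g, "focus_calibration"),
            inherits(calib_r, "focus_calibration"))
  if (is.null(V_x)) V_x <- calib_g$V_eff
  rej <- function(why) structure(
    list(cell_id = cell_id, C_free_g = NA_real_, C_free_r = NA_real_,
         C_complex = NA_real_, C_complex_raw = NA_real_,
         total_g = NA_real_, total_r = NA_real_,
         association_pct = NA_real_, floored = FALSE, rejected = TRUE,
         reason = why, qc_pass = FALSE),
    class = "dual_color_result")
  if (!is.finite(G_g0) || G_g0 <= 0) return(rej("non-positive green ACF amplitude"))
  if (!is.finite(G_r0) || G_r0 <= 0) return(rej("non-positive red ACF amplitude"))
  total_g <- .NM_PER_MOLECULE_FL / (G_g0 * calib_g$V_eff)
  total_r <- .NM_PER_MOLECULE_FL / (G_r0 * calib_r$V_eff)
  # the signed estimate is kept alongside the physical (clipped) one:
  # regression across cells must see symmetric noise around zero complex,
  # or unassociated ensembles acquire a spurious size-correlated slope
  cx_raw <- G_x0 / (G_g0 * G_r0) * .NM_PER_MOLECULE_FL / V_x
  cx <- max(cx_raw, 0)
  floored <- FALSE
  free_g <- total_g - cx
  free_r <- total_r - cx
  if (free_g < 0 || free_r < 0) {
    floored <- TRUE
    free_g <- max(free_g, 0); free_r <- max(free_r, 0)
    cx <- min(cx, min(total_g, total_r))
  }
  assoc <- 100 * cx / min(total_g, total_r)
  structure(list(cell_id = cell_id, C_free_g = unname(free_g),
                 C_free_r = unname(free_r), C_complex = unname(cx),
                 C_complex_raw = unname(cx_raw),
                 total_g = unname(total_g), total_r = unname(total_r),
                 association_pct = unname(assoc), floored = floored,
                 rejected = FALSE, reason = NA_character_,
                 qc_pass = !floored),
            class = "dual_color_result")
}

#' @export
print.dual_color_result <- function(x, ...) {
  if (x$rejected) {
    cat(sprintf("Dual-color cell %s: REJECTED (%s)\n", x$cell_id, x$reason))
    return(invisible(x))
  }
  cat(sprintf(
    "Dual-color cell %s: free (%.3g, %.3g) nM, complex %.3g nM, association %.1f%%%s\n",
    x$cell_id, x$C_free_g, x$C_free_r, x$C_complex, x$association_pct,
    if (x$floored) " [floored]" else ""))
  invisible(x)
}

#' @export
as.data.frame.dual_color_result <- function(x, ...)
  data.frame(cell_id = x$cell_id, C_free_g = x$C_free_g,
             C_free_r = x$C_free_r, C_complex = x$C_complex,
             C_complex_raw = x$C_complex_raw,
             total_g = x$total_g, total_r = x$total_r,
             association_pct = x$association_pct, floored = x$floored,
             rejected = x$rejected, qc_pass = x$qc_pass)

#' Fraction of proteins diffusing together in the same complex
#'
#' `100 * C_complex / min(C_total_g, C_total_r)` — the association
#' percentage relative to the limiting partner.
#'
#' @param result A [amplitudes_to_concentrations()] result, or a list with
#'   `C_complex`, `total_g`, `total_r`.
#' @return Percentage in `[0, 100]`, or `NA` (with a warning) when a total
#'   is zero.
#' @export
association_fraction <- function(result) {
  cx <- result$C_complex
  lim <- min(result$total_g, result$total_r)
  if (!is.finite(lim) || lim <= 0) {
    warnf("association undefined: limiting total concentration is zero")
    return(NA_real_)
  }
  100 * cx / lim
}

#' Analyse one dual-color cell from its curve triplet
#'
#' Fits the two ACFs with the two-component anomalous-diffusion model and
#' the CCF with a one-component model, takes the offset-subtracted
#' zero-lag amplitudes (`1/N`), applies the bleed-through correction, and
#' converts to concentrations. A CCF without positive amplitude (no
#' co-diffusion) yields zero complex rather than a rejection.
#'
#' @param curves List with elements `ACF_g`, `ACF_r`, `CCF`
#'   ([correlation_curve()] objects).
#' @param calib_g,calib_r Channel calibrations.
#' @param bleedthrough Spectral bleed-through coefficient.
#' @param cell_id Identifier.
#' @param kappa Structure parameter for the fits.
#' @return A [amplitudes_to_concentrations()] result with the three fits
#'   attached as attribute `"fits"`.
#' @export
fit_fccs_cell <- function(curves, calib_g, calib_r, bleedthrough = 0,
                          cell_id = NA_character_, kappa = 5) {
  for (nm in c("ACF_g", "ACF_r", "CCF"))
    if (!inherits(curves[[nm]], "correlation_curve"))
      stopf("'curves$%s' must be a correlation_curve", nm)
  fg <- fit_acf(curves$ACF_g, model = "two", kappa = kappa)
  fr <- fit_acf(curves$ACF_r, model = "two", kappa = kappa)
  fx <- fit_acf(curves$CCF, model = "one", kappa = kappa)
  amp <- function(f) if (is.null(f$failure)) 1 / f$params$N else NA_real_
  g_g0 <- amp(fg); g_r0 <- amp(fr)
  g_x0 <- if (is.null(fx$failure)) 1 / fx$params$N else {
    # no positive CCF amplitude: moment estimate (may be ~0 or negative)
    mean(head(curves$CCF$G, 3L)) - median(tail(curves$CCF$G, 5L))
  }
  inten <- curves$ACF_g$mean_intensity
  if (length(inten) < 2L) inten <- c(g = 1, r = 1)
  corr <- correct_crosstalk(g_g0, g_r0, g_x0, bleedthrough, inten)
  out <- amplitudes_to_concentrations(corr$G_g0, corr$G_r0, corr$G_x0,
                                      calib_g, calib_r, cell_id = cell_id)
  attr(out, "fits") <- list(ACF_g = fg, ACF_r = fr, CCF = fx)
  out
}

#' Estimate the dissociation constant from a cell ensemble
#'
#' Across cells in binding equilibrium, mass action gives
#' `C_free_g * C_free_r = Kd * C_complex`, so a regression through the
#' origin of the free-concentration product on the complex concentration
#' has slope `Kd`. Association is declared when the relation is linear
#' (squared Pearson correlation above `r2_threshold`); otherwise the
#' ensemble is reported as non-linear ("N.L") and no Kd is quoted. Cells
#' where flooring occurred are excluded by default (their free
#' concentrations are biased toward zero), as are rejected cells.
#'
#' @param cells List of [amplitudes_to_concentrations()] results, or a
#'   data.frame with columns `C_free_g`, `C_free_r`, `C_complex` (and
#'   optionally `floored`, `rejected`).
#' @param r2_threshold Linearity criterion on `cor(x, y)^2`.
#' @param include_floored Keep floored cells in the regression.
#' @return An object of class `kd_estimate`: `kd` (nM), `se`, `r_squared`,
#'   `n_cells`, `linear`.
#' @export
estimate_kd <- function(cells, r2_threshold = 0.5, include_floored = FALSE) {
  d <- if (is.data.frame(cells)) cells else
    do.call(rbind, lapply(cells, as.data.frame))
  if (!is.null(d$rejected)) d <- d[!d$rejected, , drop = FALSE]
  if (!include_floored && !is.null(d$floored))
    d <- d[!d$floored, , drop = FALSE]
  n <- nrow(d)
  if (n < 3L) stopf("need at least 3 usable cells (have %d)", n)
  if (n < 15L) warnf("only %d cells; Kd estimates are reported for n > 15",
                     n)
  if (!is.null(d$C_complex_raw) && !is.null(d$total_g)) {
    # signed complex estimates keep the noise symmetric around zero,
    # which is what lets a no-association ensemble fail the linearity test
    x <- d$C_complex_raw
    y <- (d$total_g - x) * (d$total_r - x)
  } else {
    x <- d$C_complex
    y <- d$C_free_g * d$C_free_r
  }
  r2 <- if (sd(x) > 0 && sd(y) > 0) cor(x, y)^2 else 0
  fit <- lm(y ~ 0 + x)
  kd <- unname(coef(fit)[1])
  se <- sqrt(diag(vcov(fit)))[1]
  linear <- is.finite(r2) && r2 >= r2_threshold && is.finite(kd) && kd > 0
  structure(list(kd = if (linear) kd else NA_real_, slope = kd,
                 se = unname(se), r_squared = r2, n_cells = n,
                 linear = linear, data = d, fit = fit),
            class = "kd_estimate")
}

#' @export
print.kd_estimate <- function(x, ...) {
  if (x$linear)
    cat(sprintf("Kd = %.4g +/- %.2g nM (n = %d cells, r^2 = %.3f)\n",
                x$kd, x$se, x$n_cells, x$r_squared))
  else
    cat(sprintf("No association detected (N.L): r^2 = %.3f, n = %d cells\n",
                x$r_squared, x$n_cells))
  invisible(x)
}

#' @export
coef.kd_estimate <- function(object, ...) c(kd = object$kd)

#' @export
summary.kd_estimate <- function(object, ...) {
  print(object)
  cat(sprintf("  mean association: %.1f%%\n",
              mean(object$data$association_pct, na.rm = TRUE)))
  invisible(object)
}

#' @export
plot.kd_estimate <- function(x, ...) {
  plot(x$data$C_complex, x$data$C_free_g * x$data$C_free_r,
       xlab = expression(C[complex] ~ "(nM)"),
       ylab = expression(C[free * ",g"] %.% C[free * ",r"] ~ (nM^2)),
       pch = 16, ...)
  if (x$linear) abline(0, x$kd, col = "red3")
  invisible(x)
}
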