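# S3 methods for fitted correlation models

#' @export
print.fcs_fit <- function(x, ...) {
  if (!is.null(x$failure)) {
    cat(sprintf("FCS fit (%s-component): FAILED — %s\n", x$model, x$failure))
    return(invisible(x))
  }
  p <- x$params
  cat(sprintf("FCS fit (%s-component%s): %s\n", x$model,
              if (x$weighted) ", weighted" else "",
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  N = %.4g, G(0) amplitude = %.4g\n", p$N, 1 / p$N))
  if (x$model == "two")
    cat(sprintf("  F2 (slow/bound fraction) = %.3f\n", p$F2))
  cat(sprintf("  tauD1 = %.4g s (alpha1 = %.3g)\n", p$tauD1, p$alpha1))
  if (x$model == "two")
    cat(sprintf("  tauD2 = %.4g s (alpha2 = %.3g)\n", p$tauD2, p$alpha2))
  cat(sprintf("  G_inf = %.3g, reduced chi2 = %.4g\n", p$G_inf,
              x$chi2_reduced))
  if (x$model == "two" && x$n_components_effective == 1L)
    cat("  note: collapsed to an effective one-component model\n")
  invisible(x)
}

#' @export
coef.fcs_fit <- function(object, ...) {
  if (!is.null(object$failure)) return(NULL)
  p <- object$params
  c(N = p$N, F2 = p$F2, tauD1 = p$tauD1, tauD2 = p$tauD2,
    alpha1 = p$alpha1, alpha2 = p$alpha2, G_inf = p$G_inf)
}

#' @export
summary.fcs_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$se)) {
    cat("  standard errors:\n")
    for (nm in names(object$se))
      cat(sprintf("    %-7s %.4g\n", nm, object$se[[nm]]))
  }
  invisible(object)
}

#' @export
predict.fcs_fit <- function(object, lags = NULL, ...) {
  if (!is.null(object$failure)) stopf("cannot predict from a failed fit")
  if (is.null(lags)) lags <- object$lags
  eval_acf_model(object$params, lags)
}

#' @export
fitted.fcs_fit <- function(object, ...) object$fitted

#' @export
residuals.fcs_fit <- function(object, ...) object$residuals

#' @export
plot.fcs_fit <- function(x, ...) {
  if (!is.null(x$failure)) stopf("cannot plot a failed fit")
  op <- par(mfrow = c(2, 1), mar = c(1, 4, 2, 1))
  on.exit(par(op))
  plot(x$lags, x$G, log = "x", pch = 16, cex = 0.5, xaxt = "n",
       xlab = "", ylab = expression(G(tau)), ...)
  grid_lags <- exp(seq(log(min(x$lags)), log(max(x$lags)), length.out = 200))
  lines(grid_lags, predict(x, grid_lags), col = "red3", lwd = 1.5)
  par(mar = c(4, 4, 0.5, 1))
  plot(x$lags, x$residuals, log = "x", type = "h",
       xlab = expression(tau ~ "(s)"), ylab = "residual")
  abline(h = 0, col = "grey50")
  invisible(x)
}

#' Simulate replicate noisy curves from a fitted model
#'
#' Draws `nsim` synthetic correlation curves from the fitted
#' anomalous-diffusion model on the fit's own lag grid, using the curve's
#' per-lag sigma (or the residual scale when absent) as the noise level —
#' a quick parametric bootstrap for fit diagnostics.
#'
#' @param object An `fcs_fit`.
#' @param nsim Number of replicate curves.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of [correlation_curve()] objects.
#' @export
simulate.fcs_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(object$failure)) stopf("cannot simulate from a failed fit")
  sig <- if (!is.null(object$curve$sigma)) object$curve$sigma else
    rep(sd(object$residuals), length(object$lags))
  lapply(seq_len(nsim), function(i)
    simulate_model_acf(object$params, object$lags, noise_sd = sig,
                       seed = if (is.null(seed)) NULL else
                         split_seed(seed, i)))
}
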