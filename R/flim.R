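#' Construct a TCSPC decay histogram
#'
#' @param bin_time Bin width in ns.
#' @param counts Non-negative integer counts per bin.
#' @param irf Instrument response description: `list(fwhm, shift)` in ns
#'   for an analytic Gaussian IRF, or `NULL` for an ideal instrument.
#' @param metadata Free-form provenance list.
#' @return An object of class `decay_histogram`; `window = n_bins * bin_time`.
#' @export
decay_histogram <- function(bin_time, counts, irf = NULL, metadata = list()) {
  check_number(bin_time, "bin_time", lower = 1e-9)
  if (!is.numeric(counts) || length(counts) < 8L || any(counts < 0))
    stopf("'counts' must be a non-negative vector with >= 8 bins")
  if (!is.null(irf)) {
    check_number(irf$fwhm, "irf$fwhm", lower = 0)
    check_number(irf$shift, "irf$shift", lower = 0)
  }
  structure(list(bin_time = bin_time, counts = as.double(counts),
                 window = bin_time * length(counts), irf = irf,
                 metadata = metadata),
            class = "decay_histogram")
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf("TCSPC decay: %d bins x %.4g ns (window %.4g ns), %d counts\n",
              length(x$counts), x$bin_time, x$window, round(sum(x$counts))))
  if (!is.null(x$irf))
    cat(sprintf("  Gaussian IRF: fwhm %.3g ns, shift %.3g ns\n",
                x$irf$fwhm, x$irf$shift))
  invisible(x)
}

# bin-centre time axis (ns)
.decay_times <- function(hist) (seq_along(hist$counts) - 0.5) * hist$bin_time

# unit-area exponential decay convolved with a Gaussian IRF (exGaussian),
# evaluated stably in log space
.decay_component <- function(t, tau, sigma, mu) {
  if (is.null(sigma) || sigma <= 0) {
    out <- numeric(length(t))
    sel <- t >= mu
    out[sel] <- exp(-(t[sel] - mu) / tau) / tau
    return(out)
  }
  x <- (sigma / tau - (t - mu) / sigma) / sqrt(2)
  lg <- -log(2 * tau) + sigma^2 / (2 * tau^2) - (t - mu) / tau +
    log(2) + pnorm(x * sqrt(2), lower.tail = FALSE, log.p = TRUE)
  exp(lg)
}

# expected photon density over bins for an amplitude-fraction mixture:
# amplitudes a_i weight pre-exponential factors; photon weights are
# a_i tau_i / sum(a_j tau_j)
.decay_shape <- function(t, lifetimes, amp_fractions, sigma, mu) {
  w <- amp_fractions * lifetimes
  w <- w / sum(w)
  shape <- numeric(length(t))
  for (i in seq_along(lifetimes))
    shape <- shape + w[i] * .decay_component(t, lifetimes[i], sigma, mu)
  shape
}

#' Parameters for simulated TCSPC decays
#'
#' @param lifetimes One or two lifetimes in ns (donor-only, or
#'   free + FRET-shortened).
#' @param amplitude_fractions Pre-exponential amplitude fractions summing
#'   to 1 (the FLIM-FRET binding fraction lives here, not in photon
#'   fractions).
#' @param total_counts Expected total photons in the histogram.
#' @param n_bins Number of histogram bins.
#' @param window Histogram window in ns; must exceed the longest lifetime
#'   (a warning flags windows under 3 lifetimes, where truncation biases
#'   fits).
#' @param irf_fwhm,irf_shift Gaussian IRF width and position, ns.
#' @param background_fraction Fraction of photons from a flat background.
#' @param seed Integer seed.
#' @return An object of class `decay_sim_params`.
#' @export
decay_sim_params <- function(lifetimes, amplitude_fractions = 1,
                             total_counts = 1e5, n_bins = 512L,
                             window = 25, irf_fwhm = 0.35, irf_shift = 2,
                             background_fraction = 0, seed = 1L) {
  if (any(lifetimes <= 0) || !length(lifetimes) %in% 1:2)
    stopf("'lifetimes' must be 1 or 2 positive values (ns)")
  if (length(amplitude_fractions) != length(lifetimes) ||
      any(amplitude_fractions < 0) ||
      abs(sum(amplitude_fractions) - 1) > 1e-9)
    stopf("'amplitude_fractions' must be non-negative and sum to 1")
  check_number(total_counts, "total_counts", lower = 1)
  check_number(n_bins, "n_bins", lower = 8)
  check_number(window, "window", lower = max(lifetimes) + 1e-12)
  check_number(irf_fwhm, "irf_fwhm", lower = 0)
  check_number(irf_shift, "irf_shift", lower = 0)
  check_number(background_fraction, "background_fraction", lower = 0,
               upper = 0.9)
  if (window < 3 * max(lifetimes))
    warnf("window (%g ns) < 3x the longest lifetime; truncation will bias fits",
          window)
  structure(list(lifetimes = lifetimes,
                 amplitude_fractions = amplitude_fractions,
                 total_counts = total_counts, n_bins = as.integer(n_bins),
                 window = window, irf_fwhm = irf_fwhm,
                 irf_shift = irf_shift,
                 background_fraction = background_fraction,
                 seed = as.integer(seed)),
            class = "decay_sim_params")
}

#' Simulate a TCSPC decay histogram
#'
#' Per-bin Poisson counts whose expectation is the amplitude-weighted
#' exponential mixture convolved with a Gaussian IRF, plus a flat
#' background; total expected counts equal `total_counts` exactly.
#'
#' @param params A [decay_sim_params()].
#' @return A [decay_histogram()] carrying the generating truth in its
#'   metadata.
#' @export
simulate_tcspc_decay <- function(params) {
  stopifnot(inherits(params, "decay_sim_params"))
  bin_time <- params$window / params$n_bins
  t <- (seq_len(params$n_bins) - 0.5) * bin_time
  sigma <- if (params$irf_fwhm > 0) params$irf_fwhm / 2.354820045 else 0
  shape <- .decay_shape(t, params$lifetimes, params$amplitude_fractions,
                        sigma, params$irf_shift)
  p <- shape / sum(shape)
  lambda <- params$total_counts *
    ((1 - params$background_fraction) * p +
       params$background_fraction / params$n_bins)
  counts <- with_seed(split_seed(params$seed, 4L),
                      rpois(params$n_bins, lambda))
  decay_histogram(bin_time, counts,
                  irf = list(fwhm = params$irf_fwhm,
                             shift = params$irf_shift),
                  metadata = list(truth = unclass(params)))
}

#' Fit a mono- or bi-exponential model to a TCSPC decay
#'
#' Maximum-likelihood fit under Poisson counting statistics (the default;
#' correct in sparsely populated tail bins) of an exponential mixture
#' convolved with the histogram's Gaussian IRF plus a flat background.
#' Least squares with Poisson weights is available for cross-checks. The
#' fit range starts half an IRF width before the decay peak; earlier bins
#' carry no decay information. For the bi-exponential model the two
#' amplitudes are reported normalised (`a1 + a2 = 1`) with `tau2 < tau1`
#' by relabelling, and the amplitude-derived binding percentage is
#' `100 a2/(a1 + a2)`.
#'
#' Fixing `tau1` to a donor-only estimate (`fix_tau1`) is the standard
#' FLIM-FRET practice: the free four-parameter bi-exponential fit is poorly
#' identifiable at typical photon counts.
#'
#' @param hist A [decay_histogram()].
#' @param model `"mono"` or `"biexp"`.
#' @param fix_tau1 Optional fixed long lifetime (ns).
#' @param objective `"mle"` (Poisson) or `"lsq"`.
#' @return An object of class `decay_fit`: `tau1`, `tau2`, `a1`, `a2`,
#'   `background` (counts/bin), `binding_pct`, amplitude- and
#'   intensity-weighted mean lifetimes, `chi2_reduced`, `se`, convergence
#'   flags, and the data.
#' @export
fit_decay <- function(hist, model = c("biexp", "mono"), fix_tau1 = NULL,
                      objective = c("mle", "lsq")) {
  stopifnot(inherits(hist, "decay_histogram"))
  model <- match.arg(model)
  objective <- match.arg(objective)
  total <- sum(hist$counts)
  if (total < 1e3)
    warnf("only %d photons; lifetime estimates will be poor", round(total))
  t <- .decay_times(hist)
  sigma <- if (!is.null(hist$irf) && hist$irf$fwhm > 0)
    hist$irf$fwhm / 2.354820045 else 0
  mu <- if (!is.null(hist$irf)) hist$irf$shift else 0

  # fit range: from half an IRF width before the (smoothed) peak
  sm <- rolling_mean(hist$counts, 5L)
  t_peak <- t[which.max(sm)]
  sel <- t >= t_peak - 0.5 * max(sigma * 2.354820045, hist$bin_time)
  ts <- t[sel]; cs <- hist$counts[sel]
  nb <- length(ts)

  # the amplitude is profiled out: with a unit-normalised shape the
  # Poisson MLE of the total is exactly the observed count in range
  n_range <- sum(cs)
  model_counts <- function(par) {
    lifes <- if (model == "mono") par[["tau1"]] else
      c(par[["tau1"]], par[["tau2"]])
    amps <- if (model == "mono") 1 else c(1 - par[["f2"]], par[["f2"]])
    shape <- .decay_shape(ts, lifes, pmax(amps, 1e-12), sigma, mu)
    p <- shape / sum(shape)
    n_range * ((1 - par[["bg"]]) * p + par[["bg"]] / nb)
  }
  nll <- function(v) {
    par <- as.list(v)
    for (nm in names(fixed)) par[[nm]] <- fixed[[nm]]
    m <- model_counts(par)
    m <- pmax(m, 1e-12)
    if (objective == "mle") sum(m - cs * log(m))
    else sum((cs - m)^2 / pmax(m, 1))
  }

  tau_guess <- max(sum(cs * (ts - mu)) / max(sum(cs), 1), hist$bin_time)
  start <- c(tau1 = tau_guess,
             if (model == "biexp") c(tau2 = tau_guess / 3, f2 = 0.3),
             bg = 0.01)
  lower <- c(tau1 = 0.05, if (model == "biexp") c(tau2 = 0.02, f2 = 0),
             bg = 0)
  upper <- c(tau1 = 30, if (model == "biexp") c(tau2 = 30, f2 = 1),
             bg = 0.8)
  fixed <- list()
  if (!is.null(fix_tau1)) {
    check_number(fix_tau1, "fix_tau1", lower = 0.01)
    fixed$tau1 <- fix_tau1
    keep <- setdiff(names(start), "tau1")
    start <- start[keep]; lower <- lower[keep]; upper <- upper[keep]
  }

  opt <- nlminb(start, nll, lower = lower, upper = upper,
                control = list(iter.max = 500, eval.max = 1000,
                               rel.tol = 1e-12))
  # verification restart: nlminb sometimes reports "false/singular
  # convergence" at a perfectly good optimum; accept the solution when a
  # fresh start from it cannot improve the objective meaningfully
  opt2 <- nlminb(opt$par, nll, lower = lower, upper = upper,
                 control = list(iter.max = 200, rel.tol = 1e-10))
  if (opt2$objective < opt$objective) opt <- opt2
  converged <- opt$convergence == 0 ||
    grepl("relative convergence|X-convergence|singular convergence",
          opt$message %||% "") ||
    abs(opt2$objective - opt$objective) <=
      1e-8 * max(abs(opt$objective), 1)
  par <- as.list(opt$par)
  for (nm in names(fixed)) par[[nm]] <- fixed[[nm]]

  tau1 <- par$tau1; tau2 <- if (model == "biexp") par$tau2 else NA_real_
  a2 <- if (model == "biexp") par$f2 else 0
  if (model == "biexp" && is.finite(tau2) && tau2 > tau1) {
    tmp <- tau1; tau1 <- tau2; tau2 <- tmp
    a2 <- 1 - a2
  }
  a1 <- 1 - a2

  m_hat <- model_counts(c(list(tau1 = tau1, tau2 = tau2, f2 = a2),
                          par["bg"]))
  p_free <- length(start)
  chi2 <- sum((cs - m_hat)^2 / pmax(m_hat, 1)) / max(nb - p_free, 1)

  se <- .decay_fit_se(nll, opt$par, lower, upper)

  taus <- c(tau1, tau2)[is.finite(c(tau1, tau2))]
  amps <- if (model == "biexp") c(a1, a2) else 1
  tau_amp <- sum(amps * taus)
  tau_int <- sum(amps * taus^2) / sum(amps * taus)

  structure(list(tau1 = tau1, tau2 = tau2, a1 = a1, a2 = a2,
                 background = par$bg * n_range / nb,
                 background_fraction = par$bg,
                 binding_pct = 100 * a2,
                 tau_mean_amplitude = tau_amp,
                 tau_mean_intensity = tau_int,
                 chi2_reduced = chi2, se = se,
                 converged = converged,
                 message = opt$message, model = model,
                 objective = objective, fix_tau1 = fix_tau1,
                 n_counts = total, hist = hist,
                 fit_range_ns = range(ts), fitted = m_hat,
                 times = ts, counts = cs),
            class = "decay_fit")
}

# observed-information standard errors via a finite-difference Hessian
.decay_fit_se <- function(nll, par, lower, upper) {
  n <- length(par)
  H <- matrix(NA_real_, n, n, dimnames = list(names(par), names(par)))
  h <- pmax(abs(par), 1e-3) * 1e-4
  f0 <- nll(par)
  ok <- TRUE
  for (i in seq_len(n)) for (j in i:n) {
    pi <- par; pj <- par; pij <- par
    pi[i] <- pi[i] + h[i]; pj[j] <- pj[j] + h[j]
    pij[i] <- pij[i] + h[i]; pij[j] <- pij[j] + h[j]
    H[i, j] <- H[j, i] <- (nll(pij) - nll(pi) - nll(pj) + f0) / (h[i] * h[j])
  }
  cov <- tryCatch(solve(H), error = function(e) { ok <<- FALSE; NULL })
  if (!ok || any(!is.finite(diag(cov))))
    return(setNames(rep(NA_real_, n), names(par)))
  setNames(sqrt(pmax(diag(cov), 0)), names(par))
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("TCSPC %s fit (%s%s): %s\n", x$model, x$objective,
              if (!is.null(x$fix_tau1)) sprintf(", tau1 fixed = %.3g ns",
                                                x$fix_tau1) else "",
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  tau1 = %.4g ns", x$tau1))
  if (x$model == "biexp")
    cat(sprintf(", tau2 = %.4g ns, a2 = %.3f (binding %.1f%%)",
                x$tau2, x$a2, x$binding_pct))
  cat(sprintf("\n  mean lifetime: %.4g ns (amplitude-weighted), %.4g ns (intensity-weighted)\n",
              x$tau_mean_amplitude, x$tau_mean_intensity))
  cat(sprintf("  reduced chi2 = %.4g, %d photons\n", x$chi2_reduced,
              round(x$n_counts)))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...)
  c(tau1 = object$tau1, tau2 = object$tau2, a1 = object$a1, a2 = object$a2,
    background_fraction = object$background_fraction)

#' @export
predict.decay_fit <- function(object, ...) object$fitted

#' @export
residuals.decay_fit <- function(object, ...)
  (object$counts - object$fitted) / sqrt(pmax(object$fitted, 1))

#' @export
plot.decay_fit <- function(x, ...) {
  plot(x$times, x$counts + 0.5, log = "y", pch = 16, cex = 0.4,
       xlab = "time (ns)", ylab = "counts", ...)
  lines(x$times, x$fitted + 0.5, col = "red3", lwd = 1.5)
  invisible(x)
}

#' Amplitude-derived FLIM-FRET binding percentage
#'
#' The fraction of donor molecules undergoing FRET, from the
#' pre-exponential amplitudes of the bi-exponential fit:
#' `100 * a2 / (a1 + a2)` with component 2 the short-lifetime (bound)
#' species. A mono-exponential fit reports 0% with a note.
#'
#' @param fit A [fit_decay()] result.
#' @return Percentage in `[0, 100]`.
#' @export
binding_percentage <- function(fit) {
  stopifnot(inherits(fit, "decay_fit"))
  if (fit$model == "mono") {
    message("mono-exponential fit: binding percentage is 0 by definition")
    return(0)
  }
  100 * fit$a2 / (fit$a1 + fit$a2)
}

#' Choose between mono- and bi-exponential decay models
#'
#' Fits both models and keeps the bi-exponential one only when it earns it:
#' an F-test on the chi-square improvement significant at `alpha` AND a
#' fitted short-lifetime amplitude of at least `min_a2`. Tiny amplitude
#' components are indistinguishable from noise however significant the
#' variance ratio looks.
#'
#' @param hist A [decay_histogram()].
#' @param fix_tau1 Optional fixed donor lifetime for the biexp candidate.
#' @param alpha F-test level.
#' @param min_a2 Amplitude floor for accepting the second component.
#' @param objective Passed to [fit_decay()].
#' @return List with `model` (`"mono"`/`"biexp"`), the chosen `fit`, both
#'   candidate fits, and the F-test `p_value`.
#' @export
select_model <- function(hist, fix_tau1 = NULL, alpha = 0.01,
                         min_a2 = 0.02, objective = "mle") {
  mono <- fit_decay(hist, "mono", objective = objective)
  bi <- fit_decay(hist, "biexp", fix_tau1 = fix_tau1, objective = objective)
  if (!mono$converged && !bi$converged)
    stopf("neither decay model converged")
  nb <- length(mono$counts)
  rss_m <- sum((mono$counts - mono$fitted)^2 / pmax(mono$fitted, 1))
  rss_b <- sum((bi$counts - bi$fitted)^2 / pmax(bi$fitted, 1))
  extra <- 2L - as.integer(!is.null(fix_tau1))
  df2 <- nb - (3L + extra)
  fstat <- ((rss_m - rss_b) / extra) / (rss_b / df2)
  p <- if (is.finite(fstat) && fstat > 0) pf(fstat, extra, df2,
                                            lower.tail = FALSE) else 1
  use_bi <- bi$converged && p < alpha && bi$a2 >= min_a2
  list(model = if (use_bi) "biexp" else "mono",
       fit = if (use_bi) bi else mono,
       mono = mono, biexp = bi, p_value = p, f_statistic = fstat)
}

#' Fit decays for a set of cells or nuclei
#'
#' One decay fit per unit (cell, nucleus, or pixel bin), assembled into a
#' flat table; units whose fit fails to converge are flagged in the
#' `converged` column rather than dropped.
#'
#' @param decays Named list of [decay_histogram()] objects.
#' @param model `"mono"`, `"biexp"` or `"auto"` ([select_model()]).
#' @param fix_tau1,objective Passed to the fitter.
#' @return A data.frame keyed by `unit` with lifetimes, amplitudes,
#'   `binding_pct`, `chi2` and convergence flags; the fits themselves are
#'   attached as the `"fits"` attribute.
#' @export
lifetime_map <- function(decays, model = c("auto", "biexp", "mono"),
                         fix_tau1 = NULL, objective = "mle") {
  model <- match.arg(model)
  if (!is.list(decays) || length(decays) == 0L)
    stopf("'decays' must be a non-empty list of decay histograms")
  ids <- names(decays)
  if (is.null(ids)) ids <- sprintf("unit_%03d", seq_along(decays))
  fits <- lapply(decays, function(h) {
    if (model == "auto") select_model(h, fix_tau1 = fix_tau1,
                                      objective = objective)$fit
    else fit_decay(h, model, fix_tau1 = fix_tau1, objective = objective)
  })
  tab <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(unit = ids[i], model = f$model, tau1 = f$tau1, tau2 = f$tau2,
               a1 = f$a1, a2 = f$a2, binding_pct = f$binding_pct,
               chi2 = f$chi2_reduced, converged = f$converged)
  }))
  attr(tab, "fits") <- setNames(fits, ids)
  tab
}

#' Read / write TCSPC decays as delimited text
#'
#' Format: a JSON header line prefixed with `#` (bin time, IRF description,
#' unit id) followed by a `time_ns,counts` CSV body.
#'
#' @param hist A [decay_histogram()].
#' @param path File path.
#' @return `read_decay()` returns a `decay_histogram`; `write_decay()`
#'   returns `path` invisibly.
#' @export
write_decay <- function(hist, path) {
  stopifnot(inherits(hist, "decay_histogram"))
  hdr <- jsonlite::toJSON(list(bin_time_ns = hist$bin_time, irf = hist$irf,
                               metadata = hist$metadata["unit"]),
                          auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# ", hdr), con)
  write.table(data.frame(time_ns = .decay_times(hist), counts = hist$counts),
              con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_decay
#' @export
read_decay <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "# ")) stopf("'%s' has no decay header", path)
  meta <- jsonlite::fromJSON(sub("^# ", "", hdr))
  d <- read.table(path, sep = ",", header = TRUE, skip = 1L)
  decay_histogram(meta$bin_time_ns, d$counts, irf = meta$irf,
                  metadata = list(source = path))
}
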