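#' Construct a correlation curve
#'
#' Container for an auto- or cross-correlation function on a lag grid, with
#' optional per-lag standard deviations used as fit weights.
#'
#' @param lags Lag times in seconds, strictly increasing and positive.
#' @param G Correlation values (dimensionless).
#' @param sigma Optional per-lag standard deviation of `G` (same length).
#' @param kind One of `"ACF_g"`, `"ACF_r"`, `"CCF"`.
#' @param mean_intensity Named numeric: mean intensity in counts/s per
#'   channel (e.g. `c(g = 12000)`).
#' @param metadata Free-form provenance list.
#' @return An object of class `correlation_curve`.
#' @export
correlation_curve <- function(lags, G, sigma = NULL,
                              kind = c("ACF_g", "ACF_r", "CCF"),
                              mean_intensity = numeric(), metadata = list()) {
  kind <- match.arg(kind)
  if (length(lags) != length(G)) stopf("'lags' and 'G' lengths differ")
  if (any(lags <= 0)) stopf("lags must be positive")
  if (any(diff(lags) <= 0)) stopf("lags must be strictly increasing")
  if (!is.null(sigma)) {
    if (length(sigma) != length(G)) stopf("'sigma' length mismatch")
    if (any(sigma < 0)) stopf("'sigma' must be non-negative")
  }
  if (any(mean_intensity < 0)) stopf("mean intensities must be non-negative")
  structure(list(lags = as.double(lags), G = as.double(G),
                 sigma = if (is.null(sigma)) NULL else as.double(sigma),
                 kind = kind, mean_intensity = mean_intensity,
                 metadata = metadata),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("%s: %d lags, %.3g s .. %.3g s, G(first) = %.4g\n",
              x$kind, length(x$lags), min(x$lags), max(x$lags), x$G[1]))
  if (!is.null(x$sigma)) cat("  per-lag sigma attached\n")
  invisible(x)
}

#' @export
as.data.frame.correlation_curve <- function(x, ...) {
  d <- data.frame(lag_s = x$lags, G = x$G)
  if (!is.null(x$sigma)) d$sigma <- x$sigma
  d
}

#' @export
plot.correlation_curve <- function(x, ..., log = "x") {
  plot(x$lags, x$G, log = log, xlab = expression(tau ~ "(s)"),
       ylab = expression(G(tau)), pch = 16, cex = 0.6, ...)
  invisible(x)
}

#' Remove slow intensity trends (photobleaching) from a trace
#'
#' Applies the standard square-root ratio-plus-offset bleaching correction,
#' anchored at the global mean:
#' \deqn{I_{corr}(t) = I(t)\sqrt{\langle I\rangle / f(t)} +
#'   \langle I\rangle - \sqrt{\langle I\rangle f(t)}}
#' where `f(t)` is a slow smoothed trend of the trace. The square-root
#' scaling restores the shot-noise variance of a stationary trace and the
#' offset pins the expectation to the global mean at every time, so the
#' trend is removed while correlation amplitudes keep their concentration
#' meaning. Both channels of a dual-color trace are corrected
#' independently.
#'
#' @param trace An [intensity_trace()].
#' @param method Trend estimator: centred moving average (default) or a
#'   zero-phase exponential smoother of equivalent timescale.
#' @param window Trend timescale in seconds. Must be at least `100 * dt` and
#'   shorter than the trace; fluctuations slower than this are treated as
#'   drift, faster ones are preserved.
#' @return A corrected `intensity_trace`.
#' @export
detrend_trace <- function(trace, method = c("moving-average", "exponential"),
                          window = 1) {
  stopifnot(inherits(trace, "intensity_trace"))
  method <- match.arg(method)
  check_number(window, "window", lower = 100 * trace$dt)
  if (window >= trace_duration(trace))
    stopf("'window' (%g s) must be shorter than the trace (%g s)",
          window, trace_duration(trace))
  k <- max(3L, as.integer(round(window / trace$dt)))
  fix_channel <- function(x) {
    m <- mean(x)
    if (m <= 0) return(x)
    f <- switch(method,
                "moving-average" = rolling_linear(x, k),
                "exponential" = ema_smooth(x, k))
    f <- pmax(f, 1e-12 * m)
    r <- sqrt(m / f)
    x * r + m - sqrt(m * f)
  }
  out <- trace
  out$counts_g <- fix_channel(trace$counts_g)
  if (!is.null(trace$counts_r)) out$counts_r <- fix_channel(trace$counts_r)
  out$metadata$detrend <- list(method = method, window_s = window)
  out
}

# centred moving average with shrinking windows at the edges, O(n)
rolling_mean <- function(x, k) {
  n <- length(x)
  h <- k %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# centred local-linear smoother (first-order Savitzky-Golay), O(n) through
# cumulative sums; unlike the plain boxcar it has no lag bias at the
# shrinking one-sided edge windows, which matters for monotone bleaching
# trends
rolling_linear <- function(x, k) {
  n <- length(x)
  h <- k %/% 2L
  idx <- as.numeric(seq_len(n))
  c0 <- cumsum(c(0, rep(1, n)))
  c1 <- cumsum(c(0, idx))
  c2 <- cumsum(c(0, idx^2))
  cy <- cumsum(c(0, x))
  cxy <- cumsum(c(0, idx * x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  S0 <- c0[hi + 1L] - c0[lo]
  S1 <- c1[hi + 1L] - c1[lo]
  S2 <- c2[hi + 1L] - c2[lo]
  Sy <- cy[hi + 1L] - cy[lo]
  Sxy <- cxy[hi + 1L] - cxy[lo]
  det <- S0 * S2 - S1^2
  b <- (S0 * Sxy - S1 * Sy) / det
  a <- (Sy - b * S1) / S0
  a + b * idx
}

# zero-phase exponential smoother: forward + backward EMA averaged
ema_smooth <- function(x, k) {
  a <- 2 / (k + 1)
  f <- stats::filter(a * x, 1 - a, method = "recursive", init = x[1])
  b <- rev(stats::filter(a * rev(x), 1 - a, method = "recursive",
                         init = x[length(x)]))
  as.numeric(f + b) / 2
}

#' Multi-tau correlation of intensity traces
#'
#' Computes the symmetrically normalised correlation estimator
#' \deqn{G(\tau) = \langle \delta I_a(t)\,\delta I_b(t+\tau)\rangle /
#'   (\langle I_a\rangle \langle I_b\rangle)}
#' on a quasi-logarithmic multi-tau lag grid: `points_per_octave` linear lags
#' at the base sampling interval, then the trace is rebinned by a factor two
#' and the upper half of the lag set is repeated at each coarser level, as in
#' hardware correlators. Symmetric normalisation uses direct and delayed
#' monitor sums over the exact overlap window of every lag, which suppresses
#' the bias from residual slow trends.
#'
#' With `a == b` the result is an autocorrelation (ACF); with different
#' channels it is the cross-correlation (CCF) of a dual-color trace.
#'
#' @param trace An [intensity_trace()].
#' @param a,b Channel selectors, `"g"` or `"r"`.
#' @param points_per_octave Lags per octave of the multi-tau grid.
#' @param min_level_bins Stop rebinning when fewer bins than this remain.
#' @return A [correlation_curve()]; the first lag equals `dt`.
#' @export
multitau_correlate <- function(trace, a = "g", b = "g",
                               points_per_octave = 16L,
                               min_level_bins = 64L) {
  stopifnot(inherits(trace, "intensity_trace"))
  a <- match.arg(a, c("g", "r")); b <- match.arg(b, c("g", "r"))
  ppo <- as.integer(points_per_octave)
  if (ppo < 4L || ppo %% 2L != 0L) stopf("'points_per_octave' must be even, >= 4")
  pick <- function(ch) {
    v <- if (ch == "g") trace$counts_g else trace$counts_r
    if (is.null(v)) stopf("trace has no '%s' channel", ch)
    v
  }
  x <- pick(a); y <- pick(b)
  if (length(x) < 1024L) stopf("trace too short for multi-tau (need >= 1024 bins)")
  if (mean(x) <= 0 || mean(y) <= 0) stopf("zero-intensity channel")

  lags <- numeric(0); G <- numeric(0)
  level <- 0L
  repeat {
    n <- length(x)
    ks <- if (level == 0L) seq_len(ppo) else (ppo %/% 2L + 1L):ppo
    bin_dt <- trace$dt * 2^level
    for (k in ks) {
      if (k >= n) break
      G <- c(G, .corr_at_lag(x, y, k))
      lags <- c(lags, k * bin_dt)
    }
    # rebin by 2 (averaging preserves intensity units)
    n2 <- n %/% 2L
    if (n2 < max(min_level_bins, 2L * ppo)) break
    x <- (x[seq(1L, 2L * n2, 2L)] + x[seq(2L, 2L * n2, 2L)]) / 2
    y <- (y[seq(1L, 2L * n2, 2L)] + y[seq(2L, 2L * n2, 2L)]) / 2
    level <- level + 1L
  }
  mi <- c(mean(trace$counts_g) / trace$dt,
          if (!is.null(trace$counts_r)) mean(trace$counts_r) / trace$dt)
  names(mi) <- c("g", if (!is.null(trace$counts_r)) "r")
  kind <- if (a == b) (if (a == "g") "ACF_g" else "ACF_r") else "CCF"
  correlation_curve(lags, G, kind = kind, mean_intensity = mi,
                    metadata = list(points_per_octave = ppo,
                                    channels = c(a = a, b = b),
                                    n_bins = length(trace$counts_g),
                                    dt_s = trace$dt))
}

# symmetric-normalised estimator at a single integer lag
.corr_at_lag <- function(x, y, k) {
  n <- length(x)
  np <- n - k
  xs <- x[seq_len(np)]
  ys <- y[(k + 1L):n]
  s <- sum(xs * ys)
  ma <- sum(xs); mb <- sum(ys)
  if (ma <= 0 || mb <= 0) return(NA_real_)
  np * s / (ma * mb) - 1
}

#' Attach per-lag noise estimates to a correlation curve
#'
#' Splits the trace into `n_segments` equal blocks, correlates each with the
#' same multi-tau schedule, and attaches
#' `sigma(tau) = sd(G_seg(tau)) / sqrt(n_segments)` — the standard error of
#' the full-trace estimator — to the full-trace curve. Lags that do not fit
#' inside a segment are dropped with a warning.
#'
#' @inheritParams multitau_correlate
#' @param n_segments Number of blocks (>= 3).
#' @return A [correlation_curve()] with `sigma` attached.
#' @export
estimate_curve_sigma <- function(trace, a = "g", b = "g", n_segments = 10L,
                                 points_per_octave = 16L) {
  stopifnot(inherits(trace, "intensity_trace"))
  n_segments <- as.integer(n_segments)
  if (n_segments < 3L) stopf("'n_segments' must be >= 3")
  full <- multitau_correlate(trace, a, b, points_per_octave)
  n <- length(trace$counts_g)
  seg_len <- n %/% n_segments
  if (seg_len < 1024L) stopf("segments too short; reduce 'n_segments'")
  seg_G <- lapply(seq_len(n_segments), function(i) {
    idx <- ((i - 1L) * seg_len + 1L):(i * seg_len)
    sub <- intensity_trace(trace$dt, trace$counts_g[idx],
                           counts_r = if (is.null(trace$counts_r)) NULL else
                             trace$counts_r[idx])
    multitau_correlate(sub, a, b, points_per_octave)
  })
  seg_lags <- seg_G[[1]]$lags
  keep <- full$lags %in% seg_lags
  if (!all(keep))
    warnf("dropping %d lags longer than the segment coverage", sum(!keep))
  Gm <- vapply(seg_G, function(cv) cv$G[match(full$lags[keep], cv$lags)],
               numeric(sum(keep)))
  sig <- apply(as.matrix(Gm), 1L, sd) / sqrt(n_segments)
  correlation_curve(full$lags[keep], full$G[keep], sigma = sig,
                    kind = full$kind, mean_intensity = full$mean_intensity,
                    metadata = c(full$metadata, list(n_segments = n_segments)))
}

#' Read / write correlation curves as delimited text
#'
#' Format: JSON header lines prefixed with `#` (kind, mean intensities,
#' provenance) followed by a `lag_s,G[,sigma]` CSV body.
#'
#' @param curve A [correlation_curve()].
#' @param path File path.
#' @return `read_curve()` returns a `correlation_curve`; `write_curve()`
#'   returns `path` invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "correlation_curve"))
  hdr <- jsonlite::toJSON(list(kind = curve$kind,
                               mean_intensity = as.list(curve$mean_intensity),
                               metadata = curve$metadata),
                          auto_unbox = TRUE, digits = NA)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# ", hdr), con)
  d <- as.data.frame(curve)
  write.table(d, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "# ")) stopf("'%s' has no curve header", path)
  meta <- jsonlite::fromJSON(sub("^# ", "", hdr))
  d <- read.table(path, sep = ",", header = TRUE, skip = 1L)
  correlation_curve(d$lag_s, d$G, sigma = d$sigma, kind = meta$kind,
                    mean_intensity = unlist(meta$mean_intensity),
                    metadata = meta$metadata)
}
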