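#' Construct an intensity trace
#'
#' Container for a one- or two-channel photon-count time series binned at a
#' fixed sampling interval — the raw measurement unit of the correlation
#' pipeline.
#'
#' @param dt Sampling interval in seconds (bin width).
#' @param counts_g Numeric vector of counts per bin, green channel.
#' @param counts_r Optional counts per bin, red channel (same length).
#' @param metadata Free-form provenance list.
#' @return An object of class `intensity_trace` with elements `dt`,
#'   `counts_g`, `counts_r` and `metadata`.
#' @export
intensity_trace <- function(dt, counts_g, counts_r = NULL, metadata = list()) {
  check_number(dt, "dt", lower = .Machine$double.eps)
  if (!is.numeric(counts_g) || length(counts_g) < 1L)
    stopf("'counts_g' must be a non-empty numeric vector")
  if (any(counts_g < 0, na.rm = TRUE)) stopf("counts must be non-negative")
  if (!is.null(counts_r)) {
    if (length(counts_r) != length(counts_g))
      stopf("channels must have equal length (%d vs %d)",
            length(counts_g), length(counts_r))
    if (any(counts_r < 0, na.rm = TRUE)) stopf("counts must be non-negative")
  }
  structure(list(dt = dt, counts_g = as.double(counts_g),
                 counts_r = if (is.null(counts_r)) NULL else as.double(counts_r),
                 metadata = metadata),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  nch <- if (is.null(x$counts_r)) 1L else 2L
  cat(sprintf("Intensity trace: %d bins, dt = %g s (%.3g s), %d channel%s\n",
              length(x$counts_g), x$dt, length(x$counts_g) * x$dt, nch,
              if (nch > 1) "s" else ""))
  cat(sprintf("  mean rate green: %.4g counts/s\n", mean(x$counts_g) / x$dt))
  if (nch == 2L)
    cat(sprintf("  mean rate red:   %.4g counts/s\n", mean(x$counts_r) / x$dt))
  invisible(x)
}

#' @export
plot.intensity_trace <- function(x, downsample = 1000L, ...) {
  n <- length(x$counts_g)
  k <- max(1L, floor(n / downsample))
  idx <- seq(1L, n - k + 1L, by = k)
  bin <- function(v) vapply(idx, function(i) mean(v[i:(i + k - 1L)]), 0) / x$dt
  t_s <- (idx + k / 2) * x$dt
  g <- bin(x$counts_g)
  ylim <- range(g, if (!is.null(x$counts_r)) bin(x$counts_r))
  plot(t_s, g, type = "l", col = "darkgreen", xlab = "time (s)",
       ylab = "intensity (counts/s)", ylim = ylim, ...)
  if (!is.null(x$counts_r)) lines(t_s, bin(x$counts_r), col = "red3")
  invisible(x)
}

#' Trace duration in seconds
#' @param trace An [intensity_trace()].
#' @return Duration (s).
#' @export
trace_duration <- function(trace) length(trace$counts_g) * trace$dt

#' Read / write intensity traces as delimited text
#'
#' The on-disk format is a comment header `# dt_s=<float> channels=<1|2>`
#' followed by one (`counts_g`) or two (`counts_g,counts_r`) comma-separated
#' count columns.
#'
#' @param trace An [intensity_trace()].
#' @param path File path.
#' @return `read_trace()` returns an `intensity_trace`; `write_trace()`
#'   returns `path` invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "intensity_trace"))
  nch <- if (is.null(trace$counts_r)) 1L else 2L
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# dt_s=%.17g channels=%d", trace$dt, nch), con)
  writeLines(if (nch == 1L) "counts_g" else "counts_g,counts_r", con)
  m <- if (nch == 1L) cbind(trace$counts_g) else
    cbind(trace$counts_g, trace$counts_r)
  write.table(m, con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec("# dt_s=([0-9.eE+-]+) channels=([12])", hdr))[[1]]
  if (length(m) != 3L) stopf("'%s' has no valid trace header", path)
  dt <- as.numeric(m[2]); nch <- as.integer(m[3])
  d <- read.table(path, sep = ",", header = TRUE, skip = 1L)
  intensity_trace(dt, d[[1]],
                  counts_r = if (nch == 2L) d[[2]] else NULL,
                  metadata = list(source = path))
}
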