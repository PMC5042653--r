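# shared fixtures and independent oracles, built in code at test time

# direct-summation correlation estimator with symmetric normalisation —
# the brute-force oracle against which the multi-tau correlator is checked
brute_force_corr <- function(x, y, k) {
  n <- length(x)
  np <- n - k
  s <- 0
  ma <- 0
  mb <- 0
  for (i in seq_len(np)) {
    s <- s + x[i] * y[i + k]
    ma <- ma + x[i]
    mb <- mb + y[i + k]
  }
  np * s / (ma * mb) - 1
}

# stationary Poisson shot-noise trace
poisson_trace <- function(n, rate = 5e4, dt = 1e-5, seed = 1, two = FALSE) {
  set.seed(seed)
  intensity_trace(dt, rpois(n, rate * dt),
                  counts_r = if (two) rpois(n, rate * dt) else NULL)
}

# mean Gaussian-profile detection efficiency over the periodic box,
# by 1D numerical quadrature (the profile separates per axis)
mean_detection_box <- function(w0, z0, box) {
  ax <- function(s) integrate(function(u) exp(-2 * u^2 / s^2),
                              -box / 2, box / 2)$value / box
  ax(w0)^2 * ax(z0)
}

default_calib <- function() calibrate_focus(2.5e-5, known_D = 400)

# canonical two-component transcription-factor-like parameter set
tf_params <- function(N = 6, F2 = 0.27, tauD1 = 3.03e-3, tauD2 = 0.1,
                      alpha1 = 1, alpha2 = 0.7, ...)
  fcs_model_params(N = N, F2 = F2, tauD1 = tauD1, tauD2 = tauD2,
                   alpha1 = alpha1, alpha2 = alpha2, ...)

# bound-fraction fit protocol used for ensembles (see methods vignette)
tf_fit <- function(curve, fixed = list(), ...)
  fit_acf(curve, model = "two",
          fixed = c(list(alpha1 = 1, G_inf = 0), fixed),
          upper = list(alpha2 = 1), ...)
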