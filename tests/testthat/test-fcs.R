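test_that("the correlation model obeys its closed-form limits", {
  # two-component model with F2 = 0 reduces to the one-component model
  p2 <- fcs_model_params(N = 4, F2 = 0, tauD1 = 1e-3, tauD2 = 1,
                         alpha1 = 0.8)
  p1 <- fcs_model_params(N = 4, F2 = 0, tauD1 = 1e-3, alpha1 = 0.8)
  lags <- make_lag_grid(1e-6, 10)
  expect_identical(eval_acf_model(p2, lags), eval_acf_model(p1, lags))

  # amplitude limit: G(tau -> 0) = G_inf + 1/N
  p <- tf_params(N = 7, G_inf = 0.002)
  expect_equal(eval_acf_model(p, 1e-12), 0.002 + 1 / 7, tolerance = 1e-6)

  # closed form at tau = tauD, alpha = 1
  kappa <- 5
  pc <- fcs_model_params(N = 3, F2 = 0, tauD1 = 2e-3, alpha1 = 1,
                         kappa = kappa)
  expected <- 1 / (3 * 2) / sqrt(1 + 1 / kappa^2)
  expect_equal(eval_acf_model(pc, 2e-3), expected, tolerance = 1e-12)

  # monotone non-increasing for alpha <= 1
  g <- eval_acf_model(tf_params(alpha1 = 0.9, alpha2 = 0.6), lags)
  expect_true(all(diff(g) <= 1e-15))
})

test_that("noiseless two-component curves are recovered to 1e-6", {
  p <- tf_params(N = 6, F2 = 0.27, tauD1 = 3.03e-3, tauD2 = 0.1,
                 alpha1 = 0.9, alpha2 = 0.7, G_inf = 0.001)
  cv <- simulate_model_acf(p, make_lag_grid(), noise_sd = 0)
  f <- fit_acf(cv, model = "two")
  truth <- c(N = 6, F2 = 0.27, tauD1 = 3.03e-3, tauD2 = 0.1,
             alpha1 = 0.9, alpha2 = 0.7, G_inf = 0.001)
  est <- coef(f)[names(truth)]
  expect_lt(max(abs(est / truth - 1)), 1e-6)
  expect_true(f$converged)
  expect_identical(f$n_components_effective, 2L)
})

test_that("one-component data collapse the two-component fit", {
  # free-fluorophore-like data (single normally diffusing species) fitted
  # with the two-component bound-fraction protocol
  p <- fcs_model_params(N = 2, F2 = 0, tauD1 = 5e-4, alpha1 = 1)
  lags <- make_lag_grid(2e-6, 1)
  sig <- fcs_noise_profile(p, lags, rel = 0.02)
  collapsed <- vapply(1:10, function(i) {
    f <- tf_fit(simulate_model_acf(p, lags, sig, seed = i))
    f$n_components_effective == 1L
  }, TRUE)
  expect_gt(mean(collapsed), 0.7)
})

test_that("component relabelling makes fits invariant to swapped inits", {
  p <- tf_params()
  cv <- simulate_model_acf(p, make_lag_grid(), noise_sd = 0)
  init_fwd <- list(N = 5, F2 = 0.3, tauD1 = 2e-3, tauD2 = 0.2,
                   alpha1 = 1, alpha2 = 0.8)
  init_swp <- list(N = 5, F2 = 0.7, tauD1 = 0.2, tauD2 = 2e-3,
                   alpha1 = 0.8, alpha2 = 1)
  f1 <- fit_acf(cv, init = init_fwd)
  f2 <- fit_acf(cv, init = init_swp)
  expect_lt(abs(f1$params$F2 - f2$params$F2), 1e-5)
  expect_lt(abs(f1$params$tauD1 / f2$params$tauD1 - 1), 1e-5)
  expect_lt(f1$params$tauD1, f1$params$tauD2)
})

test_that("F1 + F2 is exactly 1 after every fit", {
  p <- tf_params()
  lags <- make_lag_grid()
  sig <- fcs_noise_profile(p, lags)
  for (i in 1:5) {
    f <- fit_acf(simulate_model_acf(p, lags, sig, seed = i))
    expect_identical(f$params$F1 + f$params$F2, 1)
  }
})

test_that("doubling the concentration halves the fitted amplitude", {
  lags <- make_lag_grid()
  amps <- vapply(c(5, 10), function(N) {
    p <- tf_params(N = N)
    sig <- fcs_noise_profile(p, lags)
    mean(vapply(1:8, function(i)
      1 / tf_fit(simulate_model_acf(p, lags, sig, seed = i))$params$N, 0))
  }, 0)
  expect_equal(amps[1] / amps[2], 2, tolerance = 0.05)
})

test_that("curves without positive amplitude are flagged, not thrown", {
  lags <- make_lag_grid(1e-5, 1, 6)
  set.seed(40)
  flat <- correlation_curve(lags, rnorm(length(lags), 0, 1e-4))
  f <- fit_acf(flat)
  expect_false(is.null(f$failure))
  expect_false(f$converged)
  expect_output(print(f), "FAILED")
})

test_that("global fitting recovers the shared fast diffusion time", {
  lags <- make_lag_grid()
  set.seed(61)
  f2s <- runif(8, 0.15, 0.35)
  cvs <- lapply(seq_along(f2s), function(i) {
    p <- tf_params(F2 = f2s[i])
    simulate_model_acf(p, lags, fcs_noise_profile(p, lags), seed = 500 + i)
  })
  gf <- fit_acf_global(cvs, fixed = list(alpha1 = 1, G_inf = 0),
                       upper = list(alpha2 = 1))
  expect_equal(gf$tauD1, 3.03e-3, tolerance = 0.1)

  # profile optimality: no common pinned tauD1 beats the optimum
  obj_at <- function(tau1) sum(vapply(cvs, function(cv)
    tf_fit(cv, fixed = list(tauD1 = tau1))$ssr_weighted, 0))
  for (tau1 in gf$tauD1 * c(0.7, 0.9, 1.15, 1.4))
    expect_lte(gf$objective, obj_at(tau1) + 1e-6)

  # a single curve degenerates to its individual fit
  g1 <- fit_acf_global(cvs[1], fixed = list(alpha1 = 1, G_inf = 0),
                       upper = list(alpha2 = 1))
  expect_equal(g1$tauD1, g1$tauD1_individual[1], tolerance = 1e-9)
})

test_that("ensemble protocol pools alpha2 and tightens F2", {
  lags <- make_lag_grid()
  p <- tf_params()
  sig <- fcs_noise_profile(p, lags)
  cvs <- lapply(1:12, function(i) simulate_model_acf(p, lags, sig,
                                                     seed = 700 + i))
  ens <- fit_acf_ensemble(cvs)
  expect_equal(ens$alpha2_pooled, 0.7, tolerance = 0.15)
  expect_equal(mean(ens$table$F2), 0.27, tolerance = 0.1)
  expect_true(all(ens$table$converged))
})

test_that("focal calibration follows its closed form and scaling law", {
  cal <- calibrate_focus(25e-6, known_D = 400, kappa = 5)
  expect_equal(cal$w0, 0.2, tolerance = 1e-12)
  expect_equal(cal$z0, 1.0, tolerance = 1e-12)
  expect_equal(cal$V_eff, pi^1.5 * 5 * 0.2^3, tolerance = 1e-12)

  cal2 <- calibrate_focus(50e-6, known_D = 400, kappa = 5)
  expect_equal(cal2$w0 / cal$w0, sqrt(2), tolerance = 1e-12)
  expect_equal(cal2$V_eff / cal$V_eff, 2^1.5, tolerance = 1e-12)
})

test_that("two-component structure in a dye curve triggers a warning", {
  p <- tf_params(N = 1, F2 = 0.4, tauD1 = 2.5e-5, tauD2 = 0.05)
  cv <- simulate_model_acf(p, make_lag_grid(2e-6, 3), noise_sd = 0)
  expect_warning(calibrate_focus(cv, known_D = 400), "two-component")
})

test_that("physical quantities derive correctly from fit and calibration", {
  cal <- calibrate_focus(25e-6, known_D = 400, kappa = 5)
  # unit arithmetic: 1 molecule in 1 fl is ~1.66 nM
  p1 <- fcs_model_params(N = 1, F2 = 0, tauD1 = 1e-3)
  cal1 <- cal; cal1$V_eff <- 1
  expect_equal(derive_physical(p1, cal1)$concentration_nM,
               1e24 / 6.02214076e23, tolerance = 1e-9)
  # the blastula-regime inversion: N chosen to give ~44.3 nM at 1 fl
  p2 <- fcs_model_params(N = 26.7, F2 = 0, tauD1 = 1e-3)
  expect_equal(derive_physical(p2, cal1)$concentration_nM, 44.34,
               tolerance = 0.01)
  # D from the diffusion time, against independent arithmetic
  p3 <- fcs_model_params(N = 5, F2 = 0, tauD1 = 3030e-6)
  expect_equal(derive_physical(p3, cal)$D1, 0.2^2 / (4 * 3030e-6),
               tolerance = 1e-12)
})

test_that("brightness QC applies the ten-percent window at the boundary", {
  expect_true(brightness_qc(1000, 1, 1000)$pass)
  expect_true(brightness_qc(1099, 1, 1000)$pass)
  expect_false(brightness_qc(1101, 1, 1000)$pass)
  expect_false(brightness_qc(899, 1, 1000)$pass)
  expect_error(brightness_qc(1000, 1, 0), "positive")
})

test_that("aberration-like focal widening fails the brightness QC", {
  # same concentration, wider focus at constant excitation power: the
  # peak intensity (and with it the per-molecule brightness I/N) drops
  # as (w0_ref/w0)^3 while the fitted N grows with V_eff
  base <- sim_trace_params(duration = 5, dt = 2e-4,
                           n_molecules_per_species =
                             molecules_for_concentration(30, 3),
                           diffusion_coeffs = 2,
                           brightness_per_molecule = 2e4, w0 = 0.2,
                           seed = 81)
  wide <- base; wide$w0 <- 0.3; wide$seed <- 82L
  wide$brightness_per_molecule <- 2e4 * (0.2 / 0.3)^3
  fit_n <- function(prm) {
    cv <- suppressWarnings(
      estimate_curve_sigma(simulate_brownian_trace(prm), n_segments = 8))
    list(fit = tf_fit(cv), rate = cv$mean_intensity[["g"]])
  }
  a <- fit_n(base); b <- fit_n(wide)
  ref <- a$rate / a$fit$params$N
  expect_true(brightness_qc(a$rate, a$fit$params$N, ref)$pass)
  expect_false(brightness_qc(b$rate, b$fit$params$N, ref)$pass)
})

test_that("fit methods expose prediction, residuals and simulation", {
  p <- tf_params()
  lags <- make_lag_grid()
  cv <- simulate_model_acf(p, lags, fcs_noise_profile(p, lags), seed = 3)
  f <- fit_acf(cv)
  expect_equal(predict(f, lags), fitted(f))
  expect_equal(residuals(f), cv$G - fitted(f))
  reps <- simulate(f, nsim = 3, seed = 4)
  expect_length(reps, 3)
  expect_s3_class(reps[[1]], "correlation_curve")
  expect_false(identical(reps[[1]]$G, reps[[2]]$G))
})
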