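test_that("Brownian traces honour degenerate and invalid parameters", {
  p0 <- sim_trace_params(duration = 0.5, dt = 1e-3,
                         n_molecules_per_species = 0,
                         diffusion_coeffs = 10,
                         brightness_per_molecule = 1e4, seed = 1)
  tr <- simulate_brownian_trace(p0)
  expect_true(all(tr$counts_g == 0))
  expect_error(sim_trace_params(duration = 1, dt = 2,
                                n_molecules_per_species = 1,
                                diffusion_coeffs = 10,
                                brightness_per_molecule = 1e4),
               "smaller than")
  expect_error(sim_trace_params(duration = 1, dt = 1e-3,
                                n_molecules_per_species = 1,
                                diffusion_coeffs = 10,
                                brightness_per_molecule = 1e4,
                                crosstalk_coeff = 1),
               "outside")
})

test_that("mean count rate matches the numerical-integration oracle", {
  w0 <- 0.2; kappa <- 5; box <- 3
  b <- 5e4; bg <- 400; nmol <- 20
  p <- sim_trace_params(duration = 4, dt = 2e-4,
                        n_molecules_per_species = nmol,
                        diffusion_coeffs = 5,
                        brightness_per_molecule = b,
                        background_rate = bg,
                        box_size = box, w0 = w0, kappa = kappa, seed = 3)
  tr <- simulate_brownian_trace(p)
  expected_rate <- bg + nmol * b * mean_detection_box(w0, kappa * w0, box)
  observed_rate <- mean(tr$counts_g) / tr$dt
  expect_equal(observed_rate, expected_rate, tolerance = 0.1)
})

test_that("fixed seeds give bit-identical traces", {
  p <- sim_trace_params(duration = 1, dt = 1e-3,
                        n_molecules_per_species = 5,
                        diffusion_coeffs = 20,
                        brightness_per_molecule = 3e4, seed = 11)
  t1 <- simulate_brownian_trace(p)
  t2 <- simulate_brownian_trace(p)
  expect_identical(t1$counts_g, t2$counts_g)
  p2 <- p; p2$seed <- 12L
  t3 <- simulate_brownian_trace(p2)
  expect_false(identical(t1$counts_g, t3$counts_g))
})

test_that("trace ACF amplitude tracks 1/N_eff of the simulation geometry", {
  conc <- 20  # nM
  box <- 3; w0 <- 0.2; kappa <- 5
  p <- sim_trace_params(duration = 12, dt = 1e-4,
                        n_molecules_per_species =
                          molecules_for_concentration(conc, box),
                        diffusion_coeffs = 2,
                        brightness_per_molecule = 2e4,
                        box_size = box, w0 = w0, kappa = kappa, seed = 21)
  tr <- simulate_brownian_trace(p)
  cv <- multitau_correlate(tr)
  calib <- calibrate_focus(w0^2 / (4 * 400), known_D = 400, kappa = kappa)
  n_eff <- conc * calib$V_eff / (1e24 / 6.02214076e23)
  amp <- mean(head(cv$G, 3))
  expect_equal(amp, 1 / n_eff, tolerance = 0.15)
})

test_that("model-generated curves honour the noise contract", {
  p <- tf_params()
  lags <- make_lag_grid(1e-5, 1)
  cv0 <- simulate_model_acf(p, lags, noise_sd = 0)
  expect_equal(cv0$G, eval_acf_model(p, lags))
  # amplitude limit at the smallest lag
  tiny <- simulate_model_acf(p, c(1e-9, 1e-8), noise_sd = 0)
  expect_equal(tiny$G[1], p$G_inf + 1 / p$N, tolerance = 1e-4)
  expect_error(simulate_model_acf(p, lags, noise_sd = -0.1), "non-negative")
})

test_that("requested per-lag sigma is realised across Monte-Carlo replicates", {
  p <- tf_params()
  lags <- make_lag_grid(1e-5, 1, points_per_decade = 4)
  sig <- fcs_noise_profile(p, lags, rel = 0.03)
  G <- sapply(seq_len(1000), function(i)
    simulate_model_acf(p, lags, noise_sd = sig, seed = i)$G)
  sd_hat <- apply(G, 1, sd)
  expect_true(all(abs(sd_hat / sig - 1) < 0.15))
  expect_lt(mean(abs(sd_hat / sig - 1)), 0.05)
})

test_that("binding-ensemble ground truth obeys mass action exactly", {
  prm <- binding_ensemble_params(20, c(20, 150), c(10, 80), kd = 37,
                                 seed = 5)
  ens <- simulate_binding_ensemble(prm, output = "amplitudes")
  tr <- ensemble_truth(ens)
  expect_equal(nrow(tr), 20)
  resid <- tr$C_free_g * tr$C_free_r - 37 * tr$C_complex
  expect_lt(max(abs(resid)), 1e-9)
  expect_true(all(tr$total_g >= 20 & tr$total_g <= 150))
  expect_true(all(tr$total_r >= 10 & tr$total_r <= 80))
})

test_that("ensemble association limits behave at extreme kd", {
  eq <- simulate_binding_ensemble(
    binding_ensemble_params(10, c(50, 50.0001), c(50, 50.0001), kd = 0,
                            seed = 2), output = "amplitudes")
  tr <- ensemble_truth(eq)
  expect_equal(tr$C_complex, pmin(tr$total_g, tr$total_r), tolerance = 1e-9)
  loose <- simulate_binding_ensemble(
    binding_ensemble_params(10, c(20, 80), c(20, 80), kd = 1e9, seed = 2),
    output = "amplitudes")
  expect_lt(max(ensemble_truth(loose)$C_complex), 1e-5)
})

test_that("TCSPC expectation is log-linear for a bare mono-exponential", {
  tau <- 2.5
  prm <- decay_sim_params(tau, 1, total_counts = 5e6, n_bins = 256,
                          window = 20, irf_fwhm = 0, irf_shift = 0,
                          background_fraction = 0, seed = 9)
  h <- simulate_tcspc_decay(prm)
  t_ns <- (seq_along(h$counts) - 0.5) * h$bin_time
  sel <- h$counts > 50 & t_ns < 3 * tau
  fit <- lm(log(h$counts[sel]) ~ t_ns[sel], weights = h$counts[sel])
  expect_equal(unname(coef(fit)[2]), -1 / tau, tolerance = 0.02)
})

test_that("degenerate amplitude fractions reduce to the mono simulation", {
  a <- simulate_tcspc_decay(decay_sim_params(c(2.3, 0.8), c(1, 0),
                                             total_counts = 1e5, seed = 7))
  b <- simulate_tcspc_decay(decay_sim_params(2.3, 1, total_counts = 1e5,
                                             seed = 7))
  expect_identical(a$counts, b$counts)
})

test_that("short TCSPC windows trigger the truncation warning", {
  expect_warning(decay_sim_params(9, 1, window = 20), "truncation")
  expect_error(decay_sim_params(25, 1, window = 20), "outside")
})

test_that("seed splitting is deterministic and spreads streams", {
  expect_identical(split_seed(1, 0), split_seed(1, 0))
  s <- vapply(0:200, function(k) split_seed(123, k), 1L)
  expect_equal(length(unique(s)), 201L)
  expect_true(all(s >= 0 & s < 2^31 - 1))
})
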