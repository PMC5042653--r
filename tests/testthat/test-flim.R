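test_that("high-count mono decays are recovered to one percent", {
  h <- simulate_tcspc_decay(decay_sim_params(2.5, 1, total_counts = 1e6,
                                             background_fraction = 0.02,
                                             seed = 2))
  f <- fit_decay(h, "mono")
  expect_true(f$converged)
  expect_equal(f$tau1, 2.5, tolerance = 0.01)
  expect_identical(f$binding_pct, 0)
})

test_that("binding percentage follows the amplitude identity", {
  h <- simulate_tcspc_decay(decay_sim_params(c(2.3, 0.8), c(0.5, 0.5),
                                             total_counts = 3e5, seed = 6))
  f <- fit_decay(h, "biexp", fix_tau1 = 2.3)
  expect_equal(binding_percentage(f), 50, tolerance = 5)
  expect_equal(binding_percentage(f), 100 * f$a2 / (f$a1 + f$a2),
               tolerance = 1e-12)
  mono <- fit_decay(h, "mono")
  expect_message(bp <- binding_percentage(mono), "mono")
  expect_identical(bp, 0)
})

test_that("binding percentage is invariant under histogram scaling", {
  prm <- decay_sim_params(c(2.3, 0.8), c(0.7, 0.3), total_counts = 1e5,
                          seed = 8)
  h <- simulate_tcspc_decay(prm)
  f1 <- fit_decay(h, "biexp", fix_tau1 = 2.3)
  h2 <- h; h2$counts <- h$counts * 4
  f2 <- fit_decay(h2, "biexp", fix_tau1 = 2.3)
  expect_equal(f1$binding_pct, f2$binding_pct, tolerance = 0.5)
})

test_that("a vanishing second component collapses the biexp fit", {
  h <- simulate_tcspc_decay(decay_sim_params(2.3, 1, total_counts = 2e5,
                                             background_fraction = 0.01,
                                             seed = 12))
  f <- fit_decay(h, "biexp", fix_tau1 = 2.3)
  sel <- select_model(h, fix_tau1 = 2.3)
  expect_true(f$a2 < 0.02 || sel$model == "mono")
})

test_that("model selection routes by evidence and amplitude floor", {
  pure <- simulate_tcspc_decay(decay_sim_params(2.3, 1, total_counts = 1e5,
                                                background_fraction = 0.01,
                                                seed = 14))
  expect_identical(select_model(pure, fix_tau1 = 2.3)$model, "mono")

  bound30 <- simulate_tcspc_decay(decay_sim_params(c(2.3, 0.8),
                                                   c(0.7, 0.3),
                                                   total_counts = 1e5,
                                                   seed = 15))
  expect_identical(select_model(bound30, fix_tau1 = 2.3)$model, "biexp")

  bound1 <- simulate_tcspc_decay(decay_sim_params(c(2.3, 0.8),
                                                  c(0.99, 0.01),
                                                  total_counts = 1e5,
                                                  seed = 16))
  expect_identical(select_model(bound1, fix_tau1 = 2.3)$model, "mono")
})

test_that("amplitude-fraction recovery is unbiased at high counts", {
  for (a2 in c(0.1, 0.3, 0.5)) {
    est <- vapply(1:8, function(i) {
      h <- simulate_tcspc_decay(decay_sim_params(c(2.3, 0.8),
                                                 c(1 - a2, a2),
                                                 total_counts = 1e5,
                                                 seed = 100 * a2 + i))
      fit_decay(h, "biexp", fix_tau1 = 2.3)$a2
    }, 0)
    expect_lt(abs(mean(est) - a2), 0.02)
  }
})

test_that("fitted mean lifetime matches the empirical mean arrival time", {
  # intensity-weighted mean lifetime = mean photon arrival delay
  prm <- decay_sim_params(c(2.3, 0.8), c(0.7, 0.3), total_counts = 5e5,
                          window = 30, n_bins = 600, irf_fwhm = 0.35,
                          irf_shift = 2, background_fraction = 0, seed = 18)
  h <- simulate_tcspc_decay(prm)
  f <- fit_decay(h, "biexp")
  t_ns <- (seq_along(h$counts) - 0.5) * h$bin_time
  empirical <- sum(t_ns * h$counts) / sum(h$counts) - prm$irf_shift
  expect_equal(f$tau_mean_intensity, empirical, tolerance = 0.03)
})

test_that("fixing the donor lifetime sharpens the bound amplitude", {
  h <- simulate_tcspc_decay(decay_sim_params(c(2.3, 0.8), c(0.73, 0.27),
                                             total_counts = 1e5, seed = 21))
  free <- fit_decay(h, "biexp")
  fixed <- fit_decay(h, "biexp", fix_tau1 = 2.3)
  expect_lt(fixed$se[["f2"]], free$se[["f2"]])
})

test_that("low-count histograms warn", {
  prm <- decay_sim_params(2.3, 1, total_counts = 500, seed = 23)
  h <- simulate_tcspc_decay(prm)
  expect_warning(fit_decay(h, "mono"), "photons")
})

test_that("lifetime maps are deterministic and separate populations", {
  mono_h <- simulate_tcspc_decay(decay_sim_params(2.3, 1,
                                                  total_counts = 1e5,
                                                  seed = 31))
  single <- lifetime_map(list(u1 = mono_h), model = "mono")
  direct <- fit_decay(mono_h, "mono")
  expect_equal(single$tau1, direct$tau1, tolerance = 1e-12)

  same <- lifetime_map(list(a = mono_h, b = mono_h), model = "mono")
  expect_identical(same$tau1[1], same$tau1[2])

  decays <- c(
    lapply(1:6, function(i) simulate_tcspc_decay(
      decay_sim_params(2.3, 1, total_counts = 1e5,
                       background_fraction = 0.01, seed = 40 + i))),
    lapply(1:6, function(i) simulate_tcspc_decay(
      decay_sim_params(c(2.3, 0.8), c(0.7, 0.3), total_counts = 1e5,
                       background_fraction = 0.01, seed = 60 + i))))
  names(decays) <- sprintf("cell%02d", 1:12)
  tab <- lifetime_map(decays, model = "auto", fix_tau1 = 2.3)
  expect_identical(nrow(tab), 12L)
  expect_lt(max(tab$binding_pct[1:6]), min(tab$binding_pct[7:12]))
  expect_error(lifetime_map(list()), "non-empty")
})
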