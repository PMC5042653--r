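test_that("zero bleed-through leaves amplitudes untouched", {
  out <- correct_crosstalk(0.1, 0.2, 0.05, 0, c(g = 100, r = 50))
  expect_identical(out$G_g0, 0.1)
  expect_identical(out$G_r0, 0.2)
  expect_identical(out$G_x0, 0.05)
  expect_error(correct_crosstalk(0.1, 0.2, 0.05, 1, c(g = 1, r = 1)),
               "outside")
})

test_that("forward contamination then correction is an exact round trip", {
  truth <- list(G_g0 = 0.08, G_r0 = 0.15, G_x0 = 0.04)
  inten <- c(g = 120, r = 60)
  for (beta in c(0.03, 0.1, 0.2)) {
    irm <- inten[["r"]] + beta * inten[["g"]]
    meas <- list(
      G_x0 = (truth$G_x0 * inten[["r"]] + beta * truth$G_g0 * inten[["g"]]) / irm,
      G_r0 = (truth$G_r0 * inten[["r"]]^2 +
                2 * beta * truth$G_x0 * inten[["g"]] * inten[["r"]] +
                beta^2 * truth$G_g0 * inten[["g"]]^2) / irm^2)
    corr <- correct_crosstalk(truth$G_g0, meas$G_r0, meas$G_x0, beta,
                              c(g = inten[["g"]], r = irm))
    expect_equal(corr$G_r0, truth$G_r0, tolerance = 1e-12)
    expect_equal(corr$G_x0, truth$G_x0, tolerance = 1e-12)
    expect_equal(corr$intensities[["r"]], inten[["r"]], tolerance = 1e-12)
  }
})

test_that("a donor-only cell corrects to zero complex", {
  cal <- default_calib()
  # green-only species: true CCF amplitude 0, contamination creates one
  n_tg <- 10; beta <- 0.1
  g_g0 <- 1 / n_tg
  ig <- n_tg; irm <- beta * ig + 2  # small true red signal from autofluorescence
  ir <- 2
  g_x0_meas <- (0 * ir + beta * g_g0 * ig) / irm
  g_r0_meas <- (0.001 * ir^2 + beta^2 * g_g0 * ig^2) / irm^2
  corr <- correct_crosstalk(g_g0, g_r0_meas, g_x0_meas, beta,
                            c(g = ig, r = irm))
  expect_equal(corr$G_x0, 0, tolerance = 1e-12)
})

test_that("amplitude-to-concentration inversion is exact", {
  cal <- default_calib()
  nmfl <- 1e24 / 6.02214076e23
  n_tg <- (20 + 10) * cal$V_eff / nmfl
  n_tr <- (30 + 10) * cal$V_eff / nmfl
  n_cx <- 10 * cal$V_eff / nmfl
  res <- amplitudes_to_concentrations(1 / n_tg, 1 / n_tr,
                                      n_cx / (n_tg * n_tr), cal, cal)
  expect_equal(res$C_free_g, 20, tolerance = 1e-9)
  expect_equal(res$C_free_r, 30, tolerance = 1e-9)
  expect_equal(res$C_complex, 10, tolerance = 1e-9)
  expect_equal(res$association_pct, 100 * 10 / 30, tolerance = 1e-9)
  expect_false(res$floored)

  zero <- amplitudes_to_concentrations(1 / n_tg, 1 / n_tr, 0, cal, cal)
  expect_identical(zero$C_complex, 0)
  expect_identical(zero$association_pct, 0)

  bad <- amplitudes_to_concentrations(-0.1, 1 / n_tr, 0, cal, cal)
  expect_true(bad$rejected)
  expect_match(bad$reason, "green")
})

test_that("association fraction hits its limits", {
  res <- list(C_complex = 0, total_g = 50, total_r = 80)
  expect_identical(association_fraction(res), 0)
  res$C_complex <- 50
  expect_identical(association_fraction(res), 100)
  res$total_g <- 0
  expect_warning(out <- association_fraction(res), "undefined")
  expect_true(is.na(out))
})

test_that("exact mass-action points give slope kd with r^2 = 1", {
  set.seed(3)
  tg <- exp(runif(20, log(20), log(150)))
  tr <- exp(runif(20, log(20), log(150)))
  cx <- solve_equilibrium(tg, tr, 10)
  cells <- data.frame(C_free_g = tg - cx, C_free_r = tr - cx,
                      C_complex = cx)
  kd <- suppressWarnings(estimate_kd(cells))  # lm flags the perfect fit
  expect_true(kd$linear)
  expect_equal(kd$kd, 10, tolerance = 1e-9)
  expect_equal(kd$r_squared, 1, tolerance = 1e-9)
  expect_error(estimate_kd(cells[1:2, ]), "at least 3")
})

test_that("full pipeline recovers per-cell triples within sampling error", {
  cal <- default_calib()
  prm <- binding_ensemble_params(20, c(20, 150), c(20, 150), kd = 15,
                                 seed = 23)
  ens <- simulate_binding_ensemble(prm, "curves", cal, cal)
  res <- lapply(ens, function(cell)
    fit_fccs_cell(cell$curves, cal, cal, cell_id = cell$cell_id))
  d <- do.call(rbind, lapply(res, as.data.frame))
  d <- d[!d$rejected & !d$floored, ]
  viol <- abs(d$C_free_g * d$C_free_r - 15 * d$C_complex) /
    (15 * d$C_complex)
  expect_lt(median(viol), 0.3)
})

test_that("no-association ensembles are reported as non-linear", {
  cal <- default_calib()
  prm <- binding_ensemble_params(18, c(20, 150), c(20, 150), kd = 1e8,
                                 seed = 31)
  ens <- simulate_binding_ensemble(prm, "curves", cal, cal)
  res <- lapply(ens, function(cell)
    fit_fccs_cell(cell$curves, cal, cal, cell_id = cell$cell_id))
  kd <- suppressWarnings(estimate_kd(res))
  expect_false(kd$linear)
  expect_true(is.na(kd$kd))
})

test_that("mean association falls as kd rises", {
  cal <- default_calib()
  assoc <- vapply(c(5, 37, 200), function(kd) {
    prm <- binding_ensemble_params(12, c(40, 80), c(40, 80), kd = kd,
                                   seed = 47)
    ens <- simulate_binding_ensemble(prm, "curves", cal, cal)
    res <- lapply(ens, function(cell)
      fit_fccs_cell(cell$curves, cal, cal, cell_id = cell$cell_id))
    mean(vapply(res, function(r) r$association_pct, 0), na.rm = TRUE)
  }, 0)
  expect_true(all(diff(assoc) < 0))
})

test_that("kd estimates are insensitive to corrected bleed-through", {
  cal <- default_calib()
  kds <- vapply(c(0, 0.1, 0.2), function(beta) {
    prm <- binding_ensemble_params(25, c(20, 150), c(20, 150), kd = 15.34,
                                   seed = 53)
    ens <- simulate_binding_ensemble(prm, "curves", cal, cal,
                                     bleedthrough = beta)
    res <- lapply(ens, function(cell)
      fit_fccs_cell(cell$curves, cal, cal, bleedthrough = beta,
                    cell_id = cell$cell_id))
    suppressWarnings(estimate_kd(res))$slope
  }, 0)
  expect_lt(max(abs(kds / kds[1] - 1)), 0.1)
})

test_that("trace-level ensembles co-encode the complex in both channels", {
  cal <- default_calib()
  prm <- binding_ensemble_params(2, c(30, 30.001), c(30, 30.001),
                                 kd = 0.5, complex_diffusion = 2,
                                 free_diffusion = 20, seed = 71)
  ens <- simulate_binding_ensemble(prm, "traces", cal, cal,
                                   trace_duration = 4, trace_dt = 1e-4)
  tr <- ens[[1]]$trace
  expect_false(is.null(tr$counts_r))
  ccf <- multitau_correlate(tr, "g", "r")
  # nearly fully complexed cell: cross-correlation amplitude close to the
  # mass-action prediction G_x0 = N_complex / (N_g N_r)
  truth <- ens[[1]]$truth
  nmfl <- 1e24 / 6.02214076e23
  n_tg <- truth$total_g * cal$V_eff / nmfl
  n_tr <- truth$total_r * cal$V_eff / nmfl
  n_cx <- truth$C_complex * cal$V_eff / nmfl
  expect_equal(mean(head(ccf$G, 3)), n_cx / (n_tg * n_tr),
               tolerance = 0.35)
})

test_that("a kd = 0 ensemble with equal totals approaches full association", {
  cal <- default_calib()
  prm <- binding_ensemble_params(12, c(50, 60), c(50, 60), kd = 0.01,
                                 seed = 59)
  ens <- simulate_binding_ensemble(prm, "curves", cal, cal)
  res <- lapply(ens, function(cell)
    fit_fccs_cell(cell$curves, cal, cal, cell_id = cell$cell_id))
  assoc <- vapply(res, function(r)
    if (r$rejected) NA_real_ else r$association_pct, 0)
  expect_gt(mean(assoc, na.rm = TRUE), 85)
})
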