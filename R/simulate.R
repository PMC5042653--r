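#' Parameters for Brownian-dynamics trace simulation
#'
#' Describes a simulated single-point FCS/FCCS measurement: one or more
#' molecular species random-walking in a periodic cubic box around a 3D
#' Gaussian detection volume, emitting photons that are binned into one or
#' two detection channels.
#'
#' @param duration Trace duration in seconds.
#' @param dt Sampling interval (bin width) in seconds; must be < duration.
#' @param box_size Box edge in µm (periodic boundaries). The default 3 µm
#'   is >= 10 focal radii, keeping boundary artefacts negligible.
#' @param n_molecules_per_species Integer vector, molecules per species.
#' @param diffusion_coeffs Diffusion coefficient per species, µm²/s.
#' @param brightness_per_molecule Green-channel brightness per species,
#'   counts/s at the focus centre.
#' @param brightness_red Optional red-channel brightness per species; any
#'   positive entry switches on the second channel (a doubly-labelled
#'   complex has positive brightness in both).
#' @param w0 Lateral 1/e² focus radius, µm.
#' @param kappa Structure parameter; axial radius `z0 = kappa * w0`.
#' @param background_rate Green-channel background, counts/s.
#' @param background_rate_r Red-channel background, counts/s.
#' @param bleach_time Exponential photobleaching time constant in seconds,
#'   applied to molecular brightness (`NULL` = no bleaching).
#' @param crosstalk_coeff Fraction of the molecular green signal detected
#'   in the red channel (spectral bleed-through), in `[0, 1)`.
#' @param seed Integer seed.
#' @return An object of class `sim_trace_params`.
#' @export
sim_trace_params <- function(duration, dt, n_molecules_per_species,
                             diffusion_coeffs, brightness_per_molecule,
                             brightness_red = NULL,
                             box_size = 3, w0 = 0.2, kappa = 5,
                             background_rate = 0, background_rate_r = 0,
                             bleach_time = NULL, crosstalk_coeff = 0,
                             seed = 1L) {
  check_number(duration, "duration", lower = 1e-9)
  check_number(dt, "dt", lower = 1e-12)
  if (dt >= duration) stopf("'dt' must be smaller than 'duration'")
  check_number(box_size, "box_size", lower = 1e-3)
  check_number(w0, "w0", lower = 1e-6)
  check_number(kappa, "kappa", lower = 1)
  check_number(background_rate, "background_rate", lower = 0)
  check_number(background_rate_r, "background_rate_r", lower = 0)
  check_number(crosstalk_coeff, "crosstalk_coeff", lower = 0,
               upper = 1 - 1e-12)
  if (!is.null(bleach_time)) check_number(bleach_time, "bleach_time",
                                          lower = 1e-9)
  ns <- length(n_molecules_per_species)
  if (ns < 1L) stopf("need at least one species")
  if (any(n_molecules_per_species < 0)) stopf("molecule counts must be >= 0")
  if (length(diffusion_coeffs) != ns ||
      length(brightness_per_molecule) != ns)
    stopf("per-species vectors must share a length")
  if (any(diffusion_coeffs <= 0)) stopf("diffusion coefficients must be > 0")
  if (any(brightness_per_molecule < 0)) stopf("brightness must be >= 0")
  if (is.null(brightness_red)) brightness_red <- rep(0, ns)
  if (length(brightness_red) != ns || any(brightness_red < 0))
    stopf("'brightness_red' must be a length-matched non-negative vector")
  structure(list(duration = duration, dt = dt, box_size = box_size,
                 n_molecules_per_species = as.integer(n_molecules_per_species),
                 diffusion_coeffs = diffusion_coeffs,
                 brightness_per_molecule = brightness_per_molecule,
                 brightness_red = brightness_red,
                 w0 = w0, kappa = kappa,
                 background_rate = background_rate,
                 background_rate_r = background_rate_r,
                 bleach_time = bleach_time,
                 crosstalk_coeff = crosstalk_coeff,
                 seed = as.integer(seed)),
            class = "sim_trace_params")
}

#' Number of molecules matching a concentration in the simulation box
#'
#' @param conc_nM Concentration in nM.
#' @param box_size Box edge in µm.
#' @return Integer molecule count `round(C * N_A * box^3)`.
#' @export
molecules_for_concentration <- function(conc_nM, box_size = 3) {
  check_number(conc_nM, "conc_nM", lower = 0)
  as.integer(round(conc_nM * box_size^3 / .NM_PER_MOLECULE_FL))
}

#' Simulate a photon-count trace by Brownian dynamics
#'
#' Propagates every molecule with per-axis Gaussian steps of standard
#' deviation `sqrt(2 D dt_sim)`, where the inner step `dt_sim` is at most
#' `dt/5` and at most a tenth of the fastest focal transit time
#' `w0^2/(4 D)`, so intra-bin focal passages are resolved. The detection
#' profile is `exp(-2 r^2/w0^2 - 2 z^2/z0^2)`; per-bin counts are Poisson
#' draws on the time-averaged emission rate plus background, with optional
#' exponential photobleaching of the molecular brightness and spectral
#' cross-talk into the red channel. Fixed seeds give bit-identical traces.
#'
#' @param params A [sim_trace_params()].
#' @return An [intensity_trace()] (two channels when a red-emitting species
#'   or cross-talk is configured).
#' @export
simulate_brownian_trace <- function(params) {
  stopifnot(inherits(params, "sim_trace_params"))
  n_bins <- as.integer(round(params$duration / params$dt))
  transit <- params$w0^2 / (4 * max(params$diffusion_coeffs))
  substeps <- max(5L, as.integer(ceiling(params$dt / (transit / 10))))
  two_channel <- any(params$brightness_red > 0) ||
    params$crosstalk_coeff > 0 || params$background_rate_r > 0
  raw <- with_seed(split_seed(params$seed, 1L),
                   .sim_trace_cpp(n_bins, params$dt, substeps,
                                  params$box_size, params$w0,
                                  params$kappa * params$w0,
                                  params$n_molecules_per_species,
                                  params$diffusion_coeffs,
                                  params$brightness_per_molecule,
                                  params$brightness_red,
                                  params$background_rate,
                                  params$background_rate_r,
                                  if (is.null(params$bleach_time)) 0 else
                                    params$bleach_time,
                                  params$crosstalk_coeff, two_channel))
  intensity_trace(params$dt, raw$counts_g,
                  counts_r = if (two_channel) raw$counts_r else NULL,
                  metadata = list(simulation = params, substeps = substeps))
}

#' Default quasi-logarithmic lag grid
#'
#' @param lag_min,lag_max Lag range in seconds.
#' @param points_per_decade Grid density.
#' @return Increasing lag vector.
#' @export
make_lag_grid <- function(lag_min = 2e-6, lag_max = 3, points_per_decade = 24) {
  exp(seq(log(lag_min), log(lag_max),
          length.out = ceiling(log10(lag_max / lag_min) * points_per_decade)))
}

#' Realistic per-lag noise profile for model-generated curves
#'
#' Per-lag standard deviation for the fast-path curve generator, shaped as
#' \deqn{\sigma(\tau) = rel \cdot \frac{1}{N}\left(0.4 +
#'   0.6\sqrt{G_{norm}(\tau)}\right)}
#' where `G_norm` is the model decay normalised to its amplitude: full
#' `rel` noise at the amplitude, falling to 40% of it in the decayed tail.
#' The shape and the default `rel = 0.02` were calibrated once against
#' segment-wise sigma estimates from the package's own Brownian-dynamics
#' traces (30 s, tens of nM, multi-tau correlated), so fast-path ensembles
#' carry the noise a physical trace of the same conditions would.
#'
#' @param params An [fcs_model_params()].
#' @param lags Lag grid (s).
#' @param rel Relative noise at the curve amplitude.
#' @return Per-lag sigma vector.
#' @export
fcs_noise_profile <- function(params, lags, rel = 0.02) {
  g <- eval_acf_model(params, lags) - params$G_inf
  amp <- 1 / params$N
  rel * amp * (0.4 + 0.6 * sqrt(pmax(g / amp, 0)))
}

#' Generate a noisy correlation curve directly from the model
#'
#' Fast-path generator for fit-recovery studies: evaluates the
#' anomalous-diffusion model on a lag grid and adds zero-mean Gaussian
#' noise with a prescribed per-lag standard deviation, which is recorded in
#' the returned curve for weighted fitting. Orders of magnitude cheaper
#' than Brownian-dynamics simulation plus correlation, at the price of an
#' idealised noise model.
#'
#' @param params An [fcs_model_params()].
#' @param lags Strictly increasing, positive lag grid (s).
#' @param noise_sd Per-lag standard deviation: a scalar, a vector matching
#'   `lags`, or 0 for a noiseless curve.
#' @param seed Integer seed (`NULL` = use the current RNG stream).
#' @param kind Curve label.
#' @return A [correlation_curve()] with `sigma` attached.
#' @export
simulate_model_acf <- function(params, lags, noise_sd = 0, seed = NULL,
                               kind = "ACF_g") {
  stopifnot(inherits(params, "fcs_model_params"))
  if (any(lags <= 0) || any(diff(lags) <= 0))
    stopf("'lags' must be positive and strictly increasing")
  sig <- rep_len(noise_sd, length(lags))
  if (any(sig < 0)) stopf("'noise_sd' must be non-negative")
  g <- eval_acf_model(params, lags)
  noise <- with_seed(if (is.null(seed)) NULL else split_seed(seed, 2L),
                     rnorm(length(lags), 0, sig))
  correlation_curve(lags, g + noise, sigma = sig, kind = kind,
                    metadata = list(truth = unclass(params)))
}

#' Parameters for an equilibrium dual-color binding ensemble
#'
#' Describes a population of cells co-expressing a green- and a red-labelled
#' protein in binding equilibrium at a common dissociation constant, with
#' cell-to-cell expression variability. Per-cell total concentrations are
#' drawn log-uniformly over the stated ranges — a stand-in for the unknown
#' expression spread across embryonic nuclei that spreads the abscissa of
#' the Kd regression.
#'
#' @param n_cells Number of cells (>= 2).
#' @param total_green_range,total_red_range Length-2 positive ranges (nM)
#'   for the per-cell total concentrations.
#' @param kd Dissociation constant, nM.
#' @param complex_diffusion,free_diffusion Diffusion coefficients, µm²/s.
#' @param seed Integer seed.
#' @return An object of class `binding_ensemble_params`.
#' @export
binding_ensemble_params <- function(n_cells, total_green_range,
                                    total_red_range, kd,
                                    complex_diffusion = 1,
                                    free_diffusion = 30, seed = 1L) {
  check_number(n_cells, "n_cells", lower = 2)
  check_number(kd, "kd", lower = 0)
  check_number(complex_diffusion, "complex_diffusion", lower = 1e-9)
  check_number(free_diffusion, "free_diffusion", lower = 1e-9)
  rng_ok <- function(r) length(r) == 2L && all(r > 0) && r[2] >= r[1]
  if (!rng_ok(total_green_range) || !rng_ok(total_red_range))
    stopf("concentration ranges must be positive length-2 vectors")
  structure(list(n_cells = as.integer(n_cells),
                 total_green_range = total_green_range,
                 total_red_range = total_red_range, kd = kd,
                 complex_diffusion = complex_diffusion,
                 free_diffusion = free_diffusion, seed = as.integer(seed)),
            class = "binding_ensemble_params")
}

#' Simulate a dual-color binding ensemble with known ground truth
#'
#' For every cell, total concentrations of the green and red partner are
#' drawn, the complex concentration follows from mass action
#' ([solve_equilibrium()]), and dual-color FCCS observables are emitted in
#' one of three forms: exact correlation `"amplitudes"`, noisy model
#' `"curves"` (two-component ACFs in which the complex co-diffuses in both
#' channels, plus a CCF decaying at the complex diffusion time), or
#' Brownian-dynamics `"traces"` with three species (free green, free red,
#' doubly-labelled complex). Spectral bleed-through can be forward-applied
#' so the correction path is exercised. Ground truth
#' `(C_free_g, C_free_r, C_complex)` is attached per cell and satisfies
#' `C_free_g * C_free_r = kd * C_complex` exactly.
#'
#' @param params A [binding_ensemble_params()].
#' @param output `"amplitudes"`, `"curves"` or `"traces"`.
#' @param calib_g,calib_r Focal calibrations per channel
#'   ([calibrate_focus()]); defaults use `w0 = 0.2` µm, `kappa = 5`.
#' @param bleedthrough Spectral bleed-through coefficient applied forward
#'   to the red/cross observables, in `[0, 1)`.
#' @param noise_rel Relative curve noise for `output = "curves"`.
#' @param lags Lag grid for `output = "curves"`.
#' @param trace_duration,trace_dt,brightness Trace settings for
#'   `output = "traces"`.
#' @return A list of class `binding_ensemble`; one element per cell with
#'   `cell_id`, `truth` (nM triple plus totals), `intensities` and the
#'   requested observables (`amplitudes`: `G_g0`, `G_r0`, `G_x0`;
#'   `curves`: ACF_g/ACF_r/CCF; or `trace`).
#' @export
simulate_binding_ensemble <- function(params,
                                      output = c("amplitudes", "curves",
                                                 "traces"),
                                      calib_g = NULL, calib_r = NULL,
                                      bleedthrough = 0, noise_rel = 0.02,
                                      lags = make_lag_grid(),
                                      trace_duration = 30, trace_dt = 1e-5,
                                      brightness = 2e4) {
  stopifnot(inherits(params, "binding_ensemble_params"))
  output <- match.arg(output)
  check_number(bleedthrough, "bleedthrough", lower = 0, upper = 1 - 1e-9)
  if (is.null(calib_g)) calib_g <- calibrate_focus(2.5e-5, 400, channel = "green")
  if (is.null(calib_r)) calib_r <- calibrate_focus(2.5e-5, 400, channel = "red")
  v_g <- calib_g$V_eff; v_r <- calib_r$V_eff
  v_x <- v_g  # overlap volume convention: green-channel V_eff
  tau_free_g <- calib_g$w0^2 / (4 * params$free_diffusion)
  tau_free_r <- calib_r$w0^2 / (4 * params$free_diffusion)
  tau_cx_g <- calib_g$w0^2 / (4 * params$complex_diffusion)
  tau_cx_r <- calib_r$w0^2 / (4 * params$complex_diffusion)

  draw <- with_seed(split_seed(params$seed, 3L), {
    lu <- function(r, n) exp(runif(n, log(r[1]), log(r[2])))
    list(tg = lu(params$total_green_range, params$n_cells),
         tr = lu(params$total_red_range, params$n_cells),
         noise_seeds = sample.int(2^30, params$n_cells))
  })

  cells <- vector("list", params$n_cells)
  for (i in seq_len(params$n_cells)) {
    tg <- draw$tg[i]; tr <- draw$tr[i]
    cx <- solve_equilibrium(tg, tr, params$kd)
    truth <- list(total_g = tg, total_r = tr,
                  C_free_g = tg - cx, C_free_r = tr - cx, C_complex = cx,
                  kd = params$kd)
    n_tg <- tg * v_g / .NM_PER_MOLECULE_FL
    n_tr <- tr * v_r / .NM_PER_MOLECULE_FL
    n_cx <- cx * v_x / .NM_PER_MOLECULE_FL
    amp <- list(G_g0 = 1 / n_tg, G_r0 = 1 / n_tr,
                G_x0 = n_cx / (n_tg * n_tr))
    # nominal detected intensities (arbitrary brightness units cancel in
    # the bleed-through arithmetic, which uses intensity ratios); the red
    # channel reports what a detector would see, bleed-through included
    inten <- c(g = n_tg, r = n_tr)
    inten_meas <- c(g = n_tg, r = n_tr + bleedthrough * n_tg)

    cell <- list(cell_id = sprintf("cell_%03d", i), truth = truth,
                 intensities = inten_meas)
    if (output == "amplitudes") {
      cell$amplitudes <- .bleed_forward_amp(amp, bleedthrough, inten)
    } else if (output == "curves") {
      f2g <- n_cx * (v_g / v_x) / n_tg   # number fraction of complex, green
      f2r <- n_cx * (v_r / v_x) / n_tr
      pg <- fcs_model_params(N = n_tg, F2 = min(f2g, 1), tauD1 = tau_free_g,
                             tauD2 = tau_cx_g, kappa = calib_g$kappa)
      pr <- fcs_model_params(N = n_tr, F2 = min(f2r, 1), tauD1 = tau_free_r,
                             tauD2 = tau_cx_r, kappa = calib_r$kappa)
      g_g <- eval_acf_model(pg, lags)
      g_r <- eval_acf_model(pr, lags)
      px <- fcs_model_params(N = if (amp$G_x0 > 0) 1 / amp$G_x0 else 1e12,
                             F2 = 0, tauD1 = tau_cx_g, kappa = calib_g$kappa)
      g_x <- if (amp$G_x0 > 0) eval_acf_model(px, lags) else rep(0, length(lags))
      contaminated <- .bleed_forward_curves(g_g, g_r, g_x, bleedthrough, inten)
      mk <- function(vals, kind, sig_ref) {
        # same amplitude-anchored noise shape as fcs_noise_profile()
        sig <- noise_rel * sig_ref *
          (0.4 + 0.6 * sqrt(pmax(vals / sig_ref, 0)))
        noisy <- vals + rnorm(length(lags), 0, sig)
        correlation_curve(lags, noisy, sigma = sig, kind = kind,
                          mean_intensity = inten_meas,
                          metadata = list(cell_id = cell$cell_id))
      }
      cell$curves <- with_seed(draw$noise_seeds[i], list(
        ACF_g = mk(g_g, "ACF_g", 1 / n_tg),
        ACF_r = mk(contaminated$g_r, "ACF_r", 1 / n_tr),
        CCF = mk(contaminated$g_x, "CCF", max(amp$G_x0, 0.02 / sqrt(n_tg * n_tr)))))
    } else {
      box <- 3
      stp <- sim_trace_params(
        duration = trace_duration, dt = trace_dt,
        n_molecules_per_species = c(
          molecules_for_concentration(tg - cx, box),
          molecules_for_concentration(tr - cx, box),
          molecules_for_concentration(cx, box)),
        diffusion_coeffs = c(params$free_diffusion, params$free_diffusion,
                             params$complex_diffusion),
        brightness_per_molecule = c(brightness, 0, brightness),
        brightness_red = c(0, brightness, brightness),
        w0 = calib_g$w0, kappa = calib_g$kappa,
        crosstalk_coeff = bleedthrough,
        seed = draw$noise_seeds[i])
      cell$trace <- simulate_brownian_trace(stp)
    }
    cells[[i]] <- cell
  }
  structure(cells, class = "binding_ensemble",
            params = params, output = output,
            calib_g = calib_g, calib_r = calib_r,
            bleedthrough = bleedthrough)
}

# forward spectral contamination of red/cross amplitudes by bleed-through
.bleed_forward_amp <- function(amp, beta, inten) {
  if (beta <= 0) return(amp)
  ig <- inten[["g"]]; ir <- inten[["r"]]
  irm <- ir + beta * ig
  list(G_g0 = amp$G_g0,
       G_x0 = (amp$G_x0 * ir + beta * amp$G_g0 * ig) / irm,
       G_r0 = (amp$G_r0 * ir^2 + 2 * beta * amp$G_x0 * ig * ir +
                 beta^2 * amp$G_g0 * ig^2) / irm^2)
}

.bleed_forward_curves <- function(g_g, g_r, g_x, beta, inten) {
  if (beta <= 0) return(list(g_r = g_r, g_x = g_x))
  ig <- inten[["g"]]; ir <- inten[["r"]]
  irm <- ir + beta * ig
  list(g_x = (g_x * ir + beta * g_g * ig) / irm,
       g_r = (g_r * ir^2 + 2 * beta * g_x * ig * ir + beta^2 * g_g * ig^2) /
         irm^2)
}

#' Ground-truth table of a binding ensemble
#' @param ensemble A [simulate_binding_ensemble()] result.
#' @return A data.frame with one row per cell.
#' @export
ensemble_truth <- function(ensemble) {
  stopifnot(inherits(ensemble, "binding_ensemble"))
  do.call(rbind, lapply(ensemble, function(cell)
    data.frame(cell_id = cell$cell_id, as.data.frame(cell$truth))))
}

#' Write per-cell ground truth as a JSON sidecar
#' @param ensemble A [simulate_binding_ensemble()] result.
#' @param path Output file (`truth.json`).
#' @return `path`, invisibly.
#' @export
write_ensemble_truth <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "binding_ensemble"))
  payload <- list(params = unclass(attr(ensemble, "params")),
                  cells = lapply(ensemble, function(cell)
                    c(list(cell_id = cell$cell_id), cell$truth)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
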