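---
title: "Models, protocols and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, protocols and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the measurement models, the fitting protocols and why they look the way
they do, what the synthetic-data generators emulate (and what they do
not), and the numerical choices a maintainer would want written down.

## 1. The measurement chain

A confocal microscope parks its focus inside a single cell nucleus and
counts photons. Three inferences are built on those counts:

1. **FCS** — the autocorrelation of the intensity fluctuations decays on
   the timescale molecules need to cross the focus. Its zero-lag
   amplitude is `1/N` (mean focal occupancy), its decay encodes
   mobility. A transcription factor that spends part of its time bound
   to chromatin shows a second, much slower component; the slow fraction
   `F2` is read as the DNA-bound pool.
2. **FCCS** — with a green and a red label on two different proteins,
   the cross-correlation amplitude is non-zero only for species carrying
   both labels, i.e. complexes. Per cell this yields total and complex
   concentrations; across cells, mass action
   (`C_free_g · C_free_r = Kd · C_complex`) makes the free-product
   linear in the complex concentration with slope `Kd`.
3. **FLIM-FRET** — donor fluorophores bound within Förster distance of
   an acceptor decay faster. The TCSPC arrival histogram is a mixture of
   a free component (lifetime `tau1`) and a FRET component (`tau2`), and
   the *amplitude* fraction of the fast component is the bound
   percentage.

## 2. The anomalous-diffusion model and its identifiability

The fitted model is

$$G(\tau) = G_\infty + \frac{1}{N}\sum_{i=1}^{2} F_i
  \left[1+\left(\tfrac{\tau}{\tau_{D,i}}\right)^{\alpha_i}\right]^{-1}
  \left[1+\tfrac{(\tau/\tau_{D,i})^{\alpha_i}}{\kappa^2}\right]^{-1/2}$$

with `F1 + F2 = 1` enforced as a constraint. Defaults and bounds:

| parameter | default / bound | why |
|---|---|---|
| `kappa` | fixed at 5 | never identifiable together with the exponents from a single curve; instrument property, config knob |
| `tauD1` | bounds 10 µs – 50 ms | brackets free fluorophores to slow free proteins |
| `tauD2` | bounds 1 ms – 10 s | chromatin-interaction regime |
| `alpha1`, `alpha2` | bounds 0.2 – 2 in `fit_acf()` | model evaluation range; see protocol below for the bound-fraction default |
| `G_inf` | fitted, bounded at ±10 % of the amplitude | offsets beyond that indicate uncorrected drift |

**The flat ridge.** With all seven parameters free, the model has a
near-exact degeneracy: raising `alpha1` above 1, lowering `tauD2` and
inflating `F2` reproduces a given curve to a relative residual of
~10⁻³ — far below realistic noise. A single noisy curve therefore
cannot place itself along this ridge, and `F2` estimates wander over
±0.15 with a strong positive bias. This is a property of the model, not
of the optimiser; we verified it on noiseless curves.

**The bound-fraction protocol** (`fit_acf_ensemble()`) restores
identifiability with physics:

1. per-curve fit with `alpha1 = 1` pinned (the free pool of a soluble
   protein diffuses normally on focal scales), `G_inf = 0` pinned
   (multi-tau curves from detrended 30-s traces decay to zero), and
   `alpha2` free but bounded at 1 (chromatin interactions subdiffuse;
   superdiffusion would imply directed transport, which nuclear factors
   do not show);
2. `alpha2` pooled across curves that kept a genuine second component;
3. every curve refit with the pooled exponent pinned — the same
   determine-globally-then-recalculate logic used for the shared free
   diffusion time.

Under this protocol, recovery of `F2` from ensembles generated at the
study's operating point (N ≈ 6, `tauD1` ≈ 3 ms, `tauD2` ≈ 100 ms) is
unbiased to < 0.005 with a per-cell scatter of ~0.012 — commensurate
with the per-condition SEMs the measurement type reports. The pins are
arguments, not hard-coded: `fit_acf()` accepts any `fixed`/`upper`
combination.

**Global fitting.** `fit_acf_global()` estimates one shared `tauD1`
by profiling: for each candidate the remaining parameters of every curve
are re-optimised and the summed weighted SSR is minimised by a
golden-section search on a log scale. By construction no common pinned
value beats the optimum (a property the tests assert). The two-step
variant — average individual `tauD1`, then refit — is available as
`method = "average"`.

**Model collapse.** A two-component fit of one-component data is
declared collapsed when `F2 < 0.05` or `tauD2/tauD1 < 3`
(`n_components_effective = 1`), which operationalises "converged to an
effective one-component model" for free-fluorophore controls.

## 3. Calibration, physical units and QC

`calibrate_focus()` fits a reference-dye curve with the one-component
model and `alpha = 1` pinned: a free dye diffuses normally, and at
~25 µs diffusion times a free exponent is degenerate with `tauD`
(we observed the pair (α = 1.12, τ = 32 µs) and (α = 1, τ = 22 µs)
fitting the same curve), which would destabilise the volume estimate.
Then `w0 = sqrt(4 D tauD)`, `z0 = κ w0`, `V_eff = π^{3/2} κ w0³`
(1 µm³ = 1 fl), `C = N/(N_A V_eff)`, `D_i = w0²/(4 τ_{D,i})`.

Molecular brightness (`mean intensity / fitted N`) guards against
optical aberrations: measurements outside ±10 % of the reference
brightness are flagged (`brightness_qc()`), since aberrations inflate
the apparent focal volume and deflate concentrations.

## 4. Dual-color analysis

Amplitudes convert to concentrations with the per-channel volumes and an
overlap volume `V_x` that defaults to the green `V_eff` — the overlap
correction requires chromatic-shift measurements no single-point study
reports, so the default is documented and overridable.

Two estimates of the complex concentration are kept per cell: the
physical one (clipped at zero) and the signed one. The `Kd` regression
uses the *signed* estimate: amplitude noise scales with expression
level, so clipping at zero would hand a no-association ensemble a
spurious positive slope (big cells get big positive `x` excursions *and*
big `y`), defeating the "N.L" call. With symmetric noise the null
ensemble decorrelates and the linearity gate (squared Pearson
correlation ≥ 0.5, exposed as `r2_threshold`) fails as it should.

The regression runs through the origin on **free** concentrations
(total − complex): under mass action that is the only reading for which
the slope *is* `Kd`. Cells where free concentrations had to be floored
at zero are excluded by default — near full association their noise
biases the slope. Spectral bleed-through is corrected at amplitude
level from a donor-only coefficient (`correct_crosstalk()`); the
forward contamination model in the ensemble generator uses the same
algebra, and a paired test confirms the round trip is exact.

## 5. TCSPC fitting

Decays are fit by Poisson maximum likelihood (correct in sparse tail
bins; weighted least squares retained for cross-checks) of an
exponential mixture convolved with an analytic Gaussian IRF, plus a flat
background. The amplitude is profiled out exactly — with a normalised
shape the Poisson MLE of the total is the observed count in the fit
range — which removes a badly scaled parameter that otherwise stalls
the optimiser. The fit range starts half an IRF width before the decay
peak. `tau2 < tau1` is enforced by relabelling; amplitude fractions are
reported normalised.

Two protocol points mirror standard FLIM-FRET practice:

* the donor-only lifetime is fitted on donor-alone cells and then
  **fixed** as `tau1` in donor+acceptor fits (a free four-parameter
  biexponential is poorly identifiable at 10⁵ photons; fixing `tau1`
  demonstrably shrinks the standard error of the bound amplitude);
* cells that may be unbound go through `select_model()`: the second
  component must both pass an F-test at α = 0.01 and carry ≥ 2 %
  amplitude. Forcing a biexponential onto mono data lets `tau2` drift
  toward `tau1` where the amplitude split is arbitrary; the selection
  gate is what makes a 0 %-bound ensemble read < 2 %.

Both the amplitude-weighted mean lifetime (`Σ a_i τ_i`) and the
intensity-weighted one (`Σ a_i τ_i² / Σ a_i τ_i`) are reported, since
published "reduced lifetimes" can be either; the intensity-weighted one
equals the mean photon arrival delay, which the tests verify.

## 6. What the generators emulate — and what they do not

`simulate_brownian_trace()` propagates point molecules with per-axis
Gaussian steps (std `sqrt(2 D dt_sim)`) through a periodic 3-µm box
(≥ 10 focal radii: edge bias negligible at bounded cost) around a 3D
Gaussian detection profile, with the inner step at most a fifth of the
sampling bin and a tenth of the fastest focal transit. Photons are
Poisson draws per bin on the time-averaged rate — binned detection, not
photon timestamps, because the correlator consumes binned traces.
Bleaching is an exponential envelope on molecular brightness;
cross-talk adds a fraction of the molecular green rate to the red
channel. All randomness flows from one seed through a counter-based
splitter (`split_seed()`), so stages reproduce independently.

The fast-path generator (`simulate_model_acf()`) adds Gaussian noise to
the model curve. Its default per-lag profile —
`rel · (1/N) · (0.4 + 0.6 √(G/amp))` with `rel = 0.02` — was calibrated
once against segment-wise sigma estimates from the package's own
Brownian-dynamics traces at tens-of-nM, 30-s conditions, so fast-path
ensembles carry the noise a physical trace would.

Known idealisations: no triplet/blinking photophysics, no detector
afterpulsing or dead time, no photon timestamps (TTTR), uncorrelated
per-lag noise in the fast path (real multi-tau noise is
lag-correlated), log-uniform cell-to-cell expression (the embryo's true
expression spread across nuclei is unreported; the choice spreads the
`Kd` regression's abscissa and is flagged in the generator's
documentation). Passing recovery tests therefore demonstrates correct
inference under these conditions, not robustness to every pathology of
real detectors.

## 7. Detrending and correlation

Photobleaching is removed by a square-root ratio correction anchored at
the global mean, `I_corr = I·√(m/f) + m − √(m f)`, which restores
shot-noise variance and pins the expectation to `m` at every time. The
slow trend `f` is a centred **local-linear** smoother (first-order
Savitzky–Golay, O(n) via cumulative sums): unlike a plain boxcar it has
no lag bias in the shrinking one-sided edge windows, which is where a
monotone bleaching trend otherwise leaves residual slope. The default
1-s window for 30-s traces sits an order below the trace length and
well above diffusion timescales. The exponential alternative is a
zero-phase (forward+backward) EMA.

The multi-tau correlator uses 16 points per octave with factor-2
rebinning and symmetric normalisation with per-lag monitor sums over the
exact overlap window; the first lag is the sampling interval and lags
are reported at bin centres. Per-lag sigmas come from block splitting
(default 10 segments; `sd/√n` across segment curves). Block sigmas are
trustworthy in the shot-noise regime below the diffusion time; at lags
approaching the segment length the per-segment monitors absorb slow
fluctuations and the estimates fall below the truth — a known property
of the estimator, scoped accordingly in the tests.

## 8. Statistics

Groups are summarised as mean ± SEM when they pass a Shapiro–Wilk gate
at α = 0.05 and as median with quartiles otherwise; comparisons use the
Welch t-test when **both** groups pass and Mann–Whitney otherwise, both
two-tailed. The normality procedure and its α are this package's
documented stand-in — the measurement convention it mirrors names only
"normality assumptions". No multiple-testing correction is applied by
default (raw p tiers `*` to `****` are annotation only); a Holm option
exists at the `p.adjust` call site for users who need it.

## 9. Problem sizes and numerical conventions

Recovery studies in the test suite use the sizes the corresponding
experiments report: 39 curves per condition for bound fractions, 35 for
the global diffusion time, 15 cells per `Kd` ensemble, 20 decays per
FLIM group at 10⁵ photons. The Brownian-dynamics round trip in
`scripts/acceptance.R` uses two full 30-s dye traces at 4 µs binning
(7.5 × 10⁶ bins); its in-suite counterpart uses 12-s traces, which
leaves the recovery comfortably inside the 10 % band while keeping the
suite quick. Optimiser settings worth knowing: Levenberg–Marquardt with
`ftol = 1e-15` and warm multi-starts (moments init raced against any
user init and against the component-swapped solution — the exchange
symmetry is where LM stalls); `nlminb` for decay MLE with a
verification restart, because it occasionally reports "false
convergence" at a genuine optimum. Standard errors come from
finite-difference Gauss–Newton (curves) or observed-information
(decays) matrices; singular cases yield `NA` rather than an error.
Reduced χ² is reported against per-lag sigmas when present and is
otherwise an SSR scale, flagged by the `weighted` field.
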