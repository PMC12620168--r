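---
title: "watermrs: models, numerical choices, and what the synthetic benchmark establishes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{watermrs methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`watermrs` removes the residual water signal from ¹H-MRS spectra and
quantifies brain metabolites afterwards. It contains two removers — a
seven-Lorentzian gradient fitter ("WaterFit") and a classical Hankel-SVD
comparator — together with the synthetic-spectrum generator and the
downstream quantification model needed to benchmark them end to end without
any measured data. This vignette records the models, their assumptions, and
every numerical decision a maintainer would want to audit.

## Signal model and conventions

A spectrum lives on an acquisition grid: 1024 complex points at 1199 Hz
bandwidth by default, the time axis being `t_i = i / bw`. Chemical shift and
frequency offset are related by `hz = (ppm − carrier) · transmitter_mhz`.
Two values the simulation scenario never fixes are defaulted here and
exposed in `acq_grid()`: the transmitter frequency (127.7 MHz, a 3 T proton
system, matching the field strength of typical clinical test data) and the
carrier convention (zero frequency offset at 4.7 ppm, the water resonance,
as in clinical MRS practice — water components then sit at small Hz
offsets).

The Fourier convention is fixed once: the forward transform is the unscaled
DFT of the FID with bins reordered so the ppm axis ascends; the inverse
carries `1/N`. Energy satisfies `Σ|spectrum|² = N·Σ|fid|²`; all SNR and
loss definitions below refer to this convention. Frequency bands in ppm are
half-open `[lo, hi)` so that adjacent bands partition the axis exactly.

The shared model unit is the Lorentzian component
`A·e^(−w t)·e^(i(2π f t + φ))` with the damping `w` in s⁻¹ exactly as it
appears in the exponent (no π factors): its full width at half maximum in
the spectrum is `w/π` Hz. The water simulator, the WaterFit model, and the
HSVD decomposition all speak this type.

## WaterFit

The water residual is modeled as seven Lorentzian components whose spectrum
`W(ω)` is fitted to the observed spectrum `S(ω)` by minimizing

```
L(W, S) = MSE(W, S) over [4.4, 7.0) ppm
        + λ · mean |W| over [0.4, 4.4) ppm
        + Σ_m A_m²
```

- **MSE convention.** The squared differences of the real and imaginary
  parts are pooled and averaged (`Σ|W−S|² / (2·n_bins)`), because both
  absorption and dispersion must be subtracted correctly. This was a
  genuinely open choice; the magnitude-only alternative would leave
  dispersion-mode residuals unconstrained.
- **Leakage penalty.** "Penalizing the area" of the model tail in the
  metabolite band is read as λ times the *mean magnitude* of `W` over the
  band — a scalar area surrogate. A mean-squared-magnitude variant is
  available (`penalty = "mean_sq_mag"`); both are exposed rather than
  silently chosen. Default λ = 1.
- **Amplitude penalty.** The `Σ A²` term damps spuriously large components.
  It is part of the published loss and stays on by default, but note that
  it *biases* fitted amplitudes: at the loss optimum a single-Lorentzian
  water peak is reproduced a few percent weak (stationarity balances the
  data-misfit gradient against `2A`). The weight is exposed as
  `amp_penalty_weight` so parameter-recovery oracles can run the pure
  least-squares fit; benchmarks keep the published loss.

**Optimization.** Rprop (the sign-based, per-parameter adaptive-step
variant implemented by mainstream autodiff frameworks: step × 1.2 on
consistent gradient sign, × 0.5 and a zeroed update on a flip, steps
clipped to [1e−6, 50]) with initial step = learning rate = 1. Gradients are
analytic: the loss gradient with respect to the spectrum is mapped to the
time domain by the adjoint (unnormalized inverse) DFT and then to the four
parameter blocks through the Lorentzian kernel; a finite-difference check
is part of the test suite. Three numerical choices matter:

1. **Frequencies are optimized in Hz.** In the model the frequency
   multiplies `t` in seconds, so Hz is its natural unit; an initial Rprop
   step of 1 is then ≈ 0.008 ppm. (Optimizing in ppm with step 1 would
   overshoot the entire 0.6-ppm clamp window on the first iteration and
   waste tens of iterations oscillating.) Components are reported in ppm.
2. **Clamps.** After every update the frequencies are projected onto
   [4.4, 5.0] ppm (widen `freq_clamp_ppm`/`water_band_ppm` together for
   pathological, broad water peaks, e.g. 4.4–5.4 ppm). Dampings are floored
   at 0 — a guard the published method does not need to state, but without
   which a transient negative damping produces an exploding exponential.
   Amplitudes are *not* clamped; a negative amplitude is folded into the
   phase when results are reported.
3. **Early stopping on the running minimum.** "Stop after 20 iterations if
   the improvement is below 0.1 %" is implemented as: stop once the best
   loss seen has improved by less than 0.1 % (relative) over the trailing
   20 iterations. Using raw trace values instead would falsely trigger on
   the non-monotone early phase of Rprop. `max_iterations = 500` guarantees
   termination.

Initial values: amplitudes 0, dampings 30 Hz, phases 0, frequencies
`[4.7, 4.75, 4.65, 4.80, 4.60, 4.85, 4.55]` ppm. Batches are processed
vectorized, but convergence is tracked per spectrum and converged spectra
are frozen, so batch results equal per-spectrum results exactly.

## HSVD comparator

The gold-standard role is played by a plain truncated-SVD state-space HSVD
(not a Lanczos-accelerated reimplementation — functional equivalence is
what the benchmark needs): a 512 × 512 Hankel matrix of the FID, the top 30
left singular vectors, a shift-invariance least-squares solve for the pole
matrix, its eigenvalues as signal poles `z = e^((−w + i2πf)/bw)`, and a
linear least-squares fit of complex amplitudes against the full FID.
Growing poles (|z| > 1, i.e. negative damping) are projected onto the unit
circle before the amplitude fit (configurable to `"drop"`), so reported
components always reproduce the returned water model. Components with
frequency in [4.4, 5.0) ppm are summed and subtracted.

## Metabolite quantification

The spectral model is a linear combination of metabolite basis FIDs under a
common damping/shift/phase factor plus a spline baseline:

```
S(ω) = FFT[ e^(−T2c⁻¹ t + i(2π ωc t + φc)) Σ_m A_m B_m(t) ] + S_b(ω) α
```

- **Basis.** Nine metabolites as Lorentzian line lists at literature
  chemical shifts (NAA 2.01; Cr 3.03/3.91; Cho 3.19; mI 3.52/3.61; Glu
  2.35/3.75; Gln 2.45/3.77; Lac 1.31; Asp 2.68/2.80; NAA 2.6), weights
  proportional to approximate proton ratios and normalized to
  `B_m(0) = 1`, so fitted amplitudes share the simulator's units. The same
  basis drives simulation and fitting, which makes the benchmark
  self-consistent — deliberately so, since the measured basis behind the
  original benchmark is not public.
- **Baseline.** 50 cubic B-splines on uniform knots spanning the whole ppm
  axis (partition of unity; each spline supported on four knot intervals
  ≈ 0.8 ppm). Coefficients are *complex* — one spline shape fitted
  independently to absorption and dispersion — because residual water has
  arbitrary phase and a real-only baseline could not absorb its
  dispersion-mode tail. The knot spacing (~0.19 ppm) absorbs 40-Hz-damped
  Lorentzian tails to >90 % over the region containing metabolite lines;
  absorption degrades within ~0.4 ppm of the water edge, where no
  metabolite line of this basis lies.
- **Initialization.** The loss surface is multimodal in the common shift
  (combs of narrow lines lock onto wrong alignments), so gradient descent
  alone is not reliable: the shift is first estimated by an exhaustive
  projection scan (±24 Hz in 0.75-Hz steps, picking the candidate whose
  modulated basis captures the most signal energy), then amplitudes and
  spline coefficients come from one linear least-squares solve at that
  shift (amplitudes clamped non-negative — a cheap stand-in for
  non-negative least squares), with phase 0 and damping 2 Hz. Rprop then
  refines all 112 real parameters jointly (9 amplitudes, 3 common
  parameters, 50 complex spline coefficients; initial step 0.02 — the warm
  start leaves only a short refinement). The fit is deterministic and its
  configuration is identical whichever remover produced the input — the
  property the paired benchmark depends on.
- **Error metric.** `100·|A′_m − A_m|/A′_m` with the absolute value taken:
  the printed formula has no bars, but tabulated means are positive, and
  signed agreement is reported separately through Bland–Altman statistics.

## The synthetic world

Each simulated record is metabolites + water + noise:

- **Metabolites.** Per-metabolite amplitude = base value (NAA 1.12,
  Cho 8.83, Cr 1.33, Gln 1.12, NAA₂.₆ 5.46, Lac 0.83, mI 1.71, Glu 0.43,
  Asp 5.93 a.u.) × U(0.1, 2). One common draw per spectrum of frequency
  shift U(−20, 20) Hz, damping U(1.5, 6) Hz and phase U(−π/4, π/4) rad
  (the stated "{−π/4, −π/4}°" range is read as symmetric radians — a typo
  reading; degrees that small would be invisible).
  *Why per-spectrum:* simulated linewidths are 0.5–2 Hz while per-metabolite
  shifts would displace lines by up to ±20 Hz — a common-shift fitting
  model then has essentially no overlap with the displaced lines and
  main-metabolite errors approach 100 %, an order of magnitude beyond the
  benchmark this package reproduces. Per-metabolite draws remain available
  (`per_metabolite = TRUE`) for stress testing.
- **Water.** Five Lorentzians at 4.7/4.78/4.62/4.85/4.55 ppm, base
  amplitudes {1, 0.33, 0.33, 0.11, 0.11}, damping 40 Hz, randomized as
  amplitude × U(10, 150), damping × U(0.3, 1.7), shift + 0.1·N(0,1) ppm,
  phase N(0, π) rad. Water therefore dwarfs the metabolites by one to two
  orders of magnitude, and occasionally drifts beyond the 4.4–5.0 ppm
  clamp — realistic misfit for WaterFit.
- **Noise.** Circular complex Gaussian in the time domain. SNR is defined
  as the peak magnitude of the noise-free *NAA* spectrum over the
  frequency-domain per-component noise SD, drawn from U(5, 50) per
  spectrum. NAA is the field's customary SNR anchor; referencing the
  global spectrum maximum instead (available as `snr_reference = "max"`)
  ties the noise floor to the largest tabulated amplitude (Cho, 8.83 a.u.)
  and yields quantification errors several times larger than the benchmark
  scale this package reproduces.
- **Dataset size.** The original benchmark size is unstated; the nominal
  default here is 1000 spectra, and the acceptance script runs 300 (the
  test suite 120) to stay desk-scale — pooled aggregates are stable at
  these sizes.

**What a green benchmark does and does not establish.** The synthetic world
shares the removers' model class: the water residual *is* a sum of
Lorentzians, metabolite lineshapes are ideal, there is no macromolecular
background, no B0-inhomogeneity lineshape distortion, no down-field
signals, and the fitting basis matches the simulation basis exactly. Green
tests therefore establish the *relative* claim — that fitting-based removal
quantifies as accurately as Hankel-SVD removal under identical conditions —
and the internal consistency of each algorithm; they do not establish
absolute in-vivo accuracy, and the absolute error level is smaller than the
published one because this basis has less multiplet crowding than a
measured basis.

## Benchmark conventions

All methods see identical simulated records (paired design). "Main
metabolites" are Cho, Cr and NAA (2.01 ppm); the pooled summary is the mean
and SD over all (spectrum × main metabolite) percentage errors — the
pooling is not defined by the source benchmark, so it is fixed here and the
per-metabolite table is reported alongside. Method comparisons use paired
t-tests on per-spectrum pooled errors. R² is the ordinary coefficient of
determination of fitted against ground-truth amplitudes. Wall-clock timings
are recorded in the report but are informational only — they depend on
BLAS/LAPACK builds and hardware and are never acceptance-graded.

## Known limitations

- No vendor raw formats; plain-text CSV/JSON exchange only (an HDF5 layout
  would be the natural container, but the package deliberately avoids
  binary dependencies).
- The HSVD comparator computes a full truncated SVD per spectrum (~0.3 s);
  a Lanczos backend would be the speed path and is out of scope.
- Quantification reports relative amplitudes only: no water-referenced
  absolute concentrations, no Cramér–Rao uncertainty bounds, no
  macromolecule basis.
- Frequency-domain closed-form Lorentzian evaluation (avoiding the FFT per
  iteration) is a known optimization left out to keep the model definition
  identical to the time-domain formulation.
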