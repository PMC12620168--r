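# watermrs

Residual water removal and metabolite quantification for proton magnetic
resonance spectroscopy (¹H-MRS).

## The problem

After acquisition-time water suppression (CHESS/VAPOR), MRS spectra of the
brain still carry a residual water signal around 4.7 ppm that is orders of
magnitude stronger than the metabolite resonances at 0.4–4.4 ppm. It must be
removed in post-processing before metabolite amplitudes (NAA, Cho, Cr, …)
can be quantified. The classical gold standard subtracts damped sinusoids
found by a Hankel-matrix singular value decomposition (HLSVD/HSVD), which is
accurate but expensive for modern multi-voxel acquisitions.

`watermrs` implements and benchmarks, end to end on synthetic data:

- **WaterFit** — models the water residual as a sum of seven Lorentzian
  components, `W(ω) = FFT[Σₘ Aₘ e^(−ωₘt) e^(i(2π fₘ t + φₘ))]`, fitted to
  each spectrum by resilient-propagation (Rprop) gradient descent of the
  penalized loss

  `L(W, S) = MSE(W, S)│₄.₄–₇.₀ ppm + λ · mean|W|│₀.₄–₄.₄ ppm + Σₘ Aₘ²`

  with component frequencies clamped to 4.4–5.0 ppm (λ = 1, learning
  rate 1, early stopping at <0.1 % improvement over 20 iterations).
  Gradients are analytic (chain rule through the Lorentzian kernel and the
  FFT adjoint); batches are fitted vectorized but each spectrum follows its
  own independent trajectory.
- **HSVD comparator** — a classical state-space Hankel-SVD decomposition
  (512 × 512 Hankel matrix, 30 singular values) that subtracts the
  components falling in the 4.4–5.0 ppm band.
- **Simulator** — nine-metabolite spectra (randomized amplitudes, common
  shift/damping/phase), a five-Lorentzian randomized water residual, and
  complex Gaussian noise at SNR ∈ U(5, 50).
- **Metabolite quantification** — a linear-combination model
  `S(ω) = FFT[e^(−T₂꜀⁻¹ t + i(2π ω꜀ t + φ꜀)) Σₘ Aₘ Bₘ(t)] + S_b(ω) α`
  with a 50-function cubic B-spline baseline, fitted by the same Rprop
  machinery, plus the percentage-error metric `100·|A′ₘ − Aₘ|/A′ₘ`.
- **Benchmark harness** — paired comparison of removal methods on identical
  simulated records: per-metabolite error tables, pooled main-metabolite
  (Cho, Cr, NAA) summaries, R², Bland–Altman agreement statistics.

## Worked example

```r
library(watermrs)

cfg <- sim_config(seed = 5)            # 1024 pts, 1199 Hz, 3 T, water at 4.7 ppm
rec <- simulate_dataset(cfg, 1)[[1]]   # metabolites + water residual + noise

fit <- fit_water(to_spectrum(rec$fid))
fit
#> <waterfit_result> 7 components, 209 iterations (converged), final loss 689.761
#>   amplitude damping_hz freq_ppm   phase
#> 1     8.546      27.09    4.684 -1.1691
#> 2     8.189      39.19    4.719 -1.2614
#> ...

basis <- metab_basis(cfg$metabolites, cfg$grid)
mf <- fit_metabolites(fit$cleaned_spectrum, basis,
                      truth = rec$truth_amplitudes)
round(mf$per_metabolite_error_pct, 2)
#>        NAA        Cho         Cr        Gln NAA_2.6ppm        Lac
#>       2.67       0.08       0.12       0.79       0.20       0.93
#>         mI        Glu        Asp
#>       0.95       1.61       0.11
```

The water fit reports the seven Lorentzian components it subtracted and its
loss trajectory; the metabolite fit reports amplitudes in the simulator's
ground-truth units, so the percentage errors above measure how much the
water-removal step distorted quantification (here ~1 % on the main
metabolites at this record's SNR).

A full paired benchmark:

```r
rep <- run_benchmark(sim_config(seed = 1), n = 300, methods = c("waterfit", "hsvd"))
rep
#> Main metabolites (Cho, Cr, NAA) pooled:
#>          mean    sd
#> waterfit 3.80 12.65
#> hsvd     3.82 13.32
#> R^2 (main metabolites):
#>             Cho     Cr    NAA
#> waterfit 0.9998 0.9799 0.9912
#> hsvd     0.9997 0.9785 0.9912
```

The two removal methods agree to ~0.02 percentage points on the pooled
main-metabolite error — the central claim reproduced here: the fast
fitting-based remover quantifies as accurately as the SVD gold standard.

## Command line

```sh
Rscript inst/cli/watermrs.R simulate --n 100 --seed 7 --out dataset.json
Rscript inst/cli/watermrs.R remove-water --in dataset.json --out cleaned/ --method waterfit
Rscript inst/cli/watermrs.R benchmark --n 100 --seed 7 --methods waterfit,hsvd --out report/
```

(After installation the script is also available under
`system.file("cli", "watermrs.R", package = "watermrs")`.)

## Limitations

- The metabolite basis is a documented set of Lorentzian line lists at
  literature chemical shifts, not a quantum-mechanical (density-matrix)
  simulation; macromolecule backgrounds and down-field metabolites are out
  of scope.
- Vendor raw formats (Siemens .rda, SDAT/SPAR, NIfTI-MRS) are not parsed;
  the package exchanges plain-text CSV/JSON containers.
- See `vignettes/watermrs-methods.Rmd` for the model assumptions, numerical
  choices, and what the synthetic benchmark does and does not establish.
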