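# bzdecon

Perfusion quantification from dynamic susceptibility contrast MRI
(DSC-MRI) by **Bezier curve deconvolution**: the tissue residue function
R(t) is parameterized as a cubic Bezier curve and fitted, together with
cerebral blood flow and optional bolus delay/dispersion parameters, by
maximum a posteriori estimation. The package is aimed at perfusion-MRI
methods researchers who need physiologically plausible residue functions
(R(0) = 1, non-negative, monotonically decreasing, bounded) instead of the
oscillatory solutions produced by SVD-based deconvolution.

## Model

The tissue concentration curve is modeled as

    C(t) = kappa * CBF * ( Ca(t - delta) (x) VTF(t) (x) R(t) )

where `Ca` is the arterial input function (AIF), `(x)` is causal
convolution, `delta` an arterial delay, and `VTF` a gamma-family vascular
transport function describing dispersion. R(t) is a cubic Bezier curve
with anchors P0 = (0, 1) and P3y = 0 and five free control-point
coordinates; a Gaussian-prior MAP objective with a smooth constraint
penalty enforces 0 <= Piy <= 1, 0 <= Pix <= P3x and monotone decrease.
Summary parameters follow tracer-kinetic theory: MTT is the area under
R(t), CBV the curve-area ratio, and MTT = CBV/CBF.

The package also provides:

* `osvd()` — block-circulant SVD deconvolution with oscillation-index
  regularization, the standard delay-insensitive reference method;
* a complete simulation framework (`sim_config()`, `simulate_dataset()`):
  gamma-variate AIF, gamma-family residue shapes (exponential / sigmoid /
  boxcar), exponential signal model with calibrated peak drops, Rician
  noise, sub-TR delays and exponential dispersion kernels;
* evaluation drivers (`run_table2()`, `run_delay_dispersion_study()`) for
  CBF-ratio, MTT-ratio and residue-RMSE benchmarking;
* voxelwise map fitting of 4D NIfTI volumes (`fit_volume()`) with
  large-vessel exclusion (`exclude_large_vessels()`), and a thin CLI
  (`inst/cli/bzdecon.R`).

## Worked example

Simulate a noiseless gray-matter voxel (CBF 60 ml/100 g/min, CBV 4%,
exponential residue, MTT 4 s) and deconvolve it both ways:

```r
library(bzdecon)
grid <- uniform_curve(numeric(162), dt = 1.24)      # 200 s at TR = 1.24 s
aif  <- gamma_variate_aif(grid)                      # bolus at t0 = 20 s
R    <- gamma_residue(lam = 1, mtt = 4, grid = grid) # exponential shape
ctc  <- forward_model(aif, R, cbf = 60 / 6000)       # internal unit ml/g/s

fit <- bzd(ctc, aif)
summary(fit)
#> Bezier deconvolution (variant: plain)
#>   CBF     59.64 ml/100 g/min
#>   CBV      4.65 %
#>   MTT      4.05 s
#>   fit RMSE 5.169e-05, objective -1183.8910, converged (4148 evals)

osvd(ctc, aif, osvd_settings(oi_threshold = 0.035))
#> block-circulant SVD deconvolution (oSVD)
#>   CBF: 60.0 ml/100 g/min   MTT: 4.03 s   delay: 0.00 s
#>   OI: 0.0008 (threshold 0.035, cutoff fraction 0.00)
```

CBF is recovered within 1% and MTT within 2%; the reported CBV of 4.65%
carries the documented `dt/(2*MTT)` rectangle-rule inflation of the
curve-area ratio (see the methods vignette). `plot(fit)` draws the fitted
residue function next to the observed and predicted tissue curves;
`coef()`, `predict()`, `residuals()` behave as for any fitted model.

Noisy studies run through the simulator, e.g. 64 replicates per CBF level
at baseline SNR 20:

```r
res <- run_table2(sim_config(snr = 20, lam = 1, cbv = 0.04, n_reps = 64))
res$summary   # pooled mean/sd/se of CBF ratio and residue RMSE per method
```

## Layout

* `R/`, `src/` — implementation (curve container, kinetics, Bezier
  machinery, MAP fitting, oSVD, simulator, evaluation, volume I/O).
* `tests/testthat/` — unit, property and benchmark-reproduction tests.
* `vignettes/bezier-deconvolution.Rmd` — the methods vignette: model,
  priors, optimizer design, simulator scope, numerical conventions and
  known limitations.
* `inst/cli/bzdecon.R` — command-line wrapper
  (`simulate | fit | osvd | evaluate | report`).
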