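# fcivim

Flow-compensated intravoxel incoherent motion (FC-IVIM) modelling for
diffusion-weighted MRI: forward simulation, constrained fitting,
simulation-driven acquisition design, and test–retest repeatability
statistics.

## The problem

Conventional IVIM describes perfused tissue as a bi-exponential decay,
which assumes blood traverses many capillary segments during the diffusion
encoding (the pseudo-diffusion limit). In abdominal organs the encoding
time *T* (40–100 ms) is comparable to the segment traversal time *τ*, the
limit does not hold, and the perfusion parameters become acquisition- and
flow-dependent. FC-IVIM resolves this by combining conventional bipolar
gradients (velocity-sensitive, β = 0) with flow-compensated gradients
(first moment nulled, β = 1) at several diffusion times and fitting

```
S(b,T,β) = S0 [ (1−f) e^{−bD} + f · F(b,T,β,τ,v) · e^{−b·Db(β)} ]
```

where the perfusion attenuation factor `F` is computed by Monte-Carlo
simulation of spin phases in randomly oriented straight vessel segments
(velocity magnitude *v*, direction redrawn every *τ* ms). The model spans
the ballistic regime (T/τ ≪ 1, where `F` is a sinc in the first gradient
moment for bipolar encoding and ≈1 for FC encoding) through the diffusive
regime (T/τ ≫ 1, `F → exp(−b·τv²/6)`, the classical pseudo-diffusion
`D* = τv²/6`).

The package is for MR physicists and image-analysis researchers who want
to (a) fit FC-IVIM to ROI-median signal decays, (b) design compact
acquisition protocols by greedy simulation-based selection of the most
informative (b, T, β) points, and (c) quantify test–retest precision
(within-subject CV, absolute-agreement ICC, protocol bias). A synthetic
multi-subject study generator makes the whole pipeline runnable with no
external data.

## Worked example

Simulate a liver-like acquisition with an optimized-style 50-point scheme,
fit it, and rescale the perfusion fraction to a shorter echo time:

```r
library(fcivim)

scheme <- opt50_synthetic_scheme()                    # 50 (b, T, beta) points
truth  <- tissue_params(D = 1.61e-3, f = 0.45, tau = 171, v = 8.4)
curve  <- forward_signal(scheme, truth)               # noiseless decay
noisy  <- withr::with_seed(7, add_rician(curve, snr_eff = 20))
fit    <- fcivim(noisy, bounds = organ_bounds("liver"))
print(fit)
#> FC-IVIM model fit
#>   D   = 1.686 x 10^-3 mm^2/s
#>   f   = 45.18 %
#>   tau = 199.6 ms
#>   v   = 6.955 mm/s
#>   S0  = 1.009 (normalized)
#>   residual norm 0.338 on 50 acquisitions; converged (15 iterations)
```

At SNR 20, `D` and `f` come back close to truth (1.69 vs 1.61 × 10⁻³
mm²/s; 45.2 vs 45.0 %), while the microvascular parameters `tau` and `v`
carry visibly more uncertainty (200 vs 171 ms; 7.0 vs 8.4 mm/s) — exactly
the precision ordering the repeatability statistics quantify. A measured
signal fraction depends on echo time because blood and tissue T2 differ;
rescaling the fitted `f` from TE = 122 ms to a typical TE = 50 ms:

```r
round(100 * t2_adjust_f(coef(fit)[["f"]], te_obs = 122, te_target = 50), 1)
#> [1] 20.4
```

Other entry points: `greedy_optimize()` (scheme design),
`evaluate_scheme()` (error percentiles vs SNR/f), `generate_study()` /
`fit_study()` / `repeatability_summary()` (synthetic repeatability
pipeline), and the `exec/fcivim` command-line tool with subcommands
`simulate`, `optimize`, `evaluate`, `fit`, `repeatability`,
`make-fixtures`.

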