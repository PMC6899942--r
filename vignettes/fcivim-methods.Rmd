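---
title: "Flow-compensated IVIM: model, fitting and acquisition design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flow-compensated IVIM: model, fitting and acquisition design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The signal model

Intravoxel incoherent motion (IVIM) imaging describes the diffusion-weighted
MRI signal of perfused tissue as a two-compartment sum: a tissue compartment
attenuating as $e^{-bD}$ and a microvascular compartment carrying a fraction
$f$ of the signal. Conventional IVIM assumes the pseudo-diffusion limit, in
which blood flowing through many randomly oriented capillary segments during
the encoding time mimics diffusion with pseudo-diffusion coefficient
$D^* = \tau v^2 / 6$. In abdominal organs that limit is often not reached:
the encoding time $T$ (40–100 ms on clinical gradient systems) is comparable
to the characteristic segment traversal time $\tau$, so the flow sits
between the *ballistic* regime ($T/\tau \ll 1$, flow looks like constant
velocity) and the *diffusive* regime ($T/\tau \gg 1$).

The flow-compensated (FC) IVIM model resolves the regimes by acquiring with
two gradient shapes — conventional bipolar encoding ($\beta = 0$, nonzero
first gradient moment, velocity-sensitive) and flow-compensated encoding
($\beta = 1$, first moment nulled, insensitive to constant-velocity motion)
— at several diffusion times. The forward model is

$$S(b, T, \beta) = S_0\left[(1-f)\,e^{-bD}
  + f\,F(b, T, \beta, \tau, v)\,
    e^{-b\,D_{b}(\beta)}\right],$$

where $F$ is the perfusion attenuation factor of the flowing compartment
and $D_b(\beta)$ the apparent diffusion coefficient of blood
($1.30\times10^{-3}$ and $1.54\times10^{-3}$ mm$^2$/s for bipolar and FC
encoding; the values are commonly printed in the literature without the
$10^{-3}$, which would extinguish the compartment at any practical $b$ —
`blood_adc()` makes them configurable). The five free parameters of a fit
are $S_0$ (nuisance), $D$ (mm$^2$/s), $f$ (fraction), $\tau$ (ms) and $v$
(mm/s).

## The phase model

$F$ is computed by Monte-Carlo simulation of spin phases. Each spin moves
at constant speed $v$ along straight vessel segments; at segment
boundaries, every $\tau$ milliseconds, its direction is redrawn uniformly
on the sphere, and the first boundary is offset uniformly in $[0, \tau)$.
Under effective gradient $G(t)$ with dephasing
$q(t) = \gamma \int_0^t G$, a spin accumulates

$$\phi = -v \sum_k \cos\theta_k \int_{\text{segment } k} q(t)\,dt,$$

and $F = \mathrm{E}[\cos\phi]$ (the imaginary part vanishes by symmetry and
is asserted small before being discarded). This covers both limits: a
single segment gives $F = \operatorname{sinc}(v\,|m_1|)$ for bipolar
encoding and $F \to 1$ for FC encoding, while many segments give
$F \to e^{-b \tau v^2/6}$ for both shapes. $F$ may be negative in the
near-ballistic bipolar regime (sinc lobes); it is passed to the signal
model unchanged. Note that with the uniform first-boundary offset a
fraction $T/\tau$ of spins crosses one boundary even deep in the ballistic
regime, so FC attenuation approaches 1 smoothly rather than identically.

Waveforms are ideal trapezoidal lobes filling $T$ with slew-limited ramps
(time step 10 µs): two opposite-sign lobes for bipolar encoding, and a
time-symmetric $+,-,-,+$ pattern for FC encoding, whose symmetry nulls the
first moment exactly. The b-value is always recomputed from the
discretized samples ($b = \int q^2 dt$), and `build_waveform()` solves the
plateau amplitude so the target b is met to 0.1%; `max_b()` gives the
hardware ceiling (FC shapes are 4x less b-efficient). Defaults correspond
to a 45 mT/m, 200 mT/m/ms gradient system with $T \in [40, 100]$ ms.

### Cached phase tables

Direct Monte-Carlo per model evaluation is far too slow inside fits, so the
package caches the *normalized phase distribution*: for each shape and each
of 64 logarithmically spaced nodes of $T/\tau \in [10^{-2}, 10^2]$, 102 400
spins are simulated once under the ideal rectangular-lobe waveform (unit
amplitude and duration), and the sorted phases are stored as 512 bin means
— a quantile representation of the distribution. Because the phase is
linear in the gradient amplitude and in $v$, the physical phase scale is
$s = v\sqrt{b\,T/\kappa_\beta}$ with the analytic shape constants
$\kappa_{\text{bipolar}} = 1/12$, $\kappa_{\text{FC}} = 1/48$, and

$$F(b, T, \beta, \tau, v) = \tfrac{1}{m}\sum_j \cos(s\,X_j),$$

with quantiles $X_j$ interpolated across $\log(T/\tau)$ by a Catmull–Rom
cubic. The table is built with a fixed internal seed, so it is a
deterministic object and fits are reproducible; it reproduces direct
Monte-Carlo attenuation within 1% over the supported grid (ramps are
neglected in the cached shape; ramp time is at most 0.6% of $T$ here).
Inside fits a coarser 64-bin aggregation of the same table is used; its
quadrature error (a fraction of a percent in the recovered parameters) is
invisible next to acquisition noise and buys a ~2x faster fit. Queries
outside the grid are clamped to its edge nodes.

## Fitting

`fcivim()` fits all five parameters simultaneously to the mixed
bipolar/FC curve by bound-constrained Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`, function tolerance $10^{-8}$, at most 500
evaluations). The curve is first normalized to the mean $b = 0$ signal.
$D$ and $f$ start from a mono-exponential fit to the bipolar data with
$b \ge 150$ s/mm$^2$ (slope and $1 - e^{\text{intercept}}$, clipped just
inside the bounds); the remaining starts are $S_0 = 1$, $\tau = 200$ ms,
$v = 4$ mm/s. When no two distinct high-b bipolar points exist, $D$ and
$f$ start at the bound midpoints. Two bound presets are shipped — the
tighter estimation set ($0.5\!-\!3.0\times10^{-3}$ mm$^2$/s, $f < 60\%$,
$\tau \in [20, 500]$ ms, $v \in [0.2, 15]$ mm/s) and a broad optimizer set
— plus per-organ constraints for liver, spleen and kidney. Ordinary
(non-Rician) least squares is used throughout, matching common practice
for direction-averaged magnitude data.

The $(\tau, v)$ likelihood valley is shallow where the data carry little
flow information, and single-start fits occasionally stop in a local
minimum for strongly perfused, fast-flow tissue. `fcivim()` therefore
accepts `extra_starts`; the study pipeline uses three spread-out
$(\tau, v)$ restarts and keeps the smallest residual. The optimizer path
deliberately uses single starts, mirroring how scheme costs are typically
simulated. In the deep diffusive corner ($\tau$ at its lower bound) only
the product $\tau v^2$ is identifiable; noiseless recovery tests therefore
draw truths away from that corner, and users should treat $\tau$ and $v$
estimates in low-$f$, short-$\tau$ tissue with caution (their
reliability is also what the repeatability statistics quantify).

## Acquisition design

`greedy_optimize()` grows an acquisition scheme one point at a time.
Starting from an identifiable base of five acquisitions (the model has
five parameters; the shipped `base_scheme()` spans $b = 0$ in both shapes,
a high-b bipolar anchor and mid-b FC points at both ends of the $T$ range
— a non-canonical but reasonable choice), each step simulates, for every
feasible candidate $(b, T, \beta)$, tissues drawn uniformly from typical
abdominal ranges ($D$ 1–2$\times10^{-3}$ mm$^2$/s, $f$ 10–40%, $\tau$
20–500 ms, $v$ 1–10 mm/s), adds Rician noise, refits with the broad
bounds, and scores the normalized percent errors
$\theta_{\text{err}} = 100(\theta_{\text{true}} -
\theta_{\text{fit}})/\theta_{\text{norm}}$ (norms: the range midpoints
$1.5\times10^{-3}$, 25%, 260 ms, 5.5 mm/s). The per-replicate
aggregation is $\sqrt{\frac{1}{4}\sum_\theta \theta_{\text{err}}^2}$,
averaged over replicates; a `mean_square` switch drops the radical, as
the two readings of the printed cost rank schemes near-identically. All
candidates within one step share identical tissue and noise draws
(tissues are drawn before the per-replicate noise, and candidate schemes
have equal acquisition counts, so the RNG streams align); draws are
refreshed between steps. Candidates may be selected repeatedly, which
becomes signal averaging.

Rician noise follows the magnitude model
$\sqrt{(S+\epsilon_1)^2 + \epsilon_2^2}$ per diffusion direction, averaged
over six directions. The quoted SNR is interpreted as *effective* — the
SNR of the direction-averaged $b=0$ signal — so the per-direction noise SD
is $\sqrt{6}/\mathrm{SNR}$; a `per_direction` switch is provided since the
phrase is ambiguous in parts of the literature.

Candidate grids are denser in $b$ below ~40 s/mm$^2$ (where flow-related
decay concentrates), coarser above, cap $b$ at 800 s/mm$^2$, and use a
finer $T$ grid for FC than for bipolar shapes (diffusion time matters
little for bipolar encoding). `evaluate_scheme()` re-simulates a scheme
with fresh draws and the tighter estimation bounds and reports 5/25/50/75/95
error percentiles, either over random tissue ranges (fixed norms) or at a
fixed truth (errors normalized by the truth itself).

### Problem sizes

The reference workflow in the field runs thousands of replicates over a
~180-candidate grid and dozens of added points — a multi-week computation.
This package's defaults and test runs are deliberately desk-scale: the
shipped tests exercise one greedy run with a 16-candidate grid, 15 added
points and 80 replicates per candidate (which already shows the expected
$\propto 1/\sqrt{N}$ decline of the cost trace), percentile evaluations
with 300–500 replicates, and 5-candidate oracle checks at 200 replicates.
Full-scale runs are a matter of configuration (`grid_config()`, `n_rep`),
not code.

## Repeatability statistics

The in-vivo-style analysis operates on ROI-median decay curves per
subject x organ x occasion:

* `drift_correct()` — ordinary least squares of the $b=0$ signal against
  acquisition time; if the slope differs from zero (two-sided t-test,
  $p < 0.05$), all signals are divided by $(a + b\,t)$. Gradient heating
  during long acquisitions is the physical motivation.
* `wcv()` — within-subject coefficient of variation; the default is the
  root-mean-square over subjects of the per-subject CV (the standard
  repeated-measures definition), with the pooled-SD-over-grand-mean
  variant available, since published wCVs rarely state the estimator.
* `icc_agreement()` — two-way (subject x occasion) absolute-agreement,
  average-measures ICC, $(MS_R - MS_E)/(MS_R + (MS_C - MS_E)/n)$, with
  subjects random and occasions fixed; values $\ge 0.75$ are flagged good,
  negative estimates are unreliable and flagged `n.a.`.
* `protocol_bias()` — mean normalized difference of a test protocol's
  estimates against a reference protocol assumed closest to truth.
* `t2_adjust_f()` — the measured signal fraction $f$ depends on echo time
  because tissue and blood T2 differ; the compartment odds $f/(1-f)$
  rescale by $\exp[(TE' - TE)(1/T_{2,\text{tissue}} -
  1/T_{2,\text{blood}})]$. With liver tissue T2 = 46 ms and venous blood
  T2 = 181 ms, an $f$ of 45.0% measured at TE = 122 ms corresponds to
  20.3% at a typical TE of 50 ms — the worked example the test suite and
  acceptance script recompute.

## The synthetic study generator

`generate_study()` emulates the data layout of a multi-subject abdominal
repeatability experiment: per subject and organ, true parameters are drawn
from truncated normals at published per-organ population means and SDs
(liver $D = 1.61\pm0.16\times10^{-3}$ mm$^2$/s, $f = 45.0\pm4.7\%$,
$\tau = 171\pm19$ ms, $v = 8.4\pm0.6$ mm/s; spleen and kidney analogous),
bounded by the organ fit constraints so truths stay identifiable. Each of
three occasions (two intrasession, one a week-later intersession) jitters
the parameters multiplicatively by a between-occasion CV — unknown in
vivo; the default 5% is a labelled assumption chosen so that biological
and fit-noise variability are of comparable size at SNR 20. Half of the
ROI series receive a linear signal drift with slope uniform in
$\pm2\times10^{-4}$/s (so the $p<0.05$ drift gate exercises both
branches); acquisitions are spaced 20 s apart, mimicking a ~17-minute
set. Rician noise is added per direction before averaging.

What the generator does *not* emulate: image-domain effects (motion,
registration residuals, partial volume), spatially varying noise,
inflow, T1/T2 relaxation differences across acquisitions (echo time is
held constant by design), or correlated drifts across organs. Passing
pipeline tests therefore demonstrate estimator and statistics
correctness under the stated noise model, not robustness to those
real-data effects.

## Numerical choices and degenerate inputs

* All internal formulas run in SI-consistent units (b in s/mm$^2$ with
  $10^6$ s/m$^2$ conversions, $\tau$ in seconds, $v$ in m/s); user-facing
  units are the field's (ms, mm/s, s/mm$^2$, mm$^2$/s).
* Waveform amplitude solving uses `uniroot` on the discretized b (b is
  monotone in amplitude); $b = 0$ yields an explicit null waveform and
  $F = 1$ exactly.
* Greedy ties (two candidates with equal cost) resolve to the first grid
  entry; grid order is deterministic.
* Fits that hit the iteration cap are reported via `converged = FALSE`
  and their bound-clipped estimates are kept (and counted) in simulation
  summaries — dropping them would bias error percentiles optimistically.
* Curves without a $b = 0$ point cannot be normalized and are rejected;
  drift testing needs at least three $b = 0$ timepoints, ICC at least
  3 subjects x 2 complete occasions (no imputation).
* The acceptance and test runs derive every seed from a single master
  seed; the phase table uses its own fixed seed so that changing the run
  seed never changes the model itself.

## Known limitations

* The cached table assumes the ideal-lobe shape; exotic hardware limits
  with ramp times a large fraction of $T$ would need a table built from
  the discretized waveform.
* Segment lengths are fixed at $l = v\tau$ per segment; distributed
  segment lengths (and hence a distribution of $T/\tau$) are not modelled.
* Single-voxel/ROI fitting only; no spatial regularization, no Bayesian or
  neural estimators.
* Eddy currents, concomitant fields and vendor pulse-sequence export are
  out of scope; the waveform module is a design aid, not a sequence
  programmer.
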