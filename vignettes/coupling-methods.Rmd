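---
title: "Cortico-striatal coupling analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cortico-striatal coupling analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photocouple)
```

This vignette is the package's own account of its methods: the signal model
behind each estimator, the parameters that matter, what the synthetic
generator does and does not emulate, and the numerical choices made where
the analysis was genuinely open.

## Signal model and preprocessing

Each region contributes two channels: a calcium-dependent signal and a
calcium-independent isosbestic reference that shares the region's
photobleaching drift and motion artifact. We model the raw signal channel as

$$F(t) = F_\mathrm{base}\,\bigl(1 + b(t) + m(t) + c(t) + \varepsilon(t)\bigr),$$

with $b$ the bleaching drift, $m$ the motion artifact, $c$ the calcium
component and $\varepsilon$ sensor noise; the isosbestic channel carries the
same $b$ and $m$ but no $c$. `isosbestic_correct()` estimates a scale and
offset by least squares between the low-pass-detrended signal and detrended
isosbestic traces, subtracts the scaled isosbestic from the raw signal, and
restores the signal's mean level exactly. Because drift and artifact are
common to both channels, this one regression removes both; the procedure is
a documented, swappable replacement for proprietary preprocessing in
commercial acquisition software, whose internals are not public.

Behavior-locked normalization is $\Delta F/F_0 = (F - F_0)/F_0$, where $F_0$
is the mean of the corrected trace over the behavior-specific baseline:
window $(-5, 5)$ s with baseline $(-4, -2)$ s for digging and licking,
window $(-1, 1)$ s with baseline $(-1, 0)$ s for turning. Windows are
realized as half-open sample ranges $[\mathrm{round}(t_0 f_s),
\mathrm{round}(t_1 f_s))$ with the onset snapped to the nearest sample, so
every trial at a given sampling rate has exactly the same length. $F_0 \le
0$ is a hard error: it indicates a corrupted baseline, and the trial is
excluded upstream with a logged reason rather than silently producing
nonsense.

The correlation path bandpasses at 0.001–3 Hz and then trims 1 s from each
end (digging/licking only). Two realization choices matter:

- **Filter realization.** A second-order Butterworth high-pass/low-pass
  cascade applied forward–backward (`signal::filtfilt`). Zero phase is
  essential: any phase distortion would bias the lag estimates that are the
  point of the analysis. The trace mean is removed before filtering. On a
  10 s trial a 0.001 Hz corner (period ~17 min) cannot remove a constant
  offset by itself, so demeaning makes the DC gain exactly zero at any
  trace length; for long traces the high-pass does the same job anyway.
- **Order of operations.** ΔF/F₀ first, then filter, then trim — filtering
  and trimming only approximately commute, so the order is fixed and tested
  for stability rather than left to chance.

## Coupling statistics

**Static correlation** is the Pearson r of the processed trial pair.
**Sliding correlation** advances a 4 s window in 0.5 s steps and keeps only
complete windows: a trace of $T$ seconds yields
$\lfloor (T-4)/0.5 \rfloor + 1$ values.

**Phase lag.** The cross-correlogram is
$c(\tau) = \mathrm{corr}\bigl(A(t),\, B(t-\tau)\bigr)$ computed per lag over
the overlapping samples (a per-lag Pearson normalization, keeping every
value in $[-1,1]$ and robust to short trials), and the phase lag is the
$\tau$ maximizing $|c(\tau)|$ over $\pm 2$ s. The sign convention — stated
here because conventions differ silently across toolboxes — is that
**positive lag means region B (striatum) precedes region A (cortex)**.
Values of $|c|$ within $10^{-12}$ of the maximum are treated as tied, and
ties resolve toward smaller $|\tau|$, then toward negative $\tau$; exact
ties essentially only arise on synthetic periodic inputs, but the rule makes
the estimator deterministic there too. Per subject, the phase lag is read
off the *trial-averaged* cross-correlogram rather than averaging per-trial
argmaxes: with a smooth transient the per-trial $|c|$ surface is broad, and
averaging the correlograms first suppresses the spurious peaks contributed
by trial-specific uncoupled activity.

**Amplitudes** are means over half-open intervals after onset (plateau
$[1,2)$ s for digging, peak $[0,0.5)$ s for licking).

**Sum-dFF activity** splits a free-moving recording into 8 s bins (the
trailing partial bin is dropped, keeping bins of equal length), normalizes
each bin with $F_0$ = its 20th percentile, and excludes bins whose
ΔF/F₀-vs-raw-F correlation falls below 0.8. Within a bin ΔF/F₀ is an affine
map of F, so this correlation is $+1$ whenever $F_0 > 0$ and $-1$ when an
artifact pushes $F_0$ negative — the QC rule therefore rejects exactly the
corrupted and degenerate (zero-variance) bins.

## Granger causality

Per trial: bandpass both signals; test each for a unit root with an
augmented Dickey–Fuller regression (constant, no trend; augmentation order
by AIC up to $12 (n/100)^{1/4}$; p-values by interpolation of the
constant-case Dickey–Fuller tau quantiles); difference both channels to the
*maximum* of their individually required orders so the bivariate model is
balanced; select the VAR order by BIC (AIC available) up to order 10
(0.25 s at 40 Hz); then compute, for each direction,

$$\mathrm{GC}(x \to y) = \ln\frac{\hat\sigma^2_{y\,|\,y_\mathrm{lags}}}{\hat\sigma^2_{y\,|\,y_\mathrm{lags},\,x_\mathrm{lags}}} \ \ge 0,$$

with significance from the nested-model F statistic with
$(p,\; n - 2p - 1)$ degrees of freedom. Group summaries average GC over
significant trials only (p < 0.05, per trial, no multiple-testing
correction — the per-trial filter is itself the reported procedure) and
report the fraction significant. Trials still non-stationary after two
differences are flagged unusable. Degenerate designs (one channel a copy of
the other) are stabilized by a minimal ridge during order selection and are
a hard, named error in the causality fit itself.

## Motion-energy GLM

Motion energy is the summed absolute frame-by-frame grayscale difference,
resampled to the photometry clock by linear interpolation (endpoints
clamped; interpolation is convex, so nonnegativity is preserved). To match
calcium-indicator dynamics the regressor is convolved with a "2.5 s
Gaussian kernel". The parameterization of that phrase is ambiguous; the
package reads it as a **full width of 2.5 s**, i.e. $\sigma = 2.5/6$ s
truncated at $\pm 3\sigma$ (the alternative $\sigma = 2.5$ s reading is
available via `parameterization = "sigma"`). The kernel is normalized to
unit sum, and edges use reflective padding to avoid onset transients in
10 s trials. The fit is OLS with intercept; β rescales inversely with
regressor gain while R² is invariant, so the units of the motion-energy
camera do not affect variance-explained comparisons.

## Behavioral rules

Digging trials require duration ≥ 3 s and a digging-free 10 s before onset;
"digging-free" is interpreted as *no digging event intersects the 10 s
pre-onset interval* — other behaviors are allowed there, since the
definition concerns contamination of the photometry baseline by the same
behavior. Turning requires ≥ 90°, ≥ 4 s since the previous turn, and no
temporal overlap with digging. Exclusions are logged with exactly one
primary reason, evaluated in the fixed order duration → baseline → overlap
(angle → spacing → overlap for turns). Boundary conventions: duration
exactly 3 s is included; an inter-lick gap of exactly 1 s splits a bout
(strictly-below keeps it); a lick exactly at cue time belongs to the
pre-cue period and does not count as initiation. Licks group into bouts as
maximal runs with gaps < 1 s; bout length is last minus first lick, so a
lone lick is a zero-length bout.

## The synthetic generator

`simulate_session()` emulates exactly the statistical structure the
estimators assume: a shared behavior-locked drive (event boxcars convolved
with a peak-normalized double-exponential kernel), a region-B drive that is
the region-A drive shifted by the inter-region lag and mixed with an
independent smooth process at weight $1-\text{shared fraction}$,
multiplicative bleaching, a motion artifact identical in a region's signal
and isosbestic channels, white sensor noise, and a motion-energy trace at
video rate driven by the same latent drive. All randomness flows from one
seed through named sub-streams, so identical parameters give bit-identical
sessions. Event onsets are drawn uniformly over the region of the onset
space satisfying the inclusion rules (a sorted-uniform slack allocation —
the same conditional law as naive rejection sampling, without its failure
rate), so every scheduled trial is analyzable by construction; a session
too short for the requested events fails loudly with the violated
constraint.

Default study conditions (chosen once, for realism and testability): 40 Hz,
320 s sessions with 12 digging events of 3.5–6 s; transient rise 0.15 s and
decay 0.8 s (fast-indicator kinetics — the narrower autocorrelation makes
the cross-correlation peak sharp enough for sample-level lag estimation);
amplitudes 0.30/0.25 ΔF/F₀; shared fraction 0.9; sensor noise 0.02 ΔF/F₀;
bleaching amplitude 0.15 with τ = 600 s; motion artifact SD 0.01 of
baseline. The "PFF-like" cohort template lowers the shared fraction to 0.5,
adds a +0.3 s inter-region lag and halves the striatal amplitude —
direction-of-effect analogues of a parkinsonian phenotype, sized so an
8-vs-8 cohort has decisive power. The raw-signal SNR and kinetics of real
recordings are not reported numerically anywhere we could anchor them, so
these values are testability choices, not fidelity claims.

What the generator deliberately does **not** emulate: spiking or
neurotransmitter dynamics, hemodynamic contamination, non-Gaussian sensor
noise, slow behavioral state drift, or video pixel noise. Passing recovery
tests therefore demonstrates the *estimators* are correct under the stated
model, not that the model captures everything in animal data.

`simulate_coupled_trials()` is a separate, minimal construction for
correlation-recovery tests: $a = z_1$, $b = \rho z_1 + \sqrt{1-\rho^2}
z_2$ with $z_1, z_2$ independent realizations of one low-passed Gaussian
process. Because both are filtered identically downstream, the population
correlation stays exactly $\rho$ at every pipeline stage; the realizations
are intentionally *not* standardized per trial, which would break that
exactness.

## Problem sizes and tolerances

The test suite and acceptance script use sizes chosen to give each
statistical check adequate resolution: 200-seed Monte-Carlo for noisy lag
recovery, 200 trials per correlation level (mean compared at 3× its
Monte-Carlo standard error), 500 seeds for the GC type-I rate, 200 runs for
direction recovery, 80 runs of $n = 5000$ for the analytic AR(1) limit
$\ln 1.25$, and 50 replicates of the 8-vs-8 cohort contrast plus 40
identical-cohort replicates for the test level. Exact claims (ΔF/F₀
arithmetic, gain invariance, oracle equivalence of the lag scan and the
nested-OLS Granger computation) are tested at $10^{-8}$–$10^{-12}$, the
residue of double-precision filtering rather than any statistical
tolerance.

## Known limitations

- The ADF p-value interpolation uses asymptotic constant-case quantiles;
  for very short trials (< 100 samples) the finite-sample tau distribution
  differs slightly. Differencing decisions near the 0.05 boundary can
  therefore flip; the `usable` flag records trials that never reached
  stationarity.
- The isosbestic regression assumes the artifact couples into signal and
  reference with a stable linear gain over the session; slow gain drift
  would leave a residual.
- Per-subject correlation aggregates as the mean of per-trial r by default;
  correlation of trial-averaged traces is a config option
  (`aggregate = "r_of_mean_trace"`), and the two answer different questions
  (consistency of single-trial coupling vs coupling of the mean response).
- Granger causality is bivariate only; common input from an unobserved
  third region can produce spurious directionality, which no amount of
  trial filtering detects.
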