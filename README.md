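# photocouple

Analysis pipeline for **dual-site fiber photometry**: quantifying how calcium
activity in primary motor cortex (M1) and dorsal striatum (STR) co-fluctuates
and coordinates in time while an animal performs naturalistic behaviors
(digging, licking, turning). The package turns two raw fluorescence channels
(470 nm signal + 405 nm isosbestic reference per region, sampled at 40 Hz)
into behavior-locked ΔF/F₀ trials and a set of coupling statistics, and ships
a synthetic-session generator with known ground truth so that every estimator
is testable by parameter recovery.

## What it computes

Given raw fluorescence F(t) and behavior onsets:

- **ΔF/F₀** = (F − F₀)/F₀, with F₀ the mean of F over a behavior-specific
  baseline: window (−5, 5) s with baseline (−4, −2) s for digging/licking;
  (−1, 1) s with baseline (−1, 0) s for turning. Bleaching and motion
  artifacts are removed beforehand by least-squares scaling of the isosbestic
  channel.
- **Static and sliding correlation**: Pearson r between the two regional
  ΔF/F₀ traces after 0.001–3 Hz zero-phase bandpass and 1 s edge trimming
  (digging/licking only); sliding variant uses a 4 s window advanced by
  0.5 s, incomplete windows excluded.
- **Phase lag** τ\* = argmax₍τ₎ |c(τ)|, the signed shift maximizing the
  absolute normalized cross-correlation; τ\* > 0 means the striatal (second)
  signal precedes the cortical one. Per subject, τ\* is read off the
  trial-averaged cross-correlogram.
- **Plateau / peak amplitude**: mean ΔF/F₀ over 1–2 s after digging onset or
  0–0.5 s after lick initiation.
- **Sum-dFF activity**: 8 s bins, per-bin F₀ = 20th percentile, bins with
  ΔF/F₀-vs-F correlation below 0.8 excluded, retained bins summed.
- **Granger causality** (time domain, in nats): per trial, both signals are
  bandpassed, differenced to joint stationarity (augmented Dickey–Fuller
  test), the VAR order is chosen by BIC, and
  GC(x→y) = ln(σ²_restricted / σ²_full) is computed from nested
  autoregressions with an F test; group summaries average significant trials
  (p < 0.05) only.
- **Motion-energy GLM**: motion energy (summed absolute frame differences)
  is resampled to 40 Hz, convolved with a 2.5 s Gaussian kernel, and ΔF/F₀
  is regressed on it (OLS), yielding a coupling coefficient β and R².
- **Behavioral rules**: digging trials need ≥ 3 s duration and ≥ 10 s
  digging-free baseline; turning trials need ≥ 90° and ≥ 4 s spacing without
  digging overlap; licks group into bouts at inter-lick intervals < 1 s.
- **Group statistics**: Mann–Whitney (unpaired) / Wilcoxon matched-pairs
  tests via `group_compare()`.

The synthetic module (`sim_params()`, `simulate_session()`,
`simulate_var_pair()`, `simulate_coupled_trials()`, ...) generates sessions
with configurable shared-drive fraction, inter-region lag, transient
kinetics, bleaching, a motion artifact common to signal and isosbestic
channels, and sensor noise — together with the ground-truth parameters, so
recovery is checkable end to end.

## Worked example

```r
library(photocouple)
library(dplyr)

b <- simulate_session(sim_params(seed = 7))   # one mouse, 12 digging trials
res <- run_pipeline(list(mouse1 = b), pipeline_config())

res$trials %>% select(trial, r, phase_lag_s, plateau_a, plateau_b, gc_ab, p_ab, glm_beta, glm_r2)
#> # A tibble: 12 x 9
#>   trial     r phase_lag_s plateau_a plateau_b  gc_ab     p_ab glm_beta glm_r2
#>   <int> <dbl>       <dbl>     <dbl>     <dbl>  <dbl>    <dbl>    <dbl>  <dbl>
#> 1     1 0.989       0         0.248     0.167 0.0458 0.0749      0.160  0.974
#> 2     2 0.989       0.125     0.245     0.181 0.0367 0.192       0.160  0.972
#> 3     3 0.989      -0.05      0.251     0.167 0.0898 0.000241    0.165  0.974
#> 4     4 0.990      -0.025     0.245     0.184 0.0879 0.000315    0.162  0.968
#> # i 8 more rows

res$subjects %>% select(subject, r, phase_lag_s, plateau_a, glm_r2)
#> # A tibble: 1 x 5
#>   subject     r phase_lag_s plateau_a glm_r2
#>   <chr>   <dbl>       <dbl>     <dbl>  <dbl>
#> 1 mouse1  0.989      -0.025     0.248  0.970
```

Each row is one included digging trial: `r` is the cortico-striatal
correlation of the bandpassed, trimmed ΔF/F₀ pair; `phase_lag_s` the optimal
alignment shift (here ≈ 0, matching the generator's zero inter-region lag);
`plateau_a`/`plateau_b` the 1–2 s post-onset amplitudes (ground truth ≈ 0.25
and 0.17 ΔF/F₀ for this parameter set); `gc_ab`/`p_ab` the M1→STR Granger
causality and its F-test p; `glm_beta`/`glm_r2` the motion-energy coupling.
The subject row aggregates trials (mean metrics; phase lag from the
trial-averaged cross-correlogram).

Directional causality on a known unidirectional system:

```r
v <- simulate_var_pair(a_xy = 0.5, a_yx = 0, order = 1, n = 2000, seed = 3)
granger_causality(v$x, v$y, order = 1)
#> Granger causality (order 1, d = 0/0, n_eff = 1999)
#>   A -> B: GC = 0.2124 nats (F = 472.40, p = 3.47e-94)
#>   B -> A: GC = 0.0012 nats (F = 2.34, p = 0.126)
```

The A→B value sits near the asymptotic ln(1.25) ≈ 0.223 for this
coefficient, and the reverse direction is correctly non-significant.

`tidy()`/`glance()` methods cover `gc_result` and `motion_glm` objects;
`autoplot()` displays cross-correlograms and GLM fits, and
`plot_peri_event()` / `plot_sliding_correlation()` the aligned traces and
time-resolved coupling.

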