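---
title: "Methods: the delay-current pipeline and its granule-cell simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the delay-current pipeline and its granule-cell simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kvdelay)
```

## The scientific problem

Dentate granule (DG) cells fire sparsely, and the timing of their first
action potential gates what reaches CA3. A subthreshold, slowly
inactivating, dendrotoxin (DTX)-sensitive K⁺ current — the delay current,
I_D, carried by Kv1-family channels — postpones that first spike. In
kainate models of temporal-lobe epilepsy the current is strongly
upregulated through Kv1.1 transcription, and response delays lengthen in
proportion to the transcript amount in the same cell. `kvdelay`
implements each quantitative step of that argument: current-clamp feature
extraction, subtraction pharmacology and gating analysis in voltage
clamp, CT-level qPCR quantification, densitometry, and the statistics
linking them — all exercised against a conductance-based simulator with
known ground truth.

## The simulator

The model is a single electrical compartment:

$$C_m \frac{dV}{dt} = -\big[ I_L + I_{Na} + I_{Kdr} + I_{Kir} + I_D \big] + I_{inj} + \xi$$

with $I_D = g_D\, a\, b\, (V - E_K)$. The two delay-current gates follow
first-order kinetics toward Boltzmann steady states with positive slope
factors,

$$a_\infty(V) = \frac{1}{1 + e^{(V_{50}^{act} - V)/k_{act}}}, \qquad
  b_\infty(V) = \frac{1}{1 + e^{(V - V_{50}^{inact})/k_{inact}}},$$

activation increasing and inactivation decreasing with voltage. The
spike machinery (transient Na with instantaneous activation m³ and a
first-order h gate; delayed rectifier n⁴; instantaneously rectifying
Kir) is deliberately generic: no kinetic measurements exist for these
conductances in the data the package models, so they are standard
Hodgkin–Huxley-style forms whose only job is to produce overshooting
APs, a realistic rheobase, and repolarization. They are *not* claims
about DG-cell Na/K channel kinetics.

### Preset parameterization

Two presets encode the measured group phenotypes:

| parameter | naive | KA | origin |
|---|---|---|---|
| V50 activation (mV) | −32.3 | −46.0 | measured group means |
| slope activation (mV) | 17.1 | 17.0 | measured |
| V50 inactivation (mV) | −41.7 | −43.8 | measured |
| slope inactivation (mV) | 14.1 | 13.7 | measured |
| τ inactivation (ms) | 250 | 378 | measured |
| E_K (mV) | −104.3 | −104.3 | Nernst of the solutions |
| g_D (nS) | 0.18 | 2.06 | back-computed from peak I_D and C_m |
| C_m (pF) | 88 | 88 | back-computed from the reported amplitude/density pair (14.9 pA ↔ 0.17 pA/pF) |
| g_L, g_Kir (nS) | tuned | tuned | to rest ≈ −82/−84 mV and R_in ≈ 600/450 MΩ |

The passive conductances were tuned once, numerically, so that each
preset's resting potential and steady-state input resistance match the
measured group values; the tuning script solves for `(g_L, g_Kir)` by
root-finding on the steady-state I–V relation. The activation time
constant of the delay conductance is not experimentally constrained; the
package default is **2 ms**, fast relative to inactivation and within
the range reported for Kv1-family channels. This choice matters: with a
slower activation gate (say 5 ms) the family peak falls late enough that
inactivation decay biases the fitted activation midpoint by more than
1 mV, i.e. the analysis pipeline could no longer recover the programmed
gating parameters at the accuracy the rest of the package guarantees.
`tau_ms` is exposed in `sim_cell_params()` for users who want to explore
that trade-off.

### Integration

Current clamp uses a fixed-step scheme (default dt = 25 µs, upper bound
50 µs): exponential-Euler updates for the gates (exact for their locally
constant-coefficient kinetics) and an explicit update for V, implemented
in C++. Stability requires dt < 2·C_m/g_max ≈ 0.26 ms, comfortably met.
Halving dt changes measured features by well under 0.5% (tested).
Voltage clamp is ideal (no series-resistance error): within each
constant-voltage segment the gates relax analytically, so the simulated
current family is exact at any sampling interval; noise, when requested,
is white per-sample current noise. Non-finite state during integration
aborts with the offending step index.

### What the generators emulate — and what they do not

- The current-clamp generator reproduces the *structure* of the
  phenomenon (delays strictly increasing in g_D, decreasing in input
  strength, collapsing under the simulated blocker; I/O curves shifted
  by the blocker) but compresses its *scale*: simulated delays span tens
  of milliseconds, not the hundreds of milliseconds of real DG cells,
  because a point neuron with first-order gates lacks the slow
  subthreshold dynamics (dendrites, Kv1 axonal gradients, channel
  populations with dispersed kinetics) that stretch real delays. Tests
  passing on the simulator therefore validate the *measurement chain*,
  not the biophysical completeness of the model.
- The CT generator programs group differences in cycles
  (CT = baseline − log2-fold·[case] + latent + noise, censored at the
  detection ceiling, default 45 cycles). Real single-cell RT-qPCR has
  heavier-tailed noise and efficiency drift that the lognormal-like
  model omits.
- The image generator produces a uniform background with one banded
  region (the middle-molecular-layer band) plus Gaussian noise — enough
  to validate ROI densitometry and line profiles, nothing more.

## Analysis conventions and numerical choices

- **AP threshold slope**: the criterion is a dV/dt crossing; the default
  is 20 mV/ms. The prescription as reported (20 mV/s) is crossed by ordinary
  passive charging and would put "threshold" at stimulus onset; it is
  almost certainly a unit slip, but remains available
  (`slope_thresh = 0.02`).
- **AP peaks**: local maxima above 0 mV (overshoot criterion) with a
  2 ms refractory lockout; widths are interpolated at −5 mV.
- **Rheobase**: ascending 1 s steps, default grid 0–400 pA in 5 pA
  increments; censored (flagged, never a sentinel value) when the grid
  maximum stays silent. Censored delays never enter group means.
- **Input resistance**: steady state is the final 20% of the step;
  qualifying sweeps must stay within ±10 mV of rest and contain no APs.
- **Subtraction and peaks**: the first 5 ms after each voltage step are
  blanked (capacitive artifact window); the subtracted trace is lightly
  boxcar-smoothed (default 2 ms, mirroring the low-pass filtering of
  acquired currents) before its signed extremum is taken. For noisy
  *families*, `family_peaks()` measures all steps isochronally at the
  family peak time: the per-trace extremum of a near-zero trace over
  thousands of samples is biased away from zero by ~sd·√(2 ln N), which
  otherwise distorts the foot of the activation curve.
- **Boltzmann fits**: Levenberg–Marquardt least squares with a fixed
  grid of five jittered starts (midpoint from the half-maximum point,
  slope 15 mV); bounds keep k ∈ [0.5, 60] mV.
- **Reversal potential**: linear fit on the hyperpolarized limb (−110 to
  −50 mV) by default, to avoid activation curvature; the full range is a
  parameter. Two-point fits are accepted (exact line), but the
  delta-method standard error and the wide-CI flag need ≥3 points.
- **Driving force**: conductance conversion uses the fitted reversal
  when available, else the Nernst potential of the recording solutions
  (155 mM K⁺ pipette / 2.5 mM ACSF, 293.15 K → −104.3 mV; sensitivity
  ≈ 0.36 mV/K, about 1 mV across a 22–25 °C room-temperature range).
- **qPCR efficiency**: reported as E = 10^(−1/slope) − 1 so that perfect
  doubling gives 1.0 — the only reading consistent with the conventional
  0.9–1.05 acceptance band; the raw amplification factor (2.0 at perfect
  doubling) is returned alongside.
- **Fold changes**: computed on group-mean CTs (this reproduces the
  reported pearl-level arithmetic, 2^(35.9−33.3) = 6.06); at levels
  without a reference gene the absolute-CT convention (`dct_only`) is
  used. Censored CTs are excluded from means, not imputed.
- **Phenotype–expression correlation**: Pearson r of delay against −CT,
  so positive r means longer delays with more transcript; significance
  via the t transform (identical to the tabulated r-value approach).
- **Two-group statistics**: Shapiro–Wilk gate at α = 0.05 per group,
  then Student's t or Mann–Whitney (paired variants supported). No
  multiple-testing correction is applied, matching the original analysis
  style; `run_study()` reports every test it ran.
- **Paired-pulse ratio**: measured on the stimulation waveform with
  local pre-pulse baseline subtraction; at 100 Hz the decay of one pulse
  overlaps the next, and without the subtraction the last/first ratio is
  inflated by roughly 10%.

## Problem sizes

The shipped tests and the acceptance script use desk-scale sizes chosen
to make sampling error small relative to each tolerance: 100 seeded
replicates for gating-parameter recovery at SNR 20 (2.5 s families at
5 kHz), 5 replicates of 200 cells/group for fold recovery, 1000
replicates for the null false-positive rate of the correlation, and 2000
replicates for the type-I calibration of the two-group gate (binomial
99% half-width ≈ 0.013 at α = 0.05).

## Known limitations

- Point-neuron simulator: no morphology, synaptic plasticity, stochastic
  channel gating, or network context; delay magnitudes are compressed
  (see above).
- Ideal voltage clamp: series-resistance and space-clamp errors are out
  of scope, so the recovery guarantees do not cover those error modes.
- The activation-midpoint estimate retains a small (≈0.5 mV) systematic
  bias from inactivation during the rise to peak — inherent to peak-based
  activation analysis of an inactivating current, and shared with the
  experimental procedure it reproduces.
- qPCR quantification assumes one reference gene (GAPDH) and perfect
  doubling unless an efficiency is supplied; no amplification-curve
  processing.
- Imaging supports single-channel arrays only; RGB extraction happens at
  the I/O boundary, and no background subtraction is applied by default.
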