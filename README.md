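# kvdelay

Analysis toolkit for the **delay current (I_D)** of hippocampal dentate
granule (DG) cells: a slowly inactivating, subthreshold,
dendrotoxin (DTX)-sensitive K⁺ current carried by Kv1-family channels that
postpones the first action potential. Under epileptic hyperexcitation
(kainate models of temporal-lobe epilepsy) DG cells scale this current up
via Kv1.1 transcription, lengthening their response delays. `kvdelay`
implements the full quantitative chain needed to study this phenomenon —
from raw patch-clamp sweeps through channel biophysics to single-cell
RT-qPCR and the statistics tying phenotype to expression — together with a
conductance-based granule-cell simulator so that every stage can be
validated on synthetic data with known ground truth.

It is intended for cellular electrophysiologists and quantitative
neuroscientists who want reproducible, scriptable versions of analyses
that are usually performed interactively in acquisition software.

## What is computed

**Current-clamp phenotype** (module `ccfeat`): resting potential; input
resistance as the slope of the steady-state I–V relation within ±10 mV;
membrane time constant (double-exponential fit, slow component);
capacitance C_m = τ_m/R₀; AP detection with threshold (voltage-slope
criterion), width at −5 mV, rheobase (minimum current for ≥1 AP within
1 s), response delay (step onset to first AP peak, 2 s window, censored
when absent), first-spike jitter (SD and CV), somatic and synaptic
input/output curves.

**Voltage-clamp biophysics** (module `vcfeat`): pharmacological
subtraction isolates I_D; peak currents are converted to conductance
G = I/(V − V_rev) and fitted with the Boltzmann

    G/G_max = 1 / (1 + exp((V50 − V)/k))        (activation, k > 0)
    I/I_max = 1 / (1 + exp((V − V50)/k))        (inactivation)

plus a mono-exponential inactivation time constant, a linear-fit reversal
potential, and the Nernst reference E_K = (RT/F)·ln([K]out/[K]in).

**Expression** (module `qpcr`): melt-curve/primer-dimer/GAPDH quality
filtering, primer efficiency from dilution series (E = 10^(−1/slope) − 1),
ΔΔCT fold changes, abundance ranking by mean CT, z-score co-expression,
and Pearson correlation of response delay against Kv1.1 CT.

**Imaging** (module `imaging`): ROI signal densities, hilus-to-fissure
line profiles and condition comparisons for immunolabel / propidium-iodide
quantification.

**Statistics** (module `stats_report`): the Shapiro–Wilk-gated two-group
decision tree (t test vs Mann–Whitney, paired variants), extra-sum-of-squares
F tests for curve comparison, Pearson r significance brackets, and
`run_study()`, which simulates an entire naive-vs-KA cohort end to end.

**Simulator** (module `dgsim`): a single-compartment model
C_m·dV/dt = −ΣI_ion + I_inj with Na, delayed-rectifier, inward-rectifier,
leak, and the delay conductance I_D = g_D·a·b·(V − E_K); presets `"naive"`
and `"KA"` carry the measured gating parameters and current densities.
Generators for qPCR CT tables, synaptic trains and banded section images
complete the synthetic study.

## Worked example

```r
library(kvdelay)

p_naive <- granule_preset("naive")
p_ka    <- granule_preset("KA")
proto   <- step_protocol(90, onset = 0.1, duration = 2)   # 90 pA, 2 s

d_naive <- measure_delay(simulate_current_clamp(p_naive, proto, T = 2.2), proto)
d_ka    <- measure_delay(simulate_current_clamp(p_ka,    proto, T = 2.2), proto)
d_dtx   <- measure_delay(simulate_current_clamp(apply_drug(p_ka, "DTX", 1),
                                                proto, T = 2.2), proto)
cat(sprintf("delay naive %.1f ms | KA %.1f ms | KA+DTX %.1f ms\n",
            d_naive$delay, d_ka$delay, d_dtx$delay))
#> delay naive 38.5 ms | KA 51.7 ms | KA+DTX 37.5 ms

ddct_fold(c(35.9, 33.3), c("naive", "KA"), case = "KA", control = "naive")$fold
#> [1] 6.062866
nernst(K_in = 155, K_out = 2.5, temperature = 293.15)
#> [1] -104.2585

rep <- run_study(list(seed = 1, n_per_group = 12))
#> cohort: delay test mann_whitney p=3.6e-05 | Kv1.1 fold 8.9 |
#>         delay~expression r=0.53 (n=24, p=0.0074)
```

The KA-like cell responds later than the naive cell at the same input, the
simulated blocker abolishes the difference, the pearl-level CT means give
the 6.1-fold Kv1.1 increase, and a synthetic cohort reproduces the
signature finding: response delay correlates with Kv1.1 transcript
abundance at the single-cell level. (The simulator's delays span tens of
milliseconds rather than the hundreds observed in real DG cells; see the
methods vignette for what the synthetic cohorts do and do not emulate.)

## Package layout

- `R/trace_io.R` — sweep/protocol containers, directory round-tripping, recording QC
- `R/dgsim.R` — granule-cell model, presets, voltage clamp, CT/train/image generators
- `src/sim_cc.cpp` — fixed-step current-clamp integrator
- `R/ccfeat.R`, `R/vcfeat.R`, `R/qpcr.R`, `R/imaging.R`, `R/stats_report.R` — the analyses
- `vignettes/kvdelay-methods.Rmd` — model, assumptions, numerical choices
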