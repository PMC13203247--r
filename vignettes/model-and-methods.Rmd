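---
title: "The closed-loop force-control model and its outcome pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The closed-loop force-control model and its outcome pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bimanforce)
```

## The task being modeled

A participant squeezes two hand-grip dynamometers and tries to hold the
summed force at a fixed target (90 N, i.e. 45 N per hand) for 40 s. For the
first 20 s the produced force is displayed on a screen; at 20 s the display
is removed and the participant must hold the force using proprioception
alone. The empirical signature of this transition is a slow, systematic
*undershoot*: without visual reinforcement the remembered target drifts
downward, and the produced force follows it. Analysis windows of 17 s each —
`[3, 20)` s for the visual epoch and `[23, 40)` s for the proprioceptive
epoch — exclude the initial force ramp and the 3 s transition after the
display disappears.

## Model structure and assumptions

`simulate_trial()` integrates one difference equation per hand at 100 Hz.
Three assumptions shape the design:

* **Per-step gains.** The visual gain `k_vis` and the proprioceptive
  correction gain `g_proprio * k_base` multiply the error once per 10 ms
  step; they are dimensionless per-step quantities, not rates. The drift
  rate `lambda_drift` is, in contrast, a true rate (1/s) applied as
  `lambda_drift * dt` per step. Mixing the two conventions is deliberate:
  it keeps the feedback gains in the form in which they are usually
  reported for discrete controllers while making the drift independent of
  the step size.
* **Internal target decay.** From the moment vision is removed the
  internal target decays multiplicatively,
  `T_int <- T_int * (1 - lambda_drift * dt)`, starting from the displayed
  target. Because `lambda_drift = drift_coeff * (1 - 0.5 * g_proprio)`, a
  higher proprioceptive gain slows the decay. This is the mechanism behind
  the undershoot dose–response.
* **Delayed proprioceptive estimate.** The correction during the
  proprioceptive epoch compares `T_int` against the force produced 100 ms
  (10 samples) earlier, plus measurement noise. Force history from the
  visual epoch is available at the switch, so no special-casing is needed
  at onset. During the visual epoch the error uses the *current* force —
  visual feedback is treated as effectively instantaneous at this
  timescale.

Noise enters in four places: motor execution noise per hand per step
(SD 0.22 N with vision, 0.25 N without), proprioceptive measurement noise
(SD 0.15 N), a *common drive* shared by both hands (white noise low-pass
filtered at 2 Hz, weighted by 0.15), and a small sinusoidal tremor
(10–10.2 Hz, independent frequency and phase per hand). Motor and
proprioceptive noises are independent across hands; only the common drive
is shared, which is what creates inter-hand coherence concentrated below
2 Hz while leaving the tremor band incoherent.

Between-trial variability — the reason replicate simulated trials spread
like replicate human trials — comes from two per-trial draws:
`lambda_drift ~ N(base, 0.0008)` and the correction gain
`~ N(g_proprio * k_base, 0.008)`, both truncated at zero (clamped; with the
default means the truncation is a > 4 SD event and practically never
binds). The correction gain is drawn once per trial, not per step.

### Parameters the model does not pin down

Three amplitudes are not constrained by the phenomena the model targets and
had to be fixed by judgment; all are `model_params()` fields and can be
changed:

* `tremor_amplitude = 0.05` N — small enough that tremor contributes
  negligibly to 1–3 Hz power and produces no coherence peak at 7–12 Hz,
  matching the physiological observation that inter-hand coherence shows no
  tremor-band peak.
* `common_drive_sd = 1.0` N (pre-filter) with a 2nd-order Butterworth
  low-pass, forward-only, recentred to zero mean — enough shared
  low-frequency input that the 0–1 Hz coherence band dominates, as observed.
  The filter order is a choice; only the cutoff (2 Hz) is physiologically
  motivated.
* Proprioceptive noise is independent across hands. Sharing it would
  inflate low-band coherence through a second route; independence keeps the
  common drive as the single coherence mechanism.

Because absolute 1–3 Hz band power scales with these unspecified
amplitudes, the package treats only *relative* band-power claims as
meaningful: the ratio between gains and the monotone rise across the gain
grid, both of which are insensitive to the overall noise scale.

## The outcome pipeline

All scalar outcomes are computed from the summed force; coherence uses the
two per-hand channels. Choices worth knowing:

* **Zero-phase filtering.** The 15 Hz 4th-order Butterworth is applied
  forward and backward (two passes, squared magnitude response) with
  odd-reflection edge padding, so filtered force is not delayed relative to
  the target and a constant input passes through exactly.
* **Per-segment constant detrend in Welch.** The summed force sits near
  90 N; without removing each segment's mean, DC leakage through the Hann
  window would swamp the 1–3 Hz band. The same detrend is applied to
  simulated and measured data, and to both PSD and coherence estimates.
* **Half-open conventions.** Frequency bands take bins with center
  frequency in `[lo, hi)`, so the shared 1 Hz and 3 Hz edges are never
  counted twice and band powers over a partition sum exactly to the total.
  Time windows are half-open too, `[start, end)`, mapped to samples
  `floor(start*fs) .. floor(end*fs) - 1`; the standard 17 s window holds
  exactly 1700 samples at 100 Hz, giving 2 Welch segments at 1024 samples /
  50% overlap (resolution 100/1024 ≈ 0.098 Hz) and 5 coherence segments at
  512.
* **Coherence needs ≥ 2 segments**; with one segment the magnitude-squared
  estimator is identically 1, so that case errors rather than returning a
  misleading value. With the standard 5 segments, independent channels
  still show a positive small-sample bias (mean MSC ≈ 0.2, not 0) — a
  property of the estimator that the reliability of coherence outcomes
  inherits.

## Simulation experiments

`dose_response_sweep()` uses the grid {0.20, 0.25, 0.30, 0.40, 0.50, 0.60,
0.70, 0.80} by default — covering the nominal gain range with both modeled
conditions included — with 20 trials per point. Seed streams are keyed by
`(master_seed, gain value, trial index)`, so reordering the grid or adding
points never changes existing results, and condition comparisons with equal
gains are *exactly* null (they share a stream). Summaries report sample SDs
(n − 1); a single-trial summary flags its SD as `NA` rather than 0.

With defaults the sweep shows the two concurrent dose–response effects:
undershoot falls from ≈ 4.8% at gain 0.20 to ≈ 3.0% at 0.80 (≈ 4.2% at the
sham gain 0.25 and ≈ 3.3% at the stimulation gain 0.70, with across-trial
SD ≈ 0.9 pp), while 1–3 Hz corrective power rises by a factor of ≈ 2.3
between the two condition gains. In the noise-free limit the undershoot
equals the time average of the decaying internal target over the analysis
window,

```
undershoot(lambda) = 100 * (1 - (exp(-3*lambda) - exp(-20*lambda)) / (17*lambda))
```

up to a small tracking-lag correction of order
`100 * lambda * (dt/gain - delay)` (≈ 0.07 pp at the sham gain): the force
trails the falling target and therefore sits slightly *above* it. The test
suite holds the simulator to this closed form within 0.1 pp at every grid
point.

### What the epoch contrast does and does not reproduce

Removing vision degrades accuracy in the model as in experiments: RMSE over
the proprioceptive window always exceeds the visual window. But the
*composition* differs from measured data. In the model the proprioceptive
RMSE is dominated by the drift bias (≈ 4% of 90 N ≈ 3.8 N) while the visual
epoch is unbiased with ≈ 0.8 N of fluctuation, so the OFF/ON RMSE ratio is
large (≈ 5) and the fluctuation-SD ratio ≈ 3 — a sharper contrast than the
modest experimental ON-to-OFF increase. `vision_on_off_contrast()` reports
both ratios so the discrepancy is visible rather than hidden; tests assert
only the direction (OFF worse than ON), which is the claim the model is
entitled to. Relatedly, the model's visual-epoch RMSE floor sits below
typical measured values, one reason why fitting the model to individual
participants is out of scope.

## Statistical battery

`build_report()` mirrors a pre/post two-group analysis on a long-format
table (`id`, `group`, `metric`, `pre`, `post`):

* Within-group paired t tests, two-sided, with Cohen's d computed from
  difference scores (POST − PRE, so improvements in undershoot/RMSE are
  negative).
* The group × epoch interaction as a pooled-variance independent t test on
  change scores, reported as `F = t²` with `df = (1, n_a + n_b − 2)`.
* Holm correction applied within each group across the three *primary*
  metrics (undershoot, RMSE, 1–3 Hz power); coherence bands are reported
  unadjusted. The family definition is a reporting decision, switchable via
  `primary_metrics()`.
* Test–retest reliability as ICC(2,1) — two-way random effects, absolute
  agreement, single measure — from the sham group's PRE/POST pairs,
  computed from closed-form balanced two-way mean squares. Other ICC
  variants answer different questions (consistency ICC(3,1) ignores
  session-level shifts); ICC(2,1) is the stricter choice for test–retest
  agreement.
* Baseline-adjusted ANCOVA: OLS of POST on group + PRE, guarding the group
  comparison against baseline imbalance.
* Pearson correlations between the 1–3 Hz power change scores and the
  undershoot/RMSE change scores, overall and per group.

Under null simulation (both groups drawn from identical parameters) the
paired tests reject at the nominal 5% rate within binomial tolerance — the
acceptance suite verifies this on 200 replicate 12 + 12 tables, sized to
match the study design while keeping the run in the low minutes on one CPU.

## What the synthetic data do not show

The simulator generates what the model says the world is like: stationary
Gaussian noise, a single shared drive, a fixed delay, one drifting scalar
target. Real grip-force data contain slow fatigue trends, non-Gaussian
excursions, individual differences in noise level and tremor amplitude, and
possibly vision-dependent changes in bilateral coupling — none of which are
emulated. Tests passing on simulated data therefore validate the
*pipeline* (that the metrics, experiments and statistics compute what they
claim) and the *model's internal consistency* (that its printed
dose–response numbers follow from its equations), not the model's fidelity
to any individual participant. Reanalysis of deposited experimental
recordings goes through `read_force_recording()` and the `stats` command
unchanged.

## Numerical notes

* Problem sizes: a trial is 4000 steps; the default experiments simulate
  20 trials per condition or grid point; the reproducibility script uses
  200 replicate trials per reported mean. One trial simulates in a few
  milliseconds in plain R with pre-generated noise vectors.
* Determinism: `(params, seed)` fully determine a trial; draws occur in a
  fixed documented order (trial realization, common drive, motor noise L/R,
  proprioceptive noise L/R).
* Degenerate inputs error loudly rather than guessing: delays off the
  sample grid, windows beyond the recording, cutoffs at or above Nyquist,
  empty frequency bands, single-segment coherence, zero-variance
  statistical inputs.
* Forces are not clamped at zero: trajectories live near 45 N per hand and
  default noise cannot reach the floor; clamping would only mask
  misconfigured parameter sets.
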