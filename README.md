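# bimanforce

Closed-loop simulation and analysis of bimanual isometric force control.

`bimanforce` is for researchers in sensorimotor control who study how people
hold a steady grip force with both hands when visual feedback of the force is
taken away and control must rely on proprioception. It bundles three things:

1. **A closed-loop force-control simulator.** Each hand h ∈ {L, R} produces
   force at 100 Hz over a 40 s trial. While visual feedback is on
   (t < 20 s):

   F_h[t+Δt] = F_h[t] + K_vis · (T − F_h[t]) + w_c · C[t] + η_motor + τ_h[t]

   with visual gain K_vis = 0.12, target T = 45 N per hand (90 N summed), a
   shared common drive C low-pass filtered at 2 Hz, Gaussian motor noise, and
   a ~10 Hz sinusoidal tremor independent per hand. When vision is removed
   (t ≥ 20 s), an internal target T_int (initialized at T) decays each step,

   T_int[t+Δt] = T_int[t] · (1 − λ_drift · Δt),  λ_drift = 0.0045 · (1 − 0.5 · G_proprio)

   and the correction is driven by a delayed (δ = 100 ms), noisy
   proprioceptive estimate of the error:

   F_h[t+Δt] = F_h[t] + G_proprio · K_base · (T_int[t] − F_h[t−δ] + η_proprio) + w_c · C[t] + η_motor + τ_h[t]

   The proprioceptive gain G_proprio is the scientific dial: a higher gain
   both slows the internal-target drift (less undershoot) and strengthens
   corrective activity (more 1–3 Hz spectral power). Between-trial
   variability enters through per-trial draws of λ_drift and the correction
   gain.

2. **The outcome pipeline** for measured or simulated two-channel grip
   recordings: 15 Hz zero-phase 4th-order Butterworth preprocessing, percent
   force undershoot `100·(target − mean force)/target` and RMSE over the
   23–40 s analysis window, Welch band power (Hann, 1024-sample segments,
   50% overlap) in the 1–3 Hz corrective band, and inter-hand
   magnitude-squared coherence (512-sample segments) averaged over the
   0–1, 1–3, 3–7 and 7–12 Hz bands.

3. **Experiment orchestration and statistics**: dose–response sweeps of
   G_proprio (0.20–0.80, 20 trials per value), a sham (G = 0.25) versus
   anodal-stimulation (G = 0.70) condition comparison, visual/non-visual
   epoch contrasts, and the pre/post two-group battery (paired t with Holm
   correction, Cohen's d from difference scores, change-score interaction
   F(1, n−2), ICC(2,1) test–retest reliability, baseline-adjusted ANCOVA,
   change-score Pearson correlations).

## Worked example

```r
library(bimanforce)

p  <- model_params(g_proprio = 0.25)   # sham condition
tr <- simulate_trial(p, seed = 1)
compute_trial_metrics(as_force_recording(tr))
#> Trial metrics over [23, 40) s (vision_off)
#>   undershoot 3.762%, RMSE 4.307 N, 1-3 Hz power 1.718 N^2
#>   coherence: coh_0_1=0.375, coh_1_3=0.317, coh_3_7=0.232, coh_7_12=0.219

condition_comparison(n_trials = 20, master_seed = 1)
#> Condition comparison (non-visual window)
#>   sham (g=0.25, n=20): undershoot 4.24 +/- 1.02 %, RMSE 4.65 N, 1-3 Hz power 1.068 N^2
#>   tdcs (g=0.70, n=20): undershoot 3.29 +/- 0.91 %, RMSE 3.75 N, 1-3 Hz power 2.535 N^2
#>   difference (tdcs - sham): undershoot -0.96 pp, 1-3 Hz power x2.37
```

Read: at the sham gain the summed force settles about 4.2% below the 90 N
target once vision is removed (with a ~1 pp spread across trials from the
built-in between-trial variability), while the higher stimulation gain
trims the undershoot to ~3.3% and roughly doubles the 1–3 Hz corrective
power — the model's two concurrent signatures of enhanced proprioceptive
feedback.

A command-line front end is included:

```sh
Rscript inst/cli/bimanforce.R simulate --gproprio 0.25 --n-trials 20 --seed 1 --out simout
Rscript inst/cli/bimanforce.R dose-response --n-trials 20 --seed 1 --out dose_response.csv
Rscript inst/cli/bimanforce.R stats --table study_table.csv --out report.csv
Rscript inst/cli/bimanforce.R reproduce-figures --seed 1 --out figures
```

Measured recordings (delimited text with `time_s`, `force_left_N`,
`force_right_N` columns) flow through the identical pipeline via
`read_force_recording()`.

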