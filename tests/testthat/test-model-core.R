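test_that("trial realization collapses to the printed arithmetic when variability is off", {
  p <- model_params(g_proprio = 0.70, sd_lambda_trial = 0,
                    sd_kcorr_trial = 0)
  r <- sample_trial_realization(p, seed = 1)
  expect_equal(r$lambda_drift_trial, 0.0045 * (1 - 0.35))
  expect_equal(r$k_correction_trial, 0.105)
  expect_gte(r$tremor_freq_left, p$tremor_freq_lo)
  expect_lte(r$tremor_freq_left, p$tremor_freq_hi)
  expect_gte(r$tremor_phase_right, 0)
  expect_lt(r$tremor_phase_right, 2 * pi)
})

test_that("trial-level draws have the stated spread and stay nonnegative", {
  p <- model_params(g_proprio = 0.25)
  draws <- vapply(seq_len(10000), function(i) {
    r <- sample_trial_realization(p, seed = i)
    c(r$lambda_drift_trial, r$k_correction_trial)
  }, numeric(2))
  expect_equal(sd(draws[1, ]), 0.0008, tolerance = 0.05)
  expect_equal(sd(draws[2, ]), 0.008, tolerance = 0.05)
  expect_equal(mean(draws[1, ]), lambda_drift(p), tolerance = 0.01)
  expect_true(all(draws >= 0))
  # truncation binds when the mean is near zero
  p0 <- model_params(drift_coeff = 0)
  r0 <- vapply(1:200, function(i)
    sample_trial_realization(p0, seed = i)$lambda_drift_trial, numeric(1))
  expect_true(all(r0 >= 0))
  expect_true(any(r0 == 0))
})

test_that("same seed reproduces the identical realization and trial", {
  p <- model_params()
  expect_identical(sample_trial_realization(p, seed = 42),
                   sample_trial_realization(p, seed = 42))
  t1 <- simulate_trial(p, seed = 9)
  t2 <- simulate_trial(p, seed = 9)
  expect_identical(t1$force_left, t2$force_left)
  expect_identical(t1$force_right, t2$force_right)
  expect_identical(t1$common_drive, t2$common_drive)
  t3 <- simulate_trial(p, seed = 10)
  expect_false(identical(t1$force_left, t3$force_left))
})

test_that("common drive is zero-mean, band-limited and seed-stable", {
  p <- model_params(duration = 120, vision_off_time = 60)
  d1 <- generate_common_drive(p, seed = 3)
  expect_length(d1, n_steps(p))
  expect_equal(mean(d1), 0, tolerance = 1e-12)
  expect_identical(d1, generate_common_drive(p, seed = 3))
  # spectral power above twice the cutoff stays marginal
  sp <- welch_psd(d1, fs = 1 / p$dt, nperseg = 1024)
  total <- band_power(sp, 0, 50)
  high <- band_power(sp, 2 * p$common_drive_cutoff, 50)
  expect_lt(high / total, 0.05)
  # zero amplitude gives the zero sequence
  p0 <- model_params(common_drive_sd = 0)
  expect_identical(generate_common_drive(p0, seed = 1),
                   numeric(n_steps(p0)))
})

test_that("tremor is a bounded sinusoid peaking at its own frequency", {
  p <- model_params()
  expect_identical(generate_tremor(10.1, 0, 0, p), numeric(n_steps(p)))
  tr <- generate_tremor(10.1, 0.5, 0.05, p)
  expect_lte(max(abs(tr)), 0.05)
  expect_gt(max(abs(tr)), 0.05 * 0.995)
  # the amplitude is approached within the first couple of cycles
  expect_gt(max(abs(tr[1:20])), 0.05 * 0.9)
  sp <- welch_psd(tr, fs = 100, nperseg = 1024, detrend = FALSE)
  expect_equal(sp$frequency[which.max(sp$psd)], 10.1,
               tolerance = sp$resolution)
  expect_error(generate_tremor(9.0, 0, 0.05, p), "freq")
})

test_that("noise-free visual control converges geometrically onto the target", {
  p <- noise_free_params()
  tr <- simulate_trial(p, seed = 1)
  # |F - target| shrinks by (1 - k_vis) each step, exactly
  i <- 1:200
  expect_equal(tr$force_left[i + 1],
               45 - (45 - tr$force_left[i]) * (1 - p$k_vis),
               tolerance = 1e-12)
  w <- vision_off_window()
  expect_equal(undershoot_percent(summed_force(tr), 90, w, 100), 0,
               tolerance = 1e-6)
  expect_equal(rmse(summed_force(tr), 90, w, 100), 0, tolerance = 1e-6)
})

test_that("noise-free undershoot equals the internal-target decay average", {
  for (g in c(0.2, 0.25, 0.4, 0.7, 0.8)) {
    p <- noise_free_params(drift = TRUE, g_proprio = g)
    tr <- simulate_trial(p, seed = 1)
    us <- undershoot_percent(summed_force(tr), 90, vision_off_window(), 100)
    expect_lt(abs(us - drift_oracle_undershoot(lambda_drift(p))), 0.1,
              label = sprintf("|undershoot - oracle| at g=%.2f", g))
  }
})

test_that("the internal target is flat before the switch and never increases after", {
  tr <- simulate_trial(model_params(g_proprio = 0.25), seed = 4)
  p <- tr$params
  pre <- tr$time < p$vision_off_time
  expect_true(all(tr$internal_target[pre] == p$target_per_hand))
  expect_true(all(diff(tr$internal_target[!pre]) <= 0))
})

test_that("noise-free undershoot decreases strictly with the proprioceptive gain", {
  us <- vapply(c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8), function(g) {
    tr <- simulate_trial(noise_free_params(drift = TRUE, g_proprio = g), 1)
    undershoot_percent(summed_force(tr), 90, vision_off_window(), 100)
  }, numeric(1))
  expect_true(all(diff(us) < 0))
})

test_that("stochastic forces are unbiased about the noise-free trajectory", {
  p <- model_params(g_proprio = 0.5, sd_lambda_trial = 0,
                    sd_kcorr_trial = 0)
  ref <- simulate_trial(noise_free_params(drift = TRUE, g_proprio = 0.5), 1)
  w <- vision_off_window()
  idx <- bimanforce:::window_indices(w, 100, 4000)
  ref_mean <- mean(summed_force(ref)[idx])
  means <- vapply(1:60, function(s)
    mean(summed_force(simulate_trial(p, s))[idx]), numeric(1))
  # Monte-Carlo error of the mean of 60 window means
  expect_lt(abs(mean(means) - ref_mean), 3 * sd(means) / sqrt(60))
})

test_that("delay must sit on the simulation grid", {
  expect_error(model_params(delay = 0.013), "integer multiple")
})

test_that("simulate_condition derives reproducible per-trial seed streams", {
  p <- model_params(g_proprio = 0.25)
  one <- simulate_condition(p, n_trials = 1, master_seed = 5)
  expect_length(one, 1)
  a <- simulate_condition(p, n_trials = 3, master_seed = 5)
  b <- simulate_condition(p, n_trials = 3, master_seed = 5)
  expect_identical(lapply(a, summed_force), lapply(b, summed_force))
  # seeds keyed by gain value, not grid position
  expect_identical(trial_seed(1, 0.25, 2), trial_seed(1, 0.25, 2))
  expect_false(trial_seed(1, 0.25, 2) == trial_seed(1, 0.30, 2))
})
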