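#' Draw the per-trial parameter realization
#'
#' Trial-to-trial variability enters through two parameters: the
#' internal-target drift rate, drawn as
#' `Normal(lambda_drift(params), sd_lambda_trial)`, and the proprioceptive
#' correction gain, drawn as `Normal(g_proprio * k_base, sd_kcorr_trial)`;
#' both draws are truncated at zero. Tremor frequencies are drawn uniformly
#' in `[tremor_freq_lo, tremor_freq_hi]` and phases uniformly in `[0, 2*pi)`,
#' independently for each hand.
#'
#' @param params A [model_params()] object.
#' @param seed Optional non-negative integer seed. When supplied the RNG is
#'   seeded so the same `(params, seed)` always yields the same realization;
#'   when `NULL` the draw continues from the current RNG stream (used
#'   internally by [simulate_trial()]).
#' @return An object of class `"trial_realization"`.
#' @export
sample_trial_realization <- function(params, seed = NULL) {
  validate_model_params(params)
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
    set.seed(as.integer(seed))
  }
  r <- list(
    lambda_drift_trial = max(0, stats::rnorm(1, lambda_drift(params),
                                             params$sd_lambda_trial)),
    k_correction_trial = max(0, stats::rnorm(1,
                                             params$g_proprio * params$k_base,
                                             params$sd_kcorr_trial)),
    tremor_freq_left = stats::runif(1, params$tremor_freq_lo,
                                    params$tremor_freq_hi),
    tremor_freq_right = stats::runif(1, params$tremor_freq_lo,
                                     params$tremor_freq_hi),
    tremor_phase_left = stats::runif(1, 0, 2 * pi),
    tremor_phase_right = stats::runif(1, 0, 2 * pi),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
  class(r) <- "trial_realization"
  r
}

#' Generate the shared common-drive trace
#'
#' White Gaussian noise of SD `common_drive_sd` is low-pass filtered by a
#' second-order Butterworth filter at `common_drive_cutoff` (forward pass
#' only) and recentred to zero mean. The identical trace, weighted by `w_c`,
#' feeds both hands and is what produces inter-hand coherence at low
#' frequencies.
#'
#' @inheritParams sample_trial_realization
#' @return Numeric vector of length `round(duration / dt)` (N).
#' @export
generate_common_drive <- function(params, seed = NULL) {
  validate_model_params(params)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- n_steps(params)
  if (params$common_drive_sd == 0) return(numeric(n))
  white <- stats::rnorm(n, 0, params$common_drive_sd)
  bf <- signal::butter(2, params$common_drive_cutoff / (0.5 / params$dt),
                       type = "low")
  drive <- as.numeric(signal::filter(bf, white))
  drive - mean(drive)
}

#' Generate a sinusoidal tremor trace
#'
#' @param freq Tremor frequency (Hz).
#' @param phase Tremor phase (rad).
#' @param amplitude Tremor amplitude (N).
#' @param params A [model_params()] object supplying the time base.
#' @return Numeric vector `amplitude * sin(2*pi*freq*t + phase)` on the
#'   trial time base (N).
#' @export
generate_tremor <- function(freq, phase, amplitude, params) {
  validate_model_params(params)
  stopifnot(freq >= params$tremor_freq_lo, freq <= params$tremor_freq_hi,
            amplitude >= 0)
  t <- trial_time(params)
  amplitude * sin(2 * pi * freq * t + phase)
}

#' Trial time base
#' @param params A [model_params()] object.
#' @return Numeric vector of sample times, `0, dt, ..., duration - dt` (s).
#' @export
trial_time <- function(params) {
  (seq_len(n_steps(params)) - 1) * params$dt
}

#' Simulate one closed-loop bimanual force trial
#'
#' Integrates the two-epoch state model at `1/dt` Hz for `duration` s. While
#' visual feedback is available (`t < vision_off_time`) each hand h evolves
#' as
#'
#' `F_h[t+dt] = F_h[t] + k_vis * (target - F_h[t]) + w_c * C[t] +
#'  eta_motor + tau_h[t]`
#'
#' with motor noise SD `sigma_motor_on`. From `vision_off_time` on, an
#' internal target initialized at `target_per_hand` decays each step by
#' `lambda * dt` (multiplicatively), and the correction is driven by the
#' delayed proprioceptive force estimate:
#'
#' `e_hat = T_int[t] - F_h[t - delay] + eta_proprio`
#' `F_h[t+dt] = F_h[t] + k_corr * e_hat + w_c * C[t] + eta_motor + tau_h[t]`
#'
#' with motor noise SD `sigma_motor_off`, `lambda` and `k_corr` the
#' per-trial draws of [sample_trial_realization()]. Motor and proprioceptive
#' noises are independent across hands and steps; the common drive `C` is
#' shared. Forces start at 0 N; the visual epoch settles well inside the
#' first second.
#'
#' @param params A [model_params()] object.
#' @param seed Non-negative integer seed; `(params, seed)` fully determine
#'   every trace.
#' @return An object of class `"simulated_trial"`: a list with `time`,
#'   `force_left`, `force_right`, `internal_target` (per-hand scale),
#'   `common_drive`, `tremor_left`, `tremor_right`, `realization`, `params`.
#' @examples
#' tr <- simulate_trial(model_params(g_proprio = 0.7), seed = 1)
#' mean(tr$force_left + tr$force_right)
#' @export
simulate_trial <- function(params, seed) {
  validate_model_params(params)
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
  set.seed(as.integer(seed))

  n <- n_steps(params)
  dt <- params$dt
  d <- as.integer(round(params$delay / dt))
  i_off <- as.integer(round(params$vision_off_time / dt)) + 1L # first OFF step
  Tgt <- params$target_per_hand

  # draw order is fixed and documented: realization, common drive, motor
  # noise (L then R), proprioceptive noise (L then R)
  real <- sample_trial_realization(params)
  real$seed <- as.integer(seed)
  drive <- generate_common_drive(params)
  sig_m <- c(rep(params$sigma_motor_on, i_off - 1L),
             rep(params$sigma_motor_off, n - i_off + 1L))
  eta_m_l <- stats::rnorm(n, 0, 1) * sig_m
  eta_m_r <- stats::rnorm(n, 0, 1) * sig_m
  eta_p_l <- stats::rnorm(n, 0, params$sigma_proprio)
  eta_p_r <- stats::rnorm(n, 0, params$sigma_proprio)
  trem_l <- generate_tremor(real$tremor_freq_left, real$tremor_phase_left,
                            params$tremor_amplitude, params)
  trem_r <- generate_tremor(real$tremor_freq_right, real$tremor_phase_right,
                            params$tremor_amplitude, params)

  # internal target: held at the displayed target until the switch, then
  # multiplicative decay by lambda*dt per step
  t_int <- rep(Tgt, n)
  if (i_off < n) {
    decay <- Tgt * (1 - real$lambda_drift_trial * dt) ^ (seq_len(n - i_off))
    t_int[(i_off + 1L):n] <- decay
  }

  kv <- params$k_vis
  kc <- real$k_correction_trial
  wc <- params$w_c
  fl <- numeric(n)
  fr <- numeric(n)
  inp_l <- wc * drive + eta_m_l + trem_l
  inp_r <- wc * drive + eta_m_r + trem_r
  for (i in seq_len(n - 1L)) {
    if (i < i_off) {
      fl[i + 1L] <- fl[i] + kv * (Tgt - fl[i]) + inp_l[i]
      fr[i + 1L] <- fr[i] + kv * (Tgt - fr[i]) + inp_r[i]
    } else {
      j <- i - d
      fl[i + 1L] <- fl[i] + kc * (t_int[i] - fl[j] + eta_p_l[i]) + inp_l[i]
      fr[i + 1L] <- fr[i] + kc * (t_int[i] - fr[j] + eta_p_r[i]) + inp_r[i]
    }
  }

  structure(list(
    time = trial_time(params),
    force_left = fl,
    force_right = fr,
    internal_target = t_int,
    common_drive = drive,
    tremor_left = trem_l,
    tremor_right = trem_r,
    realization = real,
    params = params
  ), class = "simulated_trial")
}

#' @export
print.simulated_trial <- function(x, ...) {
  p <- x$params
  cat(sprintf("Simulated bimanual trial: %d samples at %.0f Hz (seed %s)\n",
              length(x$time), 1 / p$dt,
              ifelse(is.na(x$realization$seed), "?", x$realization$seed)))
  cat(sprintf("  g_proprio %.2f, trial lambda %.6f 1/s, trial k_corr %.4f\n",
              p$g_proprio, x$realization$lambda_drift_trial,
              x$realization$k_correction_trial))
  w <- vision_off_window(p)
  us <- undershoot_percent(x$force_left + x$force_right,
                           2 * p$target_per_hand, w, fs = 1 / p$dt)
  cat(sprintf("  undershoot over [%g, %g) s: %.2f%%\n", w$start, w$end, us))
  invisible(x)
}

#' Deterministic per-trial seed stream
#'
#' Trial seeds are `master_seed + 100003 * round(100 * g_proprio) + index`,
#' folded into the positive 31-bit integer range. Keying the stream by the
#' gain value (not the grid position) makes sweep results invariant to grid
#' ordering and to adding grid points.
#'
#' @param master_seed Non-negative integer master seed.
#' @param g_proprio Proprioceptive gain of the condition.
#' @param index Trial index, 1-based.
#' @return Integer seed.
#' @export
trial_seed <- function(master_seed, g_proprio, index) {
  base <- as.double(master_seed) + 100003 * round(100 * g_proprio) +
    as.double(index)
  as.integer(base %% 2147483647)
}

#' Simulate replicate trials of one condition
#'
#' @param params A [model_params()] object.
#' @param n_trials Number of independent trials (>= 1).
#' @param master_seed Non-negative integer; per-trial seeds come from
#'   [trial_seed()] so the same master seed reproduces the identical set.
#' @return List of [simulate_trial()] results.
#' @export
simulate_condition <- function(params, n_trials = 20, master_seed = 1) {
  validate_model_params(params)
  stopifnot(n_trials >= 1)
  lapply(seq_len(n_trials), function(i) {
    simulate_trial(params, trial_seed(master_seed, params$g_proprio, i))
  })
}
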