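# deterministic parameter sets used across tests

# every stochastic term off; optionally keep the internal-target drift
noise_free_params <- function(drift = FALSE, ...) {
  model_params(sigma_motor_on = 0, sigma_motor_off = 0, sigma_proprio = 0,
               tremor_amplitude = 0, common_drive_sd = 0,
               drift_coeff = if (drift) 0.0045 else 0,
               sd_lambda_trial = 0, sd_kcorr_trial = 0, ...)
}

# mean of the decaying internal target over [start, end) s after the
# switch, as percent undershoot: closed-form continuous-time average
drift_oracle_undershoot <- function(lambda, start = 3, end = 20) {
  if (lambda == 0) return(0)
  100 * (1 - (exp(-lambda * start) - exp(-lambda * end)) /
           ((end - start) * lambda))
}

summed_force <- function(trial) trial$force_left + trial$force_right
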