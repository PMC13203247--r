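#' Model parameters for the closed-loop bimanual force-control simulator
#'
#' Bundles every constant of the two-epoch state model. During the visual
#' epoch each hand's force is corrected toward the displayed target with a
#' per-step visual gain; after visual feedback is withdrawn, control relies
#' on a delayed, noisy proprioceptive estimate of force compared against an
#' internal target representation that decays multiplicatively at rate
#' `lambda_drift = drift_coeff * (1 - 0.5 * g_proprio)` per second. Both
#' hands additionally receive a shared low-pass-filtered common drive and an
#' independent near-10 Hz sinusoidal tremor.
#'
#' Gains `k_vis` and the correction gain (`g_proprio * k_base`, jittered per
#' trial) are applied per 10 ms step; the drift rate `lambda_drift` is per
#' second and enters the internal-target update as `lambda_drift * dt`.
#'
#' @param k_vis Per-step visual feedback gain (dimensionless).
#' @param k_base Per-step base correction gain (dimensionless).
#' @param g_proprio Proprioceptive feedback gain (dimensionless); nominal
#'   range 0.2--0.8, with 0.25 the sham reference condition and 0.70 the
#'   stimulation condition.
#' @param w_c Common-drive weight (dimensionless).
#' @param sigma_motor_on,sigma_motor_off Motor execution noise SD (N) during
#'   the visual and non-visual epochs.
#' @param sigma_proprio Proprioceptive measurement noise SD (N).
#' @param drift_coeff Drift-rate scale (1/s); the effective drift rate is
#'   `drift_coeff * (1 - 0.5 * g_proprio)`.
#' @param delay Proprioceptive feedback delay (s); must be an integer
#'   multiple of `dt`.
#' @param tremor_freq_lo,tremor_freq_hi Tremor frequency bounds (Hz).
#' @param tremor_amplitude Tremor amplitude (N).
#' @param common_drive_cutoff Low-pass cutoff of the common drive (Hz).
#' @param common_drive_sd Pre-filter SD of the common-drive noise (N).
#' @param target_per_hand Target force per hand (N); the displayed target is
#'   the sum over both hands.
#' @param duration Trial length (s).
#' @param dt Time step (s); 0.01 corresponds to the 100 Hz sampling rate.
#' @param vision_off_time Time of visual-feedback removal (s).
#' @param sd_lambda_trial Between-trial SD of the drift rate (1/s).
#' @param sd_kcorr_trial Between-trial SD of the correction gain
#'   (dimensionless).
#'
#' @return An object of class `"model_params"`: a validated named list.
#' @seealso [simulate_trial()], [lambda_drift()], [read_model_config()]
#' @examples
#' p <- model_params(g_proprio = 0.25)
#' lambda_drift(p)
#' @export
model_params <- function(k_vis = 0.12,
                         k_base = 0.15,
                         g_proprio = 0.25,
                         w_c = 0.15,
                         sigma_motor_on = 0.22,
                         sigma_motor_off = 0.25,
                         sigma_proprio = 0.15,
                         drift_coeff = 0.0045,
                         delay = 0.100,
                         tremor_freq_lo = 10.0,
                         tremor_freq_hi = 10.2,
                         tremor_amplitude = 0.05,
                         common_drive_cutoff = 2.0,
                         common_drive_sd = 1.0,
                         target_per_hand = 45.0,
                         duration = 40.0,
                         dt = 0.01,
                         vision_off_time = 20.0,
                         sd_lambda_trial = 0.0008,
                         sd_kcorr_trial = 0.008) {
  p <- list(
    k_vis = k_vis, k_base = k_base, g_proprio = g_proprio, w_c = w_c,
    sigma_motor_on = sigma_motor_on, sigma_motor_off = sigma_motor_off,
    sigma_proprio = sigma_proprio, drift_coeff = drift_coeff, delay = delay,
    tremor_freq_lo = tremor_freq_lo, tremor_freq_hi = tremor_freq_hi,
    tremor_amplitude = tremor_amplitude,
    common_drive_cutoff = common_drive_cutoff,
    common_drive_sd = common_drive_sd,
    target_per_hand = target_per_hand, duration = duration, dt = dt,
    vision_off_time = vision_off_time,
    sd_lambda_trial = sd_lambda_trial, sd_kcorr_trial = sd_kcorr_trial
  )
  class(p) <- "model_params"
  validate_model_params(p)
  p
}

validate_model_params <- function(p) {
  stopifnot(is.list(p))
  num1 <- function(field) {
    v <- p[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("parameter '%s' must be a single finite number", field),
           call. = FALSE)
    v
  }
  for (f in setdiff(names(p), character(0))) num1(f)
  if (p$dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (!(p$duration > p$vision_off_time && p$vision_off_time > 0))
    stop("need duration > vision_off_time > 0", call. = FALSE)
  if (p$delay < 0) stop("delay must be >= 0", call. = FALSE)
  if (abs(p$delay / p$dt - round(p$delay / p$dt)) > 1e-8)
    stop("delay must be an integer multiple of dt", call. = FALSE)
  nonneg <- c("sigma_motor_on", "sigma_motor_off", "sigma_proprio",
              "tremor_amplitude", "common_drive_sd",
              "sd_lambda_trial", "sd_kcorr_trial", "drift_coeff")
  for (f in nonneg)
    if (p[[f]] < 0) stop(sprintf("'%s' must be >= 0", f), call. = FALSE)
  if (p$g_proprio <= 0) stop("g_proprio must be > 0", call. = FALSE)
  if (p$tremor_freq_lo > p$tremor_freq_hi)
    stop("tremor_freq_lo must be <= tremor_freq_hi", call. = FALSE)
  if (lambda_drift(p) < 0)
    stop("drift rate drift_coeff * (1 - 0.5 * g_proprio) must be >= 0",
         call. = FALSE)
  invisible(p)
}

#' Effective internal-target drift rate
#'
#' `lambda_drift(p)` returns `drift_coeff * (1 - 0.5 * g_proprio)` in 1/s:
#' larger proprioceptive gain means slower decay of the remembered target.
#'
#' @param params A [model_params()] object.
#' @return Drift rate (1/s).
#' @export
lambda_drift <- function(params) {
  params$drift_coeff * (1 - 0.5 * params$g_proprio)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Closed-loop force-control model parameters\n")
  cat(sprintf("  sampling: %.0f Hz, duration %.1f s, vision off at %.1f s\n",
              1 / x$dt, x$duration, x$vision_off_time))
  cat(sprintf("  target: %.1f N per hand (%.1f N summed)\n",
              x$target_per_hand, 2 * x$target_per_hand))
  cat(sprintf("  gains: k_vis %.3f, k_base %.3f, g_proprio %.3f (correction %.4f)\n",
              x$k_vis, x$k_base, x$g_proprio, x$g_proprio * x$k_base))
  cat(sprintf("  drift: lambda %.6f 1/s (coeff %.4f); delay %.0f ms\n",
              lambda_drift(x), x$drift_coeff, 1000 * x$delay))
  cat(sprintf("  noise: motor %.2f/%.2f N (on/off), proprio %.2f N\n",
              x$sigma_motor_on, x$sigma_motor_off, x$sigma_proprio))
  cat(sprintf("  common drive: sd %.2f N, cutoff %.1f Hz, weight %.2f\n",
              x$common_drive_sd, x$common_drive_cutoff, x$w_c))
  cat(sprintf("  tremor: %.2f N at %.1f-%.1f Hz\n",
              x$tremor_amplitude, x$tremor_freq_lo, x$tremor_freq_hi))
  cat(sprintf("  trial variability: sd(lambda) %.4g, sd(k_corr) %.4g\n",
              x$sd_lambda_trial, x$sd_kcorr_trial))
  invisible(x)
}

#' Number of samples in a trial
#' @param params A [model_params()] object.
#' @return Integer number of time steps, `round(duration / dt)`.
#' @keywords internal
n_steps <- function(params) as.integer(round(params$duration / params$dt))

#' Read model parameters from a YAML or JSON configuration file
#'
#' The file holds a flat mapping whose keys match [model_params()] argument
#' names; any key omitted takes the default. Format is chosen by file
#' extension (`.yaml`/`.yml` or `.json`).
#'
#' @param path Path to the configuration file.
#' @return A [model_params()] object.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format '", ext, "' (use yaml or json)",
         call. = FALSE)
  )
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), names(formals(model_params)))
  if (length(unknown))
    stop("unknown configuration fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(model_params, cfg)
}
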