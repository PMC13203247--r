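#' Percent force undershoot
#'
#' `100 * (target - mean(force)) / target` over the window: the signed
#' percent by which mean produced force falls below the target (negative
#' values indicate overshoot).
#'
#' @param force_sum Summed force signal (N).
#' @param target_total Summed target force (N), nonzero.
#' @param window An [epoch_window()].
#' @param fs Sampling rate (Hz).
#' @return Undershoot in percent.
#' @export
undershoot_percent <- function(force_sum, target_total, window, fs) {
  if (target_total == 0) stop("target_total must be nonzero", call. = FALSE)
  idx <- window_indices(window, fs, length(force_sum))
  100 * (target_total - mean(force_sum[idx])) / target_total
}

#' Root mean square error of force about the target
#'
#' `sqrt(mean((force - target)^2))` over the window; combines systematic
#' bias and fluctuation: `rmse^2 = bias^2 + var` (population variance).
#'
#' @inheritParams undershoot_percent
#' @return RMSE (N).
#' @export
rmse <- function(force_sum, target_total, window, fs) {
  idx <- window_indices(window, fs, length(force_sum))
  sqrt(mean((force_sum[idx] - target_total)^2))
}

#' Compute the full outcome set for one recording and window
#'
#' All scalar outcomes are computed from the summed bimanual signal
#' (left + right): percent undershoot, RMSE, and 1--3 Hz Welch band power;
#' inter-hand coherence is computed between the two per-hand channels over
#' the same window and averaged within the four standard bands. By default
#' the recording is first low-pass filtered at 15 Hz (4th-order zero-phase
#' Butterworth), matching the acquisition convention, so simulated and
#' measured data traverse an identical path.
#'
#' @param recording A [force_recording()].
#' @param window An [epoch_window()]; default the non-visual window
#'   `[23, 40)`.
#' @param lowpass Apply [lowpass_filter()] first (default TRUE).
#' @param nperseg_psd Welch segment length for the PSD (samples).
#' @param nperseg_coh Welch segment length for coherence (samples).
#' @return An object of class `"trial_metrics"`: a list with `undershoot`
#'   (%), `rmse` (N), `band_power_1_3` (N^2), `coherence_bands` (named
#'   vector), `window`.
#' @export
compute_trial_metrics <- function(recording, window = vision_off_window(),
                                  lowpass = TRUE,
                                  nperseg_psd = 1024, nperseg_coh = 512) {
  stopifnot(inherits(recording, "force_recording"),
            inherits(window, "epoch_window"))
  if (lowpass) recording <- lowpass_filter(recording)
  fs <- recording$sampling_rate
  idx <- window_indices(window, fs, length(recording$force_left))
  left <- recording$force_left[idx]
  right <- recording$force_right[idx]
  force_sum <- left + right
  target <- recording$target_total

  spec <- welch_psd(force_sum, fs, nperseg = nperseg_psd)
  coh <- inter_hand_coherence(left, right, fs, nperseg = nperseg_coh)

  structure(list(
    undershoot = 100 * (target - mean(force_sum)) / target,
    rmse = sqrt(mean((force_sum - target)^2)),
    band_power_1_3 = band_power(spec, 1, 3),
    coherence_bands = band_mean_coherence(coh),
    window = window
  ), class = "trial_metrics")
}

#' @export
print.trial_metrics <- function(x, ...) {
  cat(sprintf("Trial metrics over [%g, %g) s (%s)\n",
              x$window$start, x$window$end, x$window$label))
  cat(sprintf("  undershoot %.3f%%, RMSE %.3f N, 1-3 Hz power %.4g N^2\n",
              x$undershoot, x$rmse, x$band_power_1_3))
  cb <- x$coherence_bands
  cat("  coherence:", paste(sprintf("%s=%.3f", names(cb), cb),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Flatten trial metrics to a one-row data frame
#'
#' @param x A [compute_trial_metrics()] result.
#' @param row.names,optional,... Passed for S3 compatibility; unused.
#' @return One-row data frame with columns `window`, `undershoot`, `rmse`,
#'   `band_power_1_3` and one column per coherence band.
#' @export
as.data.frame.trial_metrics <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  out <- data.frame(
    window = x$window$label,
    undershoot = x$undershoot,
    rmse = x$rmse,
    band_power_1_3 = x$band_power_1_3,
    stringsAsFactors = FALSE
  )
  for (nm in names(x$coherence_bands)) out[[nm]] <- x$coherence_bands[[nm]]
  out
}
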