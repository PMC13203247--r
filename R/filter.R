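#' Zero-phase Butterworth low-pass filtering of a force recording
#'
#' Both channels are filtered with an order-`order` Butterworth low-pass
#' (coefficients from [signal::butter()]) applied forward and backward, so
#' the filtered force is not delayed relative to the target. Edge effects
#' are controlled by odd-reflection padding before filtering, which leaves a
#' constant signal exactly unchanged.
#'
#' @param recording A [force_recording()].
#' @param cutoff Cutoff frequency (Hz); must be below Nyquist.
#' @param order Filter order for each pass.
#' @return A [force_recording()] with filtered channels, same length.
#' @export
lowpass_filter <- function(recording, cutoff = 15, order = 4) {
  stopifnot(inherits(recording, "force_recording"))
  fs <- recording$sampling_rate
  if (cutoff >= fs / 2)
    stop(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 cutoff, fs / 2), call. = FALSE)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  out <- recording
  out$force_left <- filtfilt_padded(bf$b, bf$a, recording$force_left)
  out$force_right <- filtfilt_padded(bf$b, bf$a, recording$force_right)
  out
}

# forward-backward IIR filtering with odd-reflection edge padding; the pad
# (up to 200 samples) is long enough that the startup transient of any
# filter used here decays below double precision before the data begin
filtfilt_padded <- function(b, a, x) {
  n <- length(x)
  p <- min(n - 1L, 200L)
  xp <- c(2 * x[1] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
  y <- as.numeric(signal::filter(b, a, xp))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[(p + 1L):(p + n)]
}
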