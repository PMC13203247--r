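#' Two-channel force recording
#'
#' Container for a measured or simulated bimanual grip-force time series:
#' left- and right-hand force in Newtons on a uniform time base, the summed
#' target force, and free-form metadata labels (participant, group, epoch).
#'
#' @param time Sample times (s), strictly increasing and uniform (jitter
#'   under a tenth of a sample period).
#' @param force_left,force_right Per-hand force (N), same length as `time`.
#' @param target_total Summed target force (N), e.g. `2 * target_per_hand`.
#' @param sampling_rate Sampling rate (Hz); by default inferred from `time`.
#' @param metadata Named list of labels.
#' @return An object of class `"force_recording"`.
#' @export
force_recording <- function(time, force_left, force_right, target_total,
                            sampling_rate = NULL, metadata = list()) {
  n <- length(time)
  if (length(force_left) != n || length(force_right) != n)
    stop("time and force channels must have equal length", call. = FALSE)
  if (n < 2) stop("recording needs at least 2 samples", call. = FALSE)
  if (anyNA(time) || anyNA(force_left) || anyNA(force_right))
    stop("recording contains missing values", call. = FALSE)
  dtv <- diff(time)
  if (any(dtv <= 0)) {
    bad <- which(dtv <= 0)[1] + 1L
    stop("time must be strictly increasing (first violation at sample ",
         bad, ")", call. = FALSE)
  }
  dt <- stats::median(dtv)
  if (max(abs(dtv - dt)) > dt / 10)
    stop("sampling is not uniform (jitter exceeds dt/10)", call. = FALSE)
  if (is.null(sampling_rate)) sampling_rate <- 1 / dt
  if (sampling_rate <= 0) stop("sampling_rate must be > 0", call. = FALSE)
  if (!is.numeric(target_total) || length(target_total) != 1L)
    stop("target_total must be a single number", call. = FALSE)
  structure(list(
    time = as.numeric(time),
    force_left = as.numeric(force_left),
    force_right = as.numeric(force_right),
    sampling_rate = sampling_rate,
    target_total = target_total,
    metadata = metadata
  ), class = "force_recording")
}

#' Convert a simulated trial to a force recording
#'
#' Simulated trials flow through the identical metrics path as measured
#' data: the recording carries the two force channels, the 100 Hz time base
#' and the summed target.
#'
#' @param x A [simulate_trial()] result.
#' @param ... Unused.
#' @return A [force_recording()].
#' @export
as_force_recording <- function(x, ...) UseMethod("as_force_recording")

#' @rdname as_force_recording
#' @export
as_force_recording.simulated_trial <- function(x, ...) {
  force_recording(
    time = x$time,
    force_left = x$force_left,
    force_right = x$force_right,
    target_total = 2 * x$params$target_per_hand,
    sampling_rate = 1 / x$params$dt,
    metadata = list(source = "simulated",
                    seed = x$realization$seed,
                    g_proprio = x$params$g_proprio)
  )
}

#' @export
print.force_recording <- function(x, ...) {
  cat(sprintf("Force recording: %d samples at %.6g Hz (%.2f s), target %.1f N\n",
              length(x$time), x$sampling_rate,
              length(x$time) / x$sampling_rate, x$target_total))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata),
                             vapply(x$metadata, format, ""),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Epoch analysis window
#'
#' Windows are half-open in time, `[start, end)`, mapped to sample indices
#' `floor(start * fs) .. floor(end * fs) - 1` (zero-based). The standard
#' windows both last 17 s: the visual epoch window `[3, 20)` skips the
#' initial force ramp, and the non-visual window `[23, 40)` skips the 3 s
#' transition after visual feedback is removed.
#'
#' @param start Window start (s), inclusive.
#' @param end Window end (s), exclusive; must exceed `start`.
#' @param label Window label.
#' @return An object of class `"epoch_window"`.
#' @export
epoch_window <- function(start, end, label = "window") {
  stopifnot(is.numeric(start), is.numeric(end), length(start) == 1L,
            length(end) == 1L, end > start, start >= 0)
  structure(list(start = start, end = end, label = label),
            class = "epoch_window")
}

#' @rdname epoch_window
#' @param params Optional [model_params()]; defaults place the windows at
#'   `[3, vision_off_time)` and `[vision_off_time + 3, duration)`.
#' @export
vision_on_window <- function(params = NULL) {
  if (is.null(params)) return(epoch_window(3, 20, "vision_on"))
  epoch_window(3, params$vision_off_time, "vision_on")
}

#' @rdname epoch_window
#' @export
vision_off_window <- function(params = NULL) {
  if (is.null(params)) return(epoch_window(23, 40, "vision_off"))
  epoch_window(params$vision_off_time + 3, params$duration, "vision_off")
}

#' Sample indices covered by an epoch window
#'
#' @param window An [epoch_window()].
#' @param fs Sampling rate (Hz).
#' @param n Number of samples available.
#' @return Integer vector of 1-based indices.
#' @keywords internal
window_indices <- function(window, fs, n) {
  lo <- floor(window$start * fs) + 1L
  hi <- floor(window$end * fs)
  if (hi > n)
    stop(sprintf("window [%g, %g) s extends beyond the recording (%d samples at %g Hz)",
                 window$start, window$end, n, fs), call. = FALSE)
  if (lo > hi) stop("window contains no samples", call. = FALSE)
  seq.int(lo, hi)
}
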