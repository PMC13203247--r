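#' Welch power spectral density estimate
#'
#' Averaged modified periodograms: the signal is split into overlapping
#' segments, each segment has its mean removed (constant detrend) and is
#' tapered with a periodic Hann window, and the one-sided periodograms are
#' averaged. With the standard configuration (1024-sample segments, 50%
#' overlap, 100 Hz) a 17 s analysis window yields 2 segments and a
#' frequency resolution of 100/1024 = 0.09766 Hz.
#'
#' Removing the per-segment mean matters here: the summed force carries a
#' large (near 90 N) DC component whose spectral leakage would otherwise
#' contaminate the 1--3 Hz band.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param nperseg Segment length in samples.
#' @param overlap_fraction Fractional overlap between consecutive segments.
#' @param detrend Remove the per-segment mean before tapering (default TRUE).
#' @return An object of class `"spectral_density"`: a list with `frequency`
#'   (Hz), `psd` (N^2/Hz), `resolution` (Hz, = `fs / nperseg`) and
#'   `n_segments`.
#' @examples
#' x <- sin(2 * pi * 2 * seq(0, 40, by = 0.01))
#' sp <- welch_psd(x, fs = 100)
#' band_power(sp, 1, 3) # ~ 0.5 = A^2/2
#' @export
welch_psd <- function(x, fs, nperseg = 1024, overlap_fraction = 0.5,
                      detrend = TRUE) {
  segs <- welch_segments(length(x), nperseg, overlap_fraction)
  w <- hann_window(nperseg)
  scale <- 1 / (fs * sum(w^2))
  nfreq <- nperseg %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in segs) {
    seg <- x[s:(s + nperseg - 1L)]
    if (detrend) seg <- seg - mean(seg)
    spec <- stats::fft(seg * w)[seq_len(nfreq)]
    pxx <- scale * (Re(spec)^2 + Im(spec)^2)
    acc <- acc + one_sided(pxx, nperseg)
  }
  structure(list(
    frequency = (seq_len(nfreq) - 1) * fs / nperseg,
    psd = acc / length(segs),
    resolution = fs / nperseg,
    n_segments = length(segs)
  ), class = "spectral_density")
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

welch_segments <- function(n, nperseg, overlap_fraction) {
  stopifnot(nperseg >= 2, overlap_fraction >= 0, overlap_fraction < 1)
  if (n < nperseg)
    stop(sprintf("signal (%d samples) is shorter than one segment (%d)",
                 n, nperseg), call. = FALSE)
  step <- nperseg - floor(nperseg * overlap_fraction)
  seq.int(1L, n - nperseg + 1L, by = step)
}

# double all bins except DC (and Nyquist when the segment length is even)
one_sided <- function(pxx, nperseg) {
  n <- length(pxx)
  mult <- rep(2, n)
  mult[1] <- 1
  if (nperseg %% 2 == 0) mult[n] <- 1
  pxx * mult
}

#' @export
print.spectral_density <- function(x, ...) {
  cat(sprintf("Welch PSD: %d bins, resolution %.5f Hz, %d segment(s)\n",
              length(x$frequency), x$resolution, x$n_segments))
  invisible(x)
}

#' Integrated band power of a spectral density
#'
#' Rectangular integration `sum(psd) * resolution` over bins whose center
#' frequency lies in the half-open band `[lo, hi)`; half-open bands prevent
#' double counting at shared band edges.
#'
#' @param spec A [welch_psd()] result.
#' @param lo,hi Band edges (Hz), `0 <= lo < hi <=` Nyquist.
#' @return Band power (N^2).
#' @export
band_power <- function(spec, lo, hi) {
  stopifnot(inherits(spec, "spectral_density"), lo >= 0, hi > lo)
  nyquist <- max(spec$frequency)
  if (hi > nyquist + 1e-9)
    stop(sprintf("band edge %g Hz exceeds the Nyquist frequency %g Hz",
                 hi, nyquist), call. = FALSE)
  sel <- spec$frequency >= lo & spec$frequency < hi
  sum(spec$psd[sel]) * spec$resolution
}

#' Inter-hand magnitude-squared coherence
#'
#' Welch cross-spectral estimate between the two hands' force signals:
#' `|mean(Pxy)|^2 / (mean(Pxx) * mean(Pyy))` over segments, with the same
#' per-segment constant detrend and periodic Hann taper as [welch_psd()].
#' At least two segments are required -- with a single segment the estimate
#' degenerates to 1 at every frequency.
#'
#' @param left,right Numeric signals of equal length.
#' @param fs Sampling rate (Hz).
#' @param nperseg Segment length in samples.
#' @param overlap_fraction Fractional overlap.
#' @return An object of class `"coherence_spectrum"`: a list with
#'   `frequency` (Hz), `coherence` (each value in `[0, 1]`), `resolution`,
#'   `n_segments`.
#' @export
inter_hand_coherence <- function(left, right, fs, nperseg = 512,
                                 overlap_fraction = 0.5) {
  if (length(left) != length(right))
    stop("channels must have equal length", call. = FALSE)
  segs <- welch_segments(length(left), nperseg, overlap_fraction)
  if (length(segs) < 2)
    stop("coherence needs at least 2 segments (estimate degenerates to 1)",
         call. = FALSE)
  w <- hann_window(nperseg)
  nfreq <- nperseg %/% 2 + 1L
  sxx <- numeric(nfreq)
  syy <- numeric(nfreq)
  sxy <- complex(nfreq)
  for (s in segs) {
    xl <- left[s:(s + nperseg - 1L)]
    xr <- right[s:(s + nperseg - 1L)]
    fl <- stats::fft((xl - mean(xl)) * w)[seq_len(nfreq)]
    fr <- stats::fft((xr - mean(xr)) * w)[seq_len(nfreq)]
    sxx <- sxx + Re(fl)^2 + Im(fl)^2
    syy <- syy + Re(fr)^2 + Im(fr)^2
    sxy <- sxy + Conj(fl) * fr
  }
  denom <- sxx * syy
  coh <- ifelse(denom > 0, (Re(sxy)^2 + Im(sxy)^2) / denom, 0)
  structure(list(
    frequency = (seq_len(nfreq) - 1) * fs / nperseg,
    coherence = pmin(1, pmax(0, coh)),
    resolution = fs / nperseg,
    n_segments = length(segs)
  ), class = "coherence_spectrum")
}

#' Standard coherence frequency bands
#'
#' The four bands used throughout: 0--1 Hz (common slow drift), 1--3 Hz
#' (corrective oscillations), 3--7 Hz (faster adjustments), 7--12 Hz
#' (physiological tremor range). Bands are half-open `[lo, hi)`.
#'
#' @return Named list of `c(lo, hi)` pairs.
#' @export
coherence_bands <- function() {
  list(coh_0_1 = c(0, 1), coh_1_3 = c(1, 3),
       coh_3_7 = c(3, 7), coh_7_12 = c(7, 12))
}

#' Band-mean coherence
#'
#' Arithmetic mean of the magnitude-squared coherence over the bins whose
#' center frequency falls in each half-open band.
#'
#' @param coh An [inter_hand_coherence()] result.
#' @param bands Named list of `c(lo, hi)` band edges (Hz); defaults to
#'   [coherence_bands()].
#' @return Named numeric vector of band means, each in `[0, 1]`.
#' @export
band_mean_coherence <- function(coh, bands = coherence_bands()) {
  stopifnot(inherits(coh, "coherence_spectrum"))
  nyquist <- max(coh$frequency)
  vapply(bands, function(b) {
    if (b[2] > nyquist + 1e-9)
      stop("band extends beyond the Nyquist frequency", call. = FALSE)
    sel <- coh$frequency >= b[1] & coh$frequency < b[2]
    if (!any(sel)) stop("band contains no frequency bins", call. = FALSE)
    mean(coh$coherence[sel])
  }, numeric(1))
}
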