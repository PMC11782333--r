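#' Construct an audio recording
#'
#' Container for a sampled auscultation (phonoangiogram) signal. Amplitudes
#' are pressure-proportional in arbitrary units; the electronic-stethoscope
#' band of interest is 20-2000 Hz, so recordings are typically sampled at
#' 4 kHz or above.
#'
#' @param samples Numeric vector of finite sample values (length >= 1).
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param label Free-text label (patient / visit / operator).
#' @return An object of class `avf_audio` with elements `samples`,
#'   `sample_rate`, `label`.
#' @export
audio_recording <- function(samples, sample_rate, label = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("audio recording needs at least one sample")
  if (!all(is.finite(samples))) stop("audio samples must all be finite")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a single positive number (Hz)")
  structure(list(samples = samples, sample_rate = as.numeric(sample_rate),
                 label = as.character(label)),
            class = "avf_audio")
}

#' @export
print.avf_audio <- function(x, ...) {
  cat(sprintf("<avf_audio> %s: %d samples @ %g Hz (%.3f s)\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$samples), x$sample_rate, duration(x)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `avf_audio` object.
#' @return Duration in seconds.
#' @export
duration <- function(rec) length(rec$samples) / rec$sample_rate

#' Trim a recording to a standard duration
#'
#' Takes the centered window of the requested duration, discarding equal
#' margins at both ends. Centering avoids the stethoscope contact
#' transients that concentrate at the start and end of bedside recordings.
#'
#' @param rec An `avf_audio` object.
#' @param duration_s Target duration in seconds (default 4).
#' @return An `avf_audio` of exactly `round(duration_s * sample_rate)`
#'   samples.
#' @export
trim_to_standard <- function(rec, duration_s = 4) {
  stopifnot(inherits(rec, "avf_audio"))
  n_out <- round(duration_s * rec$sample_rate)
  n_in <- length(rec$samples)
  if (n_in < n_out)
    stop(sprintf("recording too short: %.3f s available, %.3f s required",
                 n_in / rec$sample_rate, duration_s))
  offset <- floor((n_in - n_out) / 2)
  audio_recording(rec$samples[(offset + 1L):(offset + n_out)],
                  rec$sample_rate, rec$label)
}

#' High-pass filter a recording
#'
#' Causal single-pass Butterworth high-pass, removing the low-frequency
#' device and contact noise below the cutoff. A single pass keeps the
#' realized filter order equal to the nominal one.
#'
#' @param rec An `avf_audio` object.
#' @param cutoff_hz Cutoff (-3 dB) frequency in Hz, default 50.
#' @param order Filter order, default 4.
#' @return Filtered `avf_audio` of the same length.
#' @export
highpass_50hz <- function(rec, cutoff_hz = 50, order = 4) {
  stopifnot(inherits(rec, "avf_audio"))
  nyq <- rec$sample_rate / 2
  if (cutoff_hz >= nyq)
    stop(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 cutoff_hz, nyq))
  bf <- signal::butter(order, cutoff_hz / nyq, type = "high")
  out <- as.numeric(signal::filter(bf, rec$samples))
  audio_recording(out, rec$sample_rate, rec$label)
}

#' Single-sided amplitude spectrum
#'
#' Plain FFT of the full segment (rectangular window), folded to a
#' single-sided amplitude spectrum. Scaling is 2/N for interior bins and
#' 1/N for DC and (when N is even) Nyquist, so a unit-amplitude sinusoid
#' at an exact bin frequency shows amplitude 1.0.
#'
#' @param rec An `avf_audio` object (non-empty).
#' @return An `amplitude_spectrum`: list with `frequencies` (Hz, from 0 to
#'   Nyquist) and `amplitudes` (non-negative, same length).
#' @export
compute_spectrum <- function(rec) {
  stopifnot(inherits(rec, "avf_audio"))
  n <- length(rec$samples)
  if (n < 1L) stop("cannot compute the spectrum of an empty recording")
  sp <- stats::fft(rec$samples)
  n_half <- floor(n / 2) + 1L               # bins 0 .. Nyquist (or just below)
  amp <- Mod(sp[seq_len(n_half)]) / n
  scale2 <- rep(2, n_half)
  scale2[1L] <- 1                           # DC
  if (n %% 2 == 0) scale2[n_half] <- 1      # Nyquist bin present only for even N
  amp <- amp * scale2
  structure(list(frequencies = (seq_len(n_half) - 1) * rec$sample_rate / n,
                 amplitudes = amp),
            class = "amplitude_spectrum")
}

#' @export
print.amplitude_spectrum <- function(x, ...) {
  cat(sprintf("<amplitude_spectrum> %d bins, 0-%g Hz, resolution %g Hz\n",
              length(x$frequencies), max(x$frequencies),
              x$frequencies[2] - x$frequencies[1]))
  invisible(x)
}

#' Maximum spectral peak within a frequency band
#'
#' Finds the bin of maximum amplitude with frequency in `[f_min, f_max]`
#' (both endpoints inclusive). Ties are broken toward the lowest frequency.
#'
#' @param spec An `amplitude_spectrum`.
#' @param f_min,f_max Band edges in Hz.
#' @param band Optional band tag stored in the result (`"low"`, `"high"`,
#'   `"global"`).
#' @return A `band_peak`: list with `frequency`, `amplitude`, `band`.
#' @export
find_band_peak <- function(spec, f_min, f_max, band = "global") {
  stopifnot(inherits(spec, "amplitude_spectrum"))
  idx <- which(spec$frequencies >= f_min & spec$frequencies <= f_max)
  if (length(idx) == 0L)
    stop(sprintf("band [%g, %g] Hz contains no spectral bins", f_min, f_max))
  best <- idx[which.max(spec$amplitudes[idx])]   # which.max -> first (lowest f)
  structure(list(frequency = spec$frequencies[best],
                 amplitude = spec$amplitudes[best],
                 band = band),
            class = "band_peak")
}

#' High-low peak ratio (HLPR) of a spectrum
#'
#' HLPR is the amplitude of the maximum spectral peak in the high band
#' (500-700 Hz) divided by that in the low band (100-250 Hz). High-frequency
#' content in the AVF bruit marks disturbed, recirculating flow, so a large
#' HLPR flags a hemodynamically disturbed fistula. The ratio is invariant to
#' any positive rescaling of the waveform and to the spectrum scaling
#' convention.
#'
#' @param spec An `amplitude_spectrum`.
#' @param low Low band edges in Hz, default `c(100, 250)`.
#' @param high High band edges in Hz, default `c(500, 700)`.
#' @return A list (`hlpr_result`) with `hlpr`, `low_peak`, `high_peak`.
#' @export
compute_hlpr <- function(spec, low = c(100, 250), high = c(500, 700)) {
  lp <- find_band_peak(spec, low[1], low[2], band = "low")
  hp <- find_band_peak(spec, high[1], high[2], band = "high")
  if (lp$amplitude == 0)
    stop("low-band peak amplitude is zero; HLPR is undefined")
  structure(list(hlpr = hp$amplitude / lp$amplitude,
                 low_peak = lp, high_peak = hp),
            class = "hlpr_result")
}

#' @export
print.hlpr_result <- function(x, ...) {
  cat(sprintf("HLPR %.4f  (H %.4g @ %g Hz / L %.4g @ %g Hz)\n",
              x$hlpr, x$high_peak$amplitude, x$high_peak$frequency,
              x$low_peak$amplitude, x$low_peak$frequency))
  invisible(x)
}

#' Global maximum spectral amplitude above a frequency floor
#'
#' The overall loudest spectral component of the bruit, excluding content
#' at or below `f_floor` (the high-pass region). This is the amplitude
#' statistic regressed against brachial blood flow volume.
#'
#' @param spec An `amplitude_spectrum`.
#' @param f_floor Frequencies at or below this (Hz) are excluded; default 50.
#' @return Maximum amplitude (spectrum units).
#' @export
max_peak_amplitude <- function(spec, f_floor = 50) {
  stopifnot(inherits(spec, "amplitude_spectrum"))
  idx <- which(spec$frequencies > f_floor)
  if (length(idx) == 0L)
    stop(sprintf("spectrum has no content above %g Hz", f_floor))
  max(spec$amplitudes[idx])
}

#' Full acoustic feature extraction for one recording
#'
#' Runs the whole chain (trim to the standard duration, high-pass filter,
#' FFT, band peaks, HLPR, maximum peak amplitude) on one recording.
#'
#' @param rec An `avf_audio` object.
#' @param duration_s Trim duration (s), default 4.
#' @param cutoff_hz High-pass cutoff (Hz), default 50.
#' @param order High-pass order, default 4.
#' @param low,high Band edges in Hz.
#' @param f_floor Floor for the global peak search (Hz), default 50.
#' @return One-row `data.frame`: label, low/high peak frequency and
#'   amplitude, hlpr, max_peak_amplitude.
#' @export
analyze_recording <- function(rec, duration_s = 4, cutoff_hz = 50, order = 4,
                              low = c(100, 250), high = c(500, 700),
                              f_floor = 50) {
  spec <- compute_spectrum(highpass_50hz(trim_to_standard(rec, duration_s),
                                         cutoff_hz, order))
  hl <- compute_hlpr(spec, low, high)
  data.frame(label = rec$label,
             low_peak_hz = hl$low_peak$frequency,
             low_peak_amp = hl$low_peak$amplitude,
             high_peak_hz = hl$high_peak$frequency,
             high_peak_amp = hl$high_peak$amplitude,
             hlpr = hl$hlpr,
             max_peak_amplitude = max_peak_amplitude(spec, f_floor),
             stringsAsFactors = FALSE)
}
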