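test_that("trimming takes the centered window of the requested duration", {
  # 5 s at 4000 Hz -> 16000 samples offset by 2000; 6.5 s at 8000 Hz ->
  # 32000 samples starting at sample 10000 (0-based)
  cases <- list(list(fs = 4000, dur = 5.0, offset = 2000),
                list(fs = 8000, dur = 6.5, offset = 10000))
  for (cs in cases) {
    rec <- audio_recording(seq_len(cs$dur * cs$fs), cs$fs)
    out <- trim_to_standard(rec, 4)
    expect_length(out$samples, 4 * cs$fs)
    expect_equal(out$samples[1], cs$offset + 1)
    expect_equal(out$samples[length(out$samples)], cs$offset + 4 * cs$fs)
  }
  # exact-length input passes through unchanged
  rec4 <- audio_recording(rnorm(4 * 4000), 4000)
  expect_identical(trim_to_standard(rec4, 4)$samples, rec4$samples)
  expect_error(trim_to_standard(audio_recording(rnorm(100), 4000), 4),
               "too short.*0\\.025 s available.*4\\.000 s required")
})

test_that("audio recording invariants are enforced", {
  expect_error(audio_recording(numeric(0), 4000), "at least one sample")
  expect_error(audio_recording(c(1, NA), 4000), "finite")
  expect_error(audio_recording(1:10, -1), "positive")
})

test_that("high-pass filter kills DC and rejects cutoff at/above Nyquist", {
  rec <- audio_recording(rep(1, 4 * 4000), 4000)
  out <- highpass_50hz(rec)
  expect_length(out$samples, length(rec$samples))
  expect_lt(max(abs(out$samples[8001:16000])), 1e-6)
  expect_error(highpass_50hz(audio_recording(rnorm(100), 90), cutoff_hz = 50),
               "Nyquist")
})

test_that("filter steady-state gain matches the analytic Butterworth curve", {
  fs <- 4000
  t <- (0:(8 * fs - 1)) / fs
  probes <- c(30, 40, 50, 60, 70, 100, 150, 250, 600, 1500)
  for (f in probes) {
    rec <- audio_recording(sin(2 * pi * f * t), fs)
    got <- steady_state_amplitude(highpass_50hz(rec)$samples, f, fs)
    expect_equal(got, butter_hp_gain(f, 50, fs), tolerance = 0.01,
                 label = sprintf("gain at %g Hz", f))
  }
  # -3 dB point: unit 50 Hz sinusoid comes out at ~0.708
  rec50 <- audio_recording(sin(2 * pi * 50 * t), fs)
  expect_equal(steady_state_amplitude(highpass_50hz(rec50)$samples, 50, fs),
               1 / sqrt(2), tolerance = 0.01)
  # deep passband: 600 Hz essentially untouched
  rec600 <- audio_recording(sin(2 * pi * 600 * t), fs)
  expect_gte(steady_state_amplitude(highpass_50hz(rec600)$samples, 600, fs),
             0.999)
})

test_that("spectrum scaling puts a unit bin-aligned sinusoid at amplitude 1", {
  fs <- 4000
  t <- (0:(4 * fs - 1)) / fs
  spec <- compute_spectrum(audio_recording(
    0.8 * sin(2 * pi * 150 * t) + 0.4 * sin(2 * pi * 600 * t), fs))
  expect_equal(spec$frequencies[1], 0)
  expect_lte(max(spec$frequencies), fs / 2)
  expect_true(all(spec$amplitudes >= 0))
  expect_equal(spec$amplitudes[spec$frequencies == 150], 0.8,
               tolerance = 1e-9)
  expect_equal(spec$amplitudes[spec$frequencies == 600], 0.4,
               tolerance = 1e-9)
  # a pure unit tone peaks at exactly 1
  spec1 <- compute_spectrum(audio_recording(sin(2 * pi * 150 * t), fs))
  pk <- find_band_peak(spec1, 100, 250)
  expect_equal(pk$frequency, 150)
  expect_equal(pk$amplitude, 1, tolerance = 1e-9)
  # zero signal -> all-zero spectrum
  expect_true(all(compute_spectrum(
    audio_recording(numeric(100) , fs))$amplitudes == 0))
})

test_that("Parseval consistency holds for the documented scaling", {
  set.seed(11)
  for (n in c(4000, 4001)) {          # even and odd lengths
    x <- rnorm(n)
    spec <- compute_spectrum(audio_recording(x, 4000))
    a <- spec$amplitudes
    w <- rep(0.5, length(a))
    w[1] <- 1
    if (n %% 2 == 0) w[length(a)] <- 1
    expect_equal(n * sum(w * a^2), sum(x^2), tolerance = 1e-8)
  }
})

test_that("band peaks honor inclusive endpoints and low-frequency tie-break", {
  spec <- structure(list(frequencies = seq(0, 1000, by = 10),
                         amplitudes = rep(0, 101)),
                    class = "amplitude_spectrum")
  # flat zero spectrum -> amplitude 0 at the band's lowest bin
  pk <- find_band_peak(spec, 100, 250)
  expect_equal(pk$amplitude, 0)
  expect_equal(pk$frequency, 100)
  # two equal maxima at 520 and 680 -> the lower one wins
  spec$amplitudes[spec$frequencies == 520] <- 1
  spec$amplitudes[spec$frequencies == 680] <- 1
  expect_equal(find_band_peak(spec, 500, 700)$frequency, 520)
  expect_error(find_band_peak(spec, 1500, 1600), "no spectral bins")
})

test_that("HLPR is the high/low band peak ratio and scale-invariant", {
  fs <- 4000
  t <- (0:(4 * fs - 1)) / fs
  x <- 0.8 * sin(2 * pi * 150 * t) + 0.4 * sin(2 * pi * 600 * t)
  res <- compute_hlpr(compute_spectrum(audio_recording(x, fs)))
  expect_equal(res$hlpr, 0.5, tolerance = 1e-9)
  expect_equal(res$hlpr,
               res$high_peak$amplitude / res$low_peak$amplitude)
  # positive rescaling leaves the ratio untouched (random signals)
  set.seed(21)
  for (i in 1:5) {
    y <- rnorm(4 * fs)
    c0 <- compute_hlpr(compute_spectrum(audio_recording(y, fs)))$hlpr
    cc <- compute_hlpr(compute_spectrum(audio_recording(y * 137.2, fs)))$hlpr
    expect_equal(cc, c0, tolerance = 1e-10)
  }
  # high band silent -> HLPR 0; low band silent -> error
  lo_only <- compute_spectrum(audio_recording(sin(2 * pi * 150 * t), fs))
  expect_equal(compute_hlpr(lo_only)$hlpr, 0)
  hi_only <- structure(list(frequencies = seq(0, 1000, by = 10),
                            amplitudes = c(rep(0, 55), rep(1, 46))),
                       class = "amplitude_spectrum")   # silent below 550 Hz
  expect_error(compute_hlpr(hi_only), "undefined")
})

test_that("global peak amplitude respects the frequency floor and scales linearly", {
  fs <- 4000
  t <- (0:(4 * fs - 1)) / fs
  x <- 0.9 * sin(2 * pi * 30 * t) + 0.2 * sin(2 * pi * 200 * t)
  spec <- compute_spectrum(audio_recording(x, fs))
  expect_equal(max_peak_amplitude(spec, f_floor = 50), 0.2, tolerance = 1e-9)
  x2 <- 0.8 * sin(2 * pi * 150 * t) + 0.4 * sin(2 * pi * 600 * t)
  spec2 <- compute_spectrum(audio_recording(x2, fs))
  spec3 <- compute_spectrum(audio_recording(3 * x2, fs))
  expect_equal(max_peak_amplitude(spec2), 0.8, tolerance = 1e-9)
  expect_equal(max_peak_amplitude(spec3), 3 * max_peak_amplitude(spec2),
               tolerance = 1e-9)
})
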