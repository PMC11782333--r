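# Synthetic inputs with the statistical structure the analysis assumes:
# cardiac-modulated two-band phonoangiograms, pulsatile wall-shear fields
# with known OSI, and longitudinal cohorts with a known amplitude-BFV
# slope. All generators are pure functions of their seed.

#' Generate a synthetic phonoangiogram
#'
#' A deliberately minimal bruit model: a sum of sinusoidal components,
#' amplitude-modulated at the cardiac rate with a raised-cosine envelope,
#' plus white Gaussian noise. The modulation scales the low and high band
#' alike, so band-peak logic and the HLPR ratio are exercised without a
#' physical hemoacoustic source model.
#'
#' @param components Two-column matrix or data.frame (frequency Hz,
#'   amplitude); all frequencies must be below Nyquist.
#' @param sample_rate Hz, default 4000 (covers the stethoscope's
#'   20-2000 Hz band with Nyquist margin).
#' @param duration_s Seconds, default 6 (longer than the 4-s analysis
#'   window so trimming is exercised; bedside recordings exceed 5 s).
#' @param heart_rate_bpm Beats per minute, default 70.
#' @param modulation_depth Cardiac amplitude-modulation depth in \[0, 1\],
#'   default 0.3.
#' @param noise_sd White-noise standard deviation, default 0.
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @param label Label for the recording.
#' @return An `avf_audio` object.
#' @export
gen_phonoangiogram <- function(components, sample_rate = 4000,
                               duration_s = 6, heart_rate_bpm = 70,
                               modulation_depth = 0.3, noise_sd = 0,
                               seed = NULL, label = "synthetic") {
  components <- as.matrix(components)
  if (ncol(components) != 2) stop("components must be (frequency, amplitude)")
  if (any(components[, 1] >= sample_rate / 2))
    stop("component frequency at or beyond Nyquist")
  if (any(components[, 2] < 0)) stop("component amplitudes must be >= 0")
  if (modulation_depth < 0 || modulation_depth > 1)
    stop("modulation_depth must be in [0, 1]")
  n <- round(duration_s * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  x <- numeric(n)
  for (i in seq_len(nrow(components)))
    x <- x + components[i, 2] * sin(2 * pi * components[i, 1] * t)
  # raised-cosine cardiac envelope: mean 1 - depth/2, never negative
  f_card <- heart_rate_bpm / 60
  env <- (1 - modulation_depth) +
    modulation_depth * 0.5 * (1 - cos(2 * pi * f_card * t))
  x <- x * env
  if (noise_sd > 0) {
    if (is.null(seed)) stop("a seed is required when noise_sd > 0")
    set.seed(seed)
    x <- x + stats::rnorm(n, 0, noise_sd)
  }
  audio_recording(x, sample_rate, label)
}

#' Generate a pulsatile wall-shear-stress field with known OSI
#'
#' A chosen fraction of elements receives purely oscillatory shear
#' (zero-mean sinusoid along a random fixed direction, reference
#' OSI = 0.5); the rest receive steady-dominated shear (mean magnitude at
#' least as large as the superimposed oscillation along the same
#' direction, so the shear never reverses: reference OSI = 0). Element
#' areas are drawn uniformly positive.
#'
#' @param n_elements Number of surface elements.
#' @param period_s Cardiac period (s), default 0.857 (70 bpm).
#' @param n_timesteps Time samples over the cycle, default 200.
#' @param mean_mag_range Range (Pa) for the steady mean magnitude,
#'   default `c(0.5, 3)`.
#' @param osc_amp_range Range (Pa) for the oscillation amplitude of
#'   oscillatory elements, default `c(0.5, 2)`.
#' @param fraction_oscillatory Fraction of elements made purely
#'   oscillatory, in \[0, 1\].
#' @param area_range Range (mm^2) for element areas, default `c(0.5, 1.5)`.
#' @param seed Integer seed.
#' @return List with `field` (a `wss_field`) and `reference_osi`
#'   (per-element 0 or 0.5).
#' @export
gen_wss_field <- function(n_elements, period_s = 60 / 70, n_timesteps = 200,
                          mean_mag_range = c(0.5, 3),
                          osc_amp_range = c(0.5, 2),
                          fraction_oscillatory = 0.5,
                          area_range = c(0.5, 1.5), seed) {
  stopifnot(n_elements >= 1, n_timesteps >= 2,
            fraction_oscillatory >= 0, fraction_oscillatory <= 1)
  set.seed(seed)
  times <- seq(0, period_s, length.out = n_timesteps)
  osc <- stats::runif(n_elements) < fraction_oscillatory
  dir <- matrix(stats::rnorm(3 * n_elements), ncol = 3)
  dir <- dir / sqrt(rowSums(dir^2))
  amp <- stats::runif(n_elements, osc_amp_range[1], osc_amp_range[2])
  m <- stats::runif(n_elements, mean_mag_range[1], mean_mag_range[2])
  # steady-dominated elements: oscillation no larger than the mean
  a_steady <- m * stats::runif(n_elements, 0, 1)
  s <- sin(2 * pi * outer(rep(1, n_elements), times) / period_s)
  scalar <- ifelse(osc, 0, m) + ifelse(osc, amp, a_steady) * s
  tau <- array(0, dim = c(n_elements, n_timesteps, 3))
  for (k in 1:3) tau[, , k] <- scalar * dir[, k]
  field <- wss_field(times, tau,
                     stats::runif(n_elements, area_range[1], area_range[2]))
  list(field = field, reference_osi = ifelse(osc, 0.5, 0))
}

#' Generate a longitudinal cohort with known slope and variance components
#'
#' Per patient, a random intercept ~ Normal(0, patient_sd); per visit, a
#' brachial BFV drawn uniformly from `bfv_range` and an acoustic amplitude
#' `y = intercept + slope * BFV + u_patient + Normal(0, residual_sd)`.
#' HLPR tracks the BFV excursion from the mid-range with a specified
#' (negative) coupling plus small visit noise, so consecutive-visit
#' deltas obey `delta HLPR = coupling * delta BFV + noise` with known
#' structure. Defaults
#' mirror the study: 6 patients, 6 scheduled visits, amplitude-BFV slope
#' 0.103 with patient sd 14.97 and residual sd 31.05, brachial BFV in
#' 400-1600 mL/min.
#'
#' @param n_patients Patients (>= 2), default 6.
#' @param visits_per_patient Visits each, default 6 (the full schedule).
#' @param true_slope Amplitude units per mL/min, default 0.103.
#' @param true_intercept Amplitude units, default 50.
#' @param patient_sd Between-patient intercept sd, default 14.97.
#' @param residual_sd Within-patient residual sd, default 31.05.
#' @param bfv_range Brachial BFV range (mL/min), default `c(400, 1600)`.
#' @param hlpr_base HLPR at the BFV mid-range, default 0.7 (keeps HLPR
#'   positive across the default BFV range).
#' @param hlpr_coupling HLPR change per mL/min of BFV change, default
#'   -0.001 (a negative visit-to-visit association between the two
#'   deltas).
#' @param hlpr_noise_sd Visit-to-visit HLPR noise sd, default 0.02.
#' @param seed Integer seed.
#' @return List with `records` (visit-level `data.frame`: `patient_id`,
#'   `visit`, `hlpr`, `max_peak_amplitude`, `brachial_bfv_ml_min`) and
#'   `truth` (the generating parameters plus per-patient intercepts).
#' @export
gen_cohort <- function(n_patients = 6, visits_per_patient = 6,
                       true_slope = 0.103, true_intercept = 50,
                       patient_sd = 14.97, residual_sd = 31.05,
                       bfv_range = c(400, 1600),
                       hlpr_base = 0.7, hlpr_coupling = -0.001,
                       hlpr_noise_sd = 0.02, seed) {
  stopifnot(n_patients >= 2, visits_per_patient >= 1,
            patient_sd >= 0, residual_sd >= 0)
  set.seed(seed)
  visits <- VISIT_LEVELS[seq_len(min(visits_per_patient, length(VISIT_LEVELS)))]
  u <- stats::rnorm(n_patients, 0, patient_sd)
  rows <- lapply(seq_len(n_patients), function(p) {
    bfv <- stats::runif(length(visits), bfv_range[1], bfv_range[2])
    amp <- true_intercept + true_slope * bfv + u[p] +
      stats::rnorm(length(visits), 0, residual_sd)
    hlpr <- pmax(hlpr_base + hlpr_coupling * (bfv - mean(bfv_range)) +
                   stats::rnorm(length(visits), 0, hlpr_noise_sd), 1e-3)
    data.frame(patient_id = sprintf("P%02d", p), visit = visits,
               hlpr = hlpr, max_peak_amplitude = amp,
               brachial_bfv_ml_min = bfv)
  })
  list(records = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       truth = list(slope = true_slope, intercept = true_intercept,
                    patient_sd = patient_sd, residual_sd = residual_sd,
                    hlpr_coupling = hlpr_coupling, patient_intercepts = u))
}

#' Published per-patient HLPR and high-OSI-area table
#'
#' The 12 patient-visit rows (patients P1-P4 at 3 days, 3 weeks and
#' 1 year) pairing each HLPR with the percentage of lumen area at
#' OSI > 0.1, for the published longitudinal cohort. This fixture drives
#' the median-split subgroup comparison.
#'
#' @return `data.frame` with `patient_id`, `visit`, `hlpr`,
#'   `osi_area_percent`.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_hlpr_osi.csv", package = "avfsound",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
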