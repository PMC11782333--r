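# Independent oracles used across tests.

# Scalar-quadrature OSI for tau(t) = m + a sin(2 pi t / T) along a fixed
# direction, via adaptive quadrature (independent of the trapezoid code).
osi_quadrature_oracle <- function(m, a, T = 60 / 70) {
  int_abs <- stats::integrate(function(t) abs(m + a * sin(2 * pi * t / T)),
                              0, T, subdivisions = 2000L,
                              rel.tol = 1e-12)$value
  0.5 * (1 - abs(m * T) / int_abs)
}

# Wrap a 1-D scalar shear history into a single-element wss_field.
scalar_wss_field <- function(scalar, times, direction = c(1, 0, 0), area = 1) {
  tau <- array(0, dim = c(1, length(times), 3))
  for (k in 1:3) tau[1, , k] <- scalar * direction[k]
  wss_field(times, tau, area)
}

# Analytic magnitude response of an order-n Butterworth high-pass,
# evaluated on the bilinear-transform (prewarped) frequency axis so it is
# the exact steady-state gain of the implemented digital filter.
butter_hp_gain <- function(f, cutoff, fs, order = 4) {
  ratio <- tan(pi * cutoff / fs) / tan(pi * f / fs)
  1 / sqrt(1 + ratio^(2 * order))
}

# Steady-state amplitude of a sinusoid at frequency f in a signal,
# measured by synchronous demodulation over an integer number of cycles
# after discarding a settling transient.
steady_state_amplitude <- function(x, f, fs, settle_s = 1) {
  i0 <- round(settle_s * fs) + 1
  x <- x[i0:length(x)]
  n_cyc <- floor(length(x) * f / fs)
  n_use <- round(n_cyc * fs / f)
  x <- x[seq_len(n_use)]
  t <- (seq_along(x) - 1) / fs
  2 * Mod(mean(x * exp(-2i * pi * f * t)))
}
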