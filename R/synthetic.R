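#' Specification of a synthetic ECG-like waveform
#'
#' Describes a quasi-periodic train of heartbeats, each beat the sum of five
#' Gaussian bumps standing in for the P, Q, R, S and T waves, with
#' beat-to-beat interval jitter and additive white noise.  The defaults give a
#' physiologically plausible adult resting trace of the clean clinical class:
#' 72 bpm with 3 bpm variability, a 1.1 mV R peak, and 0.005 mV measurement
#' noise at 250 Hz (the noise scale implied by published sub-0.005 mV one-step
#' forecast errors on Holter recordings).
#'
#' @param duration_s Length of the generated trace in seconds.
#' @param fs Sampling rate in Hz.
#' @param mean_hr_bpm Mean heart rate, beats/minute.
#' @param hr_sd_bpm Heart-rate standard deviation, beats/minute; beat-to-beat
#'   RR intervals are drawn Normal(60/mean_hr, scaled sd), truncated positive.
#' @param wave_params 5 x 3 numeric matrix, one row per wave (P, Q, R, S, T),
#'   columns: amplitude (mV), Gaussian width (s), offset from the R peak (s).
#' @param noise_sd Additive white-noise standard deviation (mV).
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return A list of class `synth_ecg_spec`.
#' @export
synth_ecg_spec <- function(duration_s = 8, fs = 250, mean_hr_bpm = 72,
                           hr_sd_bpm = 3,
                           wave_params = default_wave_params(),
                           noise_sd = 0.005, seed = 1L) {
  wave_params <- as.matrix(wave_params)
  stopifnot(duration_s > 0, fs > 0, mean_hr_bpm > 0, hr_sd_bpm >= 0,
            noise_sd >= 0, nrow(wave_params) == 5L, ncol(wave_params) == 3L,
            all(wave_params[, 2] > 0))
  structure(list(duration_s = duration_s, fs = fs,
                 mean_hr_bpm = mean_hr_bpm, hr_sd_bpm = hr_sd_bpm,
                 wave_params = wave_params, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_ecg_spec")
}

#' @rdname synth_ecg_spec
#' @export
default_wave_params <- function() {
  matrix(c(
    0.12, 0.030, -0.200,   # P
   -0.12, 0.012, -0.028,   # Q
    1.10, 0.014,  0.000,   # R
   -0.18, 0.012,  0.030,   # S
    0.28, 0.055,  0.260),  # T
    nrow = 5, byrow = TRUE,
    dimnames = list(c("P", "Q", "R", "S", "T"),
                    c("amp_mV", "width_s", "offset_s")))
}

#' Generate a synthetic ECG-like signal
#'
#' Draws beat onsets from the RR-interval model of the spec, renders each beat
#' as the sum of its five Gaussian bumps, and adds white Gaussian noise.
#' Deterministic given the spec (including its seed).
#'
#' @param spec A [synth_ecg_spec()].
#' @return An [ecg_signal] with `fs = spec$fs`.
#' @examples
#' s <- synth_ecg(synth_ecg_spec(duration_s = 4, seed = 42))
#' @export
synth_ecg <- function(spec) {
  stopifnot(inherits(spec, "synth_ecg_spec"))
  with_seed(spec$seed, {
    rr_mean <- 60 / spec$mean_hr_bpm
    rr_sd <- 60 * spec$hr_sd_bpm / spec$mean_hr_bpm^2
    t_end <- spec$duration_s
    # beat times; start half a mean interval in, pad one beat past the end
    beats <- numeric(0)
    t_beat <- rr_mean / 2
    while (t_beat < t_end + rr_mean) {
      beats <- c(beats, t_beat)
      rr <- if (rr_sd > 0) stats::rnorm(1, rr_mean, rr_sd) else rr_mean
      rr <- max(rr, 0.2 * rr_mean)       # truncate: keep positive, sane
      t_beat <- t_beat + rr
    }
    tt <- seq(0, t_end - 1 / spec$fs, by = 1 / spec$fs)
    x <- numeric(length(tt))
    wp <- spec$wave_params
    for (b in beats)
      for (w in seq_len(nrow(wp)))
        x <- x + wp[w, 1] * exp(-(tt - b - wp[w, 3])^2 / (2 * wp[w, 2]^2))
    if (spec$noise_sd > 0)
      x <- x + stats::rnorm(length(x), 0, spec$noise_sd)
    ecg_signal(x, fs = spec$fs, name = sprintf("synth_ecg_seed%d", spec$seed))
  })
}

#' Mixture of cosine tones
#'
#' `sum_i amps[i] * cos(2 pi freqs[i] t)` for t = 0..n-1, plus optional white
#' Gaussian noise.  The standard oracle input for the mode-decomposition
#' tests: each tone should be recovered as one narrow-band mode.
#'
#' @param freqs Frequencies in cycles/sample, each in (0, 0.5).
#' @param amps Amplitudes, same length as `freqs`.
#' @param n Number of samples.
#' @param noise_sd White-noise standard deviation (default 0).
#' @param seed Integer seed for the noise.
#' @return An [ecg_signal] (unit-less amplitudes).
#' @export
tone_mixture <- function(freqs, amps, n, noise_sd = 0, seed = 1L) {
  if (length(freqs) == 0L) stop("freqs must be non-empty", call. = FALSE)
  if (length(freqs) != length(amps))
    stop("freqs and amps must have equal length", call. = FALSE)
  if (any(freqs <= 0 | freqs >= 0.5))
    stop("frequencies must lie strictly inside (0, 0.5) cycles/sample",
         call. = FALSE)
  t <- 0:(n - 1)
  x <- numeric(n)
  for (i in seq_along(freqs)) x <- x + amps[i] * cos(2 * pi * freqs[i] * t)
  if (noise_sd > 0)
    x <- x + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  ecg_signal(x, name = "tone_mixture")
}

#' Lorenz-63 x-component
#'
#' Integrates the Lorenz-63 system (sigma = 10, rho = 28, beta = 8/3) with a
#' fixed-step fourth-order Runge--Kutta scheme, discards `n_transient` initial
#' steps so the trajectory has settled onto the attractor, and returns the x
#' component.  A standard chaotic fixture whose minimal embedding dimension is
#' 3, used to exercise the false-nearest-neighbour selector.
#'
#' @param n Number of samples returned (at least 100).
#' @param dt Integration step, in (0, 0.05].
#' @param initial Numeric length-3 initial state.
#' @param n_transient Number of leading integration steps discarded.
#' @return Numeric vector of length `n`.
#' @export
lorenz63 <- function(n, dt = 0.01, initial = c(1, 1, 1), n_transient = 1000L) {
  stopifnot(n >= 100L, dt > 0, dt <= 0.05, length(initial) == 3L,
            n_transient >= 0L)
  sig <- 10; rho <- 28; beta <- 8 / 3
  f <- function(s) c(sig * (s[2] - s[1]),
                     s[1] * (rho - s[3]) - s[2],
                     s[1] * s[2] - beta * s[3])
  s <- as.numeric(initial)
  total <- n + n_transient
  out <- numeric(n)
  for (i in seq_len(total)) {
    k1 <- f(s)
    k2 <- f(s + dt / 2 * k1)
    k3 <- f(s + dt / 2 * k2)
    k4 <- f(s + dt * k3)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (i > n_transient) out[i - n_transient] <- s[1]
  }
  out
}
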