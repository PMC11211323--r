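# Synthetic 12-lead ECG generator.
#
# Beats are a per-lead sum of three Gaussian deflections (P, QRS, T) placed
# at exactly 60/heart_rate_bpm intervals, plus optional white noise and
# sinusoidal baseline wander.  The template is deliberately simple: the
# downstream stages only need detectable R-peaks and a morphology parameter
# (QRS width) that can covary with outcome.

#' Default per-lead wave amplitudes
#'
#' A 12 x 3 matrix (rows = standard lead order I, II, III, aVR, aVL, aVF,
#' V1-V6; columns = P, QRS, T) of component amplitudes in millivolts,
#' loosely following normal adult lead polarity (negative QRS in aVR and V1).
#'
#' @return A numeric 12 x 3 matrix with dimnames.
#' @export
default_wave_amplitudes <- function() {
  qrs <- c(0.6, 1.0, 0.5, -0.9, 0.2, 0.7, -0.4, 0.5, 0.9, 1.2, 1.0, 0.8)
  p <- c(0.08, 0.12, 0.06, -0.10, 0.03, 0.08, 0.04, 0.05, 0.06, 0.07, 0.06, 0.05)
  t <- c(0.20, 0.30, 0.15, -0.25, 0.08, 0.22, -0.10, 0.15, 0.30, 0.35, 0.30, 0.25)
  m <- cbind(P = p, QRS = qrs, T = t)
  rownames(m) <- lead_names_12()
  m
}

#' Parameters for the synthetic ECG generator
#'
#' @param heart_rate_bpm Heart rate in beats per minute.
#' @param duration_s Record duration in seconds (default 10, the standard
#'   resting-ECG length).
#' @param fs_hz Sampling frequency in Hz (default 500).
#' @param wave_amplitudes 12 x 3 matrix of P/QRS/T amplitudes per lead (mV).
#' @param qrs_width_ms Total QRS duration in milliseconds; the QRS Gaussian
#'   standard deviation is `qrs_width_ms / 6` so that +-3 SD spans the width.
#' @param noise_sd_mv Standard deviation of additive white noise (mV).
#' @param wander_amp_mv Amplitude of sinusoidal baseline wander (mV).
#' @param wander_freq_hz Baseline-wander frequency; must stay below the
#'   0.5 Hz cutoff the preprocessing stage removes.
#' @param seed Integer seed; identical parameters and seed give a
#'   bit-identical record.
#'
#' @return An object of class `ecg_sim_params`.
#' @export
ecg_sim_params <- function(heart_rate_bpm = 60, duration_s = 10, fs_hz = 500,
                           wave_amplitudes = default_wave_amplitudes(),
                           qrs_width_ms = 90, noise_sd_mv = 0.02,
                           wander_amp_mv = 0.1, wander_freq_hz = 0.3,
                           seed = 1L) {
  assert_that(is_scalar_num(heart_rate_bpm) && heart_rate_bpm > 0,
              "heart_rate_bpm must be a positive number")
  assert_that(is_scalar_num(duration_s) && duration_s > 0,
              "duration_s must be a positive number")
  assert_that(is_scalar_num(fs_hz) && fs_hz > 0, "fs_hz must be positive")
  n <- duration_s * fs_hz
  assert_that(abs(n - round(n)) < 1e-8,
              "duration_s * fs_hz must be an integer sample count")
  assert_that(is.matrix(wave_amplitudes) && all(dim(wave_amplitudes) == c(12, 3)),
              "wave_amplitudes must be a 12 x 3 matrix")
  assert_that(is_scalar_num(qrs_width_ms) && qrs_width_ms > 0,
              "qrs_width_ms must be positive")
  assert_that(is_scalar_num(noise_sd_mv) && noise_sd_mv >= 0,
              "noise_sd_mv must be non-negative")
  assert_that(is_scalar_num(wander_amp_mv) && wander_amp_mv >= 0,
              "wander_amp_mv must be non-negative")
  assert_that(is_scalar_num(wander_freq_hz) && wander_freq_hz > 0 &&
                wander_freq_hz < 0.5,
              "wander_freq_hz must lie in (0, 0.5)")
  structure(list(heart_rate_bpm = heart_rate_bpm, duration_s = duration_s,
                 fs_hz = fs_hz, wave_amplitudes = wave_amplitudes,
                 qrs_width_ms = qrs_width_ms, noise_sd_mv = noise_sd_mv,
                 wander_amp_mv = wander_amp_mv, wander_freq_hz = wander_freq_hz,
                 seed = as.integer(seed)),
            class = "ecg_sim_params")
}

# Component timing (seconds relative to the R-peak) and widths shared by the
# generator and the template oracle.
ecg_component_layout <- function(qrs_width_ms) {
  list(center = c(P = -0.16, QRS = 0, T = 0.28),
       sd = c(P = 0.025, QRS = qrs_width_ms / 1000 / 6, T = 0.05))
}

#' Noise-free beat template per lead
#'
#' Evaluates the three-Gaussian P-QRS-T template at times `t_rel` (seconds
#' relative to the R-peak) for every lead.  Used by the generator and as the
#' ground-truth oracle in preprocessing tests.
#'
#' @param params An [ecg_sim_params()] object.
#' @param t_rel Numeric vector of times relative to the R-peak, in seconds.
#' @return A 12 x length(t_rel) matrix of millivolt amplitudes.
#' @export
ecg_beat_template <- function(params, t_rel) {
  lay <- ecg_component_layout(params$qrs_width_ms)
  out <- matrix(0, nrow = 12, ncol = length(t_rel))
  for (k in 1:3) {
    g <- exp(-0.5 * ((t_rel - lay$center[k]) / lay$sd[k])^2)
    out <- out + params$wave_amplitudes[, k, drop = FALSE] %*% matrix(g, nrow = 1)
  }
  rownames(out) <- rownames(params$wave_amplitudes)
  out
}

#' Simulate a 12-lead resting ECG
#'
#' Generates a `duration_s`-second, 12-channel record with beats at exactly
#' `60 / heart_rate_bpm` second intervals.  The true R-peak sample indices
#' are attached as attribute `r_peaks` for oracle checks.
#'
#' @param params An [ecg_sim_params()] object.
#' @return An [ecg_record()] with attributes `r_peaks` (true R-peak sample
#'   indices) and `sim_params`.
#' @export
simulate_ecg <- function(params) {
  stopifnot(inherits(params, "ecg_sim_params"))
  fs <- params$fs_hz
  n <- as.integer(round(params$duration_s * fs))
  t <- (seq_len(n) - 1) / fs
  rr <- 60 / params$heart_rate_bpm
  beat_times <- seq(rr / 2, params$duration_s - 1e-9, by = rr)
  sig <- matrix(0, nrow = 12, ncol = n)
  for (bt in beat_times) {
    # template support is ~[-0.3, +0.5] s; evaluate only there for speed
    idx <- which(t >= bt - 0.35 & t <= bt + 0.55)
    sig[, idx] <- sig[, idx] + ecg_beat_template(params, t[idx] - bt)
  }
  with_seed(params$seed, {
    if (params$noise_sd_mv > 0) {
      sig <- sig + matrix(rnorm(12 * n, sd = params$noise_sd_mv), nrow = 12)
    }
    if (params$wander_amp_mv > 0) {
      phase <- runif(12, 0, 2 * pi)
      wander <- params$wander_amp_mv *
        sin(outer(phase, rep(1, n)) + 2 * pi * params$wander_freq_hz *
              outer(rep(1, 12), t))
      sig <- sig + wander
    }
  })
  rec <- ecg_record(sig, fs_hz = fs)
  attr(rec, "r_peaks") <- as.integer(round(beat_times * fs)) + 1L
  attr(rec, "sim_params") <- params
  rec
}
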