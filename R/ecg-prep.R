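# 12-lead ECG preprocessing: downsampling to 250 Hz, Savitzky-Golay
# smoothing, truncated-Fourier baseline removal, R-peak marking and
# template-aligned mean P-QRS-T beat extraction.

#' Construct a 12-lead ECG record
#'
#' @param signals 12 x T numeric matrix (millivolts), one row per lead.
#' @param fs_hz Sampling frequency in Hz.
#' @param lead_names Lead labels; defaults to the standard 12-lead order.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(signals, fs_hz, lead_names = lead_names_12()) {
  assert_that(is.matrix(signals) && nrow(signals) == 12,
              "signals must be a 12 x T matrix")
  assert_that(is_scalar_num(fs_hz) && fs_hz > 0, "fs_hz must be positive")
  assert_that(length(lead_names) == 12 && !anyDuplicated(lead_names),
              "lead_names must be 12 unique labels")
  rownames(signals) <- lead_names
  structure(list(signals = signals, fs_hz = fs_hz, lead_names = lead_names),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> 12 leads x %d samples @ %g Hz (%.1f s)\n",
              ncol(x$signals), x$fs_hz, ncol(x$signals) / x$fs_hz))
  invisible(x)
}

#' Downsample an ECG record
#'
#' Zero-phase Fourier resampling of every lead to `target_fs`: the
#' spectrum is truncated at the new Nyquist frequency (the anti-aliasing
#' step) and inverted onto the shorter sample grid, so no group delay is
#' introduced.  Upsampling is refused: the preprocessing chain only ever
#' reduces rate.
#'
#' @param rec An [ecg_record()].
#' @param target_fs Target sampling frequency (default 250 Hz).
#' @return An [ecg_record()] at `target_fs`.
#' @export
ecg_resample <- function(rec, target_fs = 250) {
  stopifnot(inherits(rec, "ecg_record"))
  assert_that(rec$fs_hz >= target_fs,
              "upsampling is not supported: record rate is below target_fs")
  if (rec$fs_hz == target_fs) return(rec)
  n_out <- as.integer(round(ncol(rec$signals) * target_fs / rec$fs_hz))
  out <- t(apply(rec$signals, 1, fft_resample, n_out = n_out))
  ecg_record(out, fs_hz = target_fs, lead_names = rec$lead_names)
}

# Fourier-domain resampling to n_out samples (spectral truncation).
fft_resample <- function(x, n_out) {
  n <- length(x)
  X <- stats::fft(x)
  K <- n_out %/% 2
  Y <- complex(n_out)
  Y[1] <- X[1]
  if (K >= 1) {
    Y[2:(K + 1)] <- X[2:(K + 1)]
    Y[(n_out - K + 1):n_out] <- X[(n - K + 1):n]
  }
  if (n_out %% 2 == 0) Y[K + 1] <- Re(X[K + 1])  # fold the Nyquist bin
  Re(stats::fft(Y, inverse = TRUE)) / n
}

# Truncated Fourier-series baseline of a single lead: the inverse FFT of
# the components strictly below `cutoff_hz` (DC included).
fourier_baseline <- function(x, fs, cutoff_hz) {
  n <- length(x)
  X <- stats::fft(x)
  freqs <- (seq_len(n) - 1) / n * fs
  freqs <- pmin(freqs, fs - freqs)  # two-sided
  X[freqs >= cutoff_hz] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Smooth and detrend an ECG record
#'
#' Per lead: Savitzky-Golay smoothing (high-order local polynomial fit)
#' followed by subtraction of a low-resolution Fourier-series fit of the
#' lead, removing baseline wander below `baseline_cutoff_hz`.
#'
#' @param rec An [ecg_record()] (expected at 250 Hz).
#' @param sg_window Savitzky-Golay window length in samples (odd; default
#'   31, about 124 ms at 250 Hz — wide enough to suppress high-frequency
#'   noise).
#' @param sg_order Savitzky-Golay polynomial order (default 7; a high
#'   order is needed so the local fit can follow the narrow QRS complex
#'   without attenuating it).
#' @param baseline_cutoff_hz Frequencies below this are treated as baseline
#'   and subtracted (default 0.5 Hz).
#' @return A detrended [ecg_record()].
#' @export
ecg_denoise <- function(rec, sg_window = 31, sg_order = 7,
                        baseline_cutoff_hz = 0.5) {
  stopifnot(inherits(rec, "ecg_record"))
  assert_that(sg_window %% 2 == 1, "sg_window must be odd")
  assert_that(sg_window <= ncol(rec$signals),
              "sg_window longer than the signal")
  out <- rec$signals
  filt <- cached_sgolay(sg_order, sg_window)
  for (i in 1:12) {
    sm <- signal::sgolayfilt(out[i, ], filt)
    out[i, ] <- sm - fourier_baseline(sm, rec$fs_hz, baseline_cutoff_hz)
  }
  ecg_record(out, fs_hz = rec$fs_hz, lead_names = rec$lead_names)
}

# The Savitzky-Golay projection matrix costs an SVD to build, so cache it
# per (order, window) pair for the cohort-scale preprocessing loops.
.sgolay_cache <- new.env(parent = emptyenv())
cached_sgolay <- function(p, n) {
  key <- paste(p, n, sep = "_")
  if (is.null(.sgolay_cache[[key]])) {
    .sgolay_cache[[key]] <- signal::sgolay(p = p, n = n)
  }
  .sgolay_cache[[key]]
}

#' Mark R-peak locations
#'
#' Squared-derivative energy detector with moving-window integration and an
#' adaptive threshold (Pan-Tompkins style), run on a single reference lead;
#' the returned indices are shared across leads.  A refractory gap of
#' `min_rr_s` seconds is enforced.
#'
#' @param rec A detrended [ecg_record()].
#' @param ref_lead Lead used for detection (default `"II"`).
#' @param min_rr_s Minimum RR interval in seconds (default 0.2).
#' @return Integer vector of strictly increasing sample indices (possibly
#'   empty when no peak rises above the adaptive threshold).
#' @export
detect_r_peaks <- function(rec, ref_lead = "II", min_rr_s = 0.2) {
  stopifnot(inherits(rec, "ecg_record"))
  fs <- rec$fs_hz
  x <- rec$signals[ref_lead, ]
  d <- diff(x)
  e <- c(d, 0)^2
  w <- max(3L, as.integer(round(0.15 * fs)))
  integ <- stats::filter(e, rep(1 / w, w), sides = 2)
  integ[is.na(integ)] <- 0
  integ <- as.numeric(integ)
  thr <- 0.25 * max(integ)
  if (max(integ) <= 0 || stats::sd(x) < 1e-12) return(integer(0))
  refr <- as.integer(round(min_rr_s * fs))
  above <- integ > thr
  peaks <- integer(0)
  i <- 1L
  n <- length(x)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      # refine: maximum absolute amplitude of the reference lead in a
      # small neighbourhood of the energy burst
      lo <- max(1L, i - 5L); hi <- min(n, j + 5L)
      p <- lo + which.max(abs(x[lo:hi])) - 1L
      if (length(peaks) == 0 || p - peaks[length(peaks)] >= refr) {
        peaks <- c(peaks, p)
      } else if (abs(x[p]) > abs(x[peaks[length(peaks)]])) {
        peaks[length(peaks)] <- p
      }
      i <- j + 1L
    }
    i <- i + 1L
  }
  as.integer(peaks)
}

#' Extract the aligned mean P-QRS-T beat per lead
#'
#' Cuts a fixed window (`pre_ms` before to `post_ms` after each R-peak),
#' drops beats whose windows overrun the record, aligns each beat to the
#' first beat by cross-correlation on the reference lead (the shift is
#' applied to all leads), averages per lead, and normalizes.
#'
#' @param rec A detrended [ecg_record()] at 250 Hz.
#' @param peaks R-peak sample indices from [detect_r_peaks()].
#' @param pre_ms,post_ms Window extent around the R-peak (defaults 200/400
#'   ms, covering P through T at resting rates).
#' @param max_shift Maximum alignment shift in samples (default 10).
#' @param normalize Per-lead normalization: `"zscore"` (default),
#'   `"minmax"` or `"none"`.
#' @param ref_lead Lead driving the cross-correlation alignment.
#' @return An object of class `mean_beat_set`: list with `beats` (12 x L
#'   matrix), `fs_hz`, `alignment_index` (R-peak sample within the window)
#'   and `n_beats`.
#' @export
extract_mean_beats <- function(rec, peaks, pre_ms = 200, post_ms = 400,
                               max_shift = 10, normalize = "zscore",
                               ref_lead = "II") {
  stopifnot(inherits(rec, "ecg_record"))
  fs <- rec$fs_hz
  pre <- as.integer(round(pre_ms / 1000 * fs))
  post <- as.integer(round(post_ms / 1000 * fs))
  L <- pre + post
  n <- ncol(rec$signals)
  usable <- peaks[peaks - pre + 1 >= 1 & peaks + post <= n]
  if (length(usable) < 3) {
    abort(sprintf("need >= 3 usable beats, got %d", length(usable)),
          class = "deeprisk_insufficient_beats")
  }
  # beats: array lead x L x beat
  cut <- function(p) rec$signals[, (p - pre + 1):(p + post), drop = FALSE]
  beats <- lapply(usable, cut)
  ref_i <- match(ref_lead, rec$lead_names)
  template <- beats[[1]][ref_i, ]
  shift_of <- function(b) {
    xc <- vapply(-max_shift:max_shift, function(s) {
      a <- template
      v <- shift_vec(b[ref_i, ], s)
      sum(a * v)
    }, numeric(1))
    (-max_shift:max_shift)[which.max(xc)]
  }
  aligned <- lapply(beats, function(b) {
    s <- shift_of(b)
    t(apply(b, 1, shift_vec, s))
  })
  mean_beat <- Reduce(`+`, aligned) / length(aligned)
  rownames(mean_beat) <- rec$lead_names
  mbs <- structure(list(beats = mean_beat, fs_hz = fs,
                        alignment_index = pre, n_beats = length(usable)),
                   class = "mean_beat_set")
  normalize_beats(mbs, method = normalize)
}

# Shift a vector by s samples (positive = right), padding with edge values.
shift_vec <- function(x, s) {
  n <- length(x)
  if (s == 0) return(x)
  if (s > 0) c(rep(x[1], s), x[1:(n - s)]) else c(x[(1 - s):n], rep(x[n], -s))
}

#' Normalize a mean-beat set per lead
#'
#' `"zscore"` maps each lead to mean 0, SD 1 (a constant lead maps to
#' zeros); `"minmax"` maps each lead to `[0, 1]`; `"none"` passes through.
#'
#' @param mbs A `mean_beat_set`.
#' @param method One of `"zscore"`, `"minmax"`, `"none"`.
#' @return A `mean_beat_set` with normalized `beats`.
#' @export
normalize_beats <- function(mbs, method = c("zscore", "minmax", "none")) {
  stopifnot(inherits(mbs, "mean_beat_set"))
  method <- match.arg(method)
  b <- mbs$beats
  if (method == "zscore") {
    b <- t(apply(b, 1, zscore))
  } else if (method == "minmax") {
    b <- t(apply(b, 1, function(x) {
      r <- diff(range(x))
      if (r == 0) rep(0, length(x)) else (x - min(x)) / r
    }))
  }
  rownames(b) <- rownames(mbs$beats)
  mbs$beats <- b
  mbs
}

#' @export
print.mean_beat_set <- function(x, ...) {
  cat(sprintf("<mean_beat_set> 12 leads x %d samples @ %g Hz (R at %d, %d beats)\n",
              ncol(x$beats), x$fs_hz, x$alignment_index, x$n_beats))
  invisible(x)
}

#' Full ECG preprocessing chain
#'
#' Resample to 250 Hz, Savitzky-Golay smooth, remove the Fourier baseline,
#' mark R-peaks and extract the normalized mean beat.
#'
#' @param rec A raw [ecg_record()].
#' @inheritParams ecg_denoise
#' @inheritParams extract_mean_beats
#' @return A `mean_beat_set`.
#' @export
prep_ecg <- function(rec, sg_window = 31, sg_order = 7,
                     baseline_cutoff_hz = 0.5, pre_ms = 200, post_ms = 400,
                     normalize = "zscore") {
  rec <- ecg_resample(rec, 250)
  rec <- ecg_denoise(rec, sg_window = sg_window, sg_order = sg_order,
                     baseline_cutoff_hz = baseline_cutoff_hz)
  peaks <- detect_r_peaks(rec)
  extract_mean_beats(rec, peaks, pre_ms = pre_ms, post_ms = post_ms,
                     normalize = normalize)
}

#' Tidy a mean-beat set into long format
#'
#' @param x A `mean_beat_set`.
#' @param ... Unused.
#' @return A tibble with columns `lead`, `sample`, `time_s`, `value`.
#' @export
tidy.mean_beat_set <- function(x, ...) {
  tibble::tibble(
    lead = rep(rownames(x$beats), times = ncol(x$beats)),
    sample = rep(seq_len(ncol(x$beats)), each = 12),
    value = as.numeric(x$beats)
  ) |>
    dplyr::mutate(time_s = (.data$sample - x$alignment_index) / x$fs_hz) |>
    dplyr::arrange(.data$lead, .data$sample)
}

#' Plot a mean-beat set
#'
#' @param object A `mean_beat_set`.
#' @param ... Unused.
#' @return A ggplot faceted by lead.
#' @export
autoplot.mean_beat_set <- function(object, ...) {
  df <- tidy.mean_beat_set(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~lead, ncol = 4) +
    ggplot2::labs(x = "time relative to R-peak (s)", y = "normalized amplitude")
}
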