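#' Preprocessing configuration
#'
#' @param target_fs_hz resampling rate in Hz (default 300).
#' @param highpass_hz drift-removal cutoff in Hz (default 1.5, below the
#'   slowest tremor band at 3 Hz and above postural drift).
#' @param detrend_linear subtract the least-squares linear trend first.
#' @param smoother running-median smoother variant (only `"3RS3R"`).
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_fs_hz = 300, highpass_hz = 1.5,
                              detrend_linear = TRUE, smoother = "3RS3R") {
  if (target_fs_hz <= 0) stop("target_fs_hz must be positive")
  if (!(highpass_hz > 0 && highpass_hz < target_fs_hz / 2))
    stop("highpass_hz must lie in (0, target_fs_hz/2)")
  smoother <- match.arg(smoother, "3RS3R")
  structure(list(target_fs_hz = target_fs_hz, highpass_hz = highpass_hz,
                 detrend_linear = detrend_linear, smoother = smoother),
            class = "preprocess_config")
}

#' Resample a recording on a uniform grid by cubic splines
#'
#' Interpolates the samples with an FMM cubic spline onto a uniform grid at
#' `target_fs_hz` spanning the nominal trial duration `[0, n/fs]`, giving
#' `floor(duration * target_fs_hz) + 1` output samples (750 samples at 50 Hz
#' become 4501 at 300 Hz).
#'
#' @param rec a `gyro_recording`.
#' @param target_fs_hz output sampling rate.
#' @return resampled `gyro_recording`.
#' @export
resample_spline <- function(rec, target_fs_hz = 300) {
  x <- rec$samples
  n <- length(x)
  if (n < 4) stop("need at least 4 samples for cubic-spline resampling")
  duration <- n / rec$fs_hz
  m <- floor(duration * target_fs_hz + 1e-9)
  t_new <- (0:m) / target_fs_hz
  y <- stats::spline(x = (0:(n - 1)) / rec$fs_hz, y = x, xout = t_new,
                     method = "fmm")$y
  out <- rec
  out$samples <- y
  out$fs_hz <- target_fs_hz
  out
}

#' Tukey running-median smoothing (3RS3R)
#'
#' Compound smoother: running medians of 3 repeated to convergence, splitting
#' of two-point flats at local extrema, running medians of 3 again, and
#' Tukey's end rule at the boundaries. The compound pass is itself repeated
#' until the sequence no longer changes, so the smoother is a projection
#' (idempotent) even on tie-heavy sequences whose flats a single pass would
#' leave splittable.
#'
#' @param samples numeric vector; inputs shorter than 3 are returned unchanged.
#' @return smoothed numeric vector of the same length.
#' @export
tukey_smooth <- function(samples) {
  if (length(samples) < 3) return(samples)
  y <- as.numeric(samples)
  for (pass in 1:100) {
    x <- stats::smooth(y, kind = "3R", twiceit = FALSE, endrule = "copy")
    x <- stats::smooth(x, kind = "S", twiceit = FALSE, endrule = "copy")
    x <- as.numeric(stats::smooth(x, kind = "3R", twiceit = FALSE,
                                  endrule = "Tukey"))
    if (identical(x, y)) break
    y <- x
  }
  y
}

#' Remove linear trend and sub-tremor drift
#'
#' Subtracts the least-squares linear trend, then applies a zero-phase
#' (forward-backward) 4th-order Butterworth high-pass at `highpass_hz` to
#' remove slow baseline components unrelated to tremor.
#'
#' @param samples numeric vector.
#' @param fs_hz sampling rate of `samples`.
#' @param cfg a [preprocess_config()].
#' @return detrended numeric vector, mean approximately zero.
#' @export
detrend_signal <- function(samples, fs_hz, cfg = preprocess_config()) {
  if (cfg$highpass_hz >= fs_hz / 2)
    stop("high-pass cutoff must be below the Nyquist frequency")
  x <- samples
  n <- length(x)
  if (cfg$detrend_linear && n >= 2) {
    t <- seq_len(n)
    fit <- stats::lm.fit(cbind(1, t), x)
    x <- fit$residuals
  }
  bf <- signal::butter(4, cfg$highpass_hz / (fs_hz / 2), type = "high")
  as.numeric(signal::filtfilt(bf, x))
}

#' Preprocess a raw tremor recording
#'
#' Fixed stage order: cubic-spline resampling to `target_fs_hz`, Tukey 3RS3R
#' running-median smoothing, then linear detrend + zero-phase Butterworth
#' high-pass. The stage order and configuration are recorded as provenance on
#' the output.
#'
#' @param rec a `gyro_recording`.
#' @param cfg a [preprocess_config()].
#' @return preprocessed `gyro_recording` at `cfg$target_fs_hz`.
#' @export
preprocess <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(cfg, "preprocess_config"))
  if (length(rec$samples) == 0) stop("empty recording")
  out <- resample_spline(rec, cfg$target_fs_hz)
  out$samples <- tukey_smooth(out$samples)
  out$samples <- detrend_signal(out$samples, out$fs_hz, cfg)
  attr(out, "provenance") <- list(stages = c("resample", "smooth", "detrend"),
                                  config = unclass(cfg))
  out
}
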