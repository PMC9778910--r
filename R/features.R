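#' Windowing and feature-extraction configuration
#'
#' @param win_s window length in seconds (default 1).
#' @param overlap window overlap fraction in \[0, 1) (default 0.5).
#' @param sampen_m sample-entropy template length (default 2).
#' @param sampen_r_factor sample-entropy tolerance as a factor of the window
#'   standard deviation (default 0.2).
#' @param outlier_fence IQR multiplier for the window-level outlier screen.
#' @param outlier_mode `"flag"` (default) or `"drop"`.
#' @return object of class `window_config`.
#' @export
window_config <- function(win_s = 1.0, overlap = 0.5, sampen_m = 2,
                          sampen_r_factor = 0.2, outlier_fence = 3.0,
                          outlier_mode = c("flag", "drop")) {
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  if (sampen_m < 1) stop("sampen_m must be >= 1")
  if (sampen_r_factor <= 0) stop("sampen_r_factor must be positive")
  structure(list(win_s = win_s, overlap = overlap, sampen_m = as.integer(sampen_m),
                 sampen_r_factor = sampen_r_factor, outlier_fence = outlier_fence,
                 outlier_mode = match.arg(outlier_mode)),
            class = "window_config")
}

#' Segment a recording into overlapping windows
#'
#' Windows of `round(win_s * fs)` samples advance by
#' `round(n * (1 - overlap))` samples; a trailing partial window is discarded.
#'
#' @param rec a `gyro_recording` (or numeric vector together with `fs_hz`).
#' @param cfg a [window_config()].
#' @param fs_hz sampling rate, required when `rec` is a bare numeric vector.
#' @return matrix with one window per row; attributes `t_start_s`, `n`, `step`.
#' @export
segment_windows <- function(rec, cfg = window_config(), fs_hz = NULL) {
  if (inherits(rec, "gyro_recording")) {
    x <- rec$samples; fs <- rec$fs_hz
  } else {
    if (is.null(fs_hz)) stop("fs_hz required for a bare numeric signal")
    x <- rec; fs <- fs_hz
  }
  n <- round(cfg$win_s * fs)
  step <- round(n * (1 - cfg$overlap))
  L <- length(x)
  if (L < n) stop("signal shorter than one window")
  starts <- seq(1L, L - n + 1L, by = step)
  w <- matrix(0, length(starts), n)
  for (i in seq_along(starts)) w[i, ] <- x[starts[i]:(starts[i] + n - 1L)]
  attr(w, "t_start_s") <- (starts - 1) / fs
  attr(w, "n") <- n
  attr(w, "step") <- step
  w
}

#' Mean absolute value of a window
#' @param window numeric vector.
#' @return `mean(|x|)`.
#' @export
feature_mav <- function(window) {
  if (length(window) == 0) stop("empty window")
  mean(abs(window))
}

#' Coefficient of variation of a window
#'
#' Sample standard deviation (N-1 denominator) divided by the mean. A window
#' with mean exactly zero yields `NaN`; near-zero means produce the extreme
#' dispersion this statistic is known for on detrended tremor windows.
#' @param window numeric vector.
#' @return `sd(x)/mean(x)` or `NaN` when the mean is exactly 0.
#' @export
feature_cv <- function(window) {
  if (length(window) == 0) stop("empty window")
  m <- mean(window)
  if (m == 0) return(NaN)
  stats::sd(window) / m
}

#' Zero-crossing rate of a window
#'
#' `(1/2N) * sum |sgn(x[i+1]) - sgn(x[i])|` with `sgn(0) = +1`. For an f Hz
#' sinusoid sampled at fs this approaches `2 f / fs`.
#' @param window numeric vector of length >= 2.
#' @return value in \[0, 1\].
#' @export
feature_zcr <- function(window) {
  n <- length(window)
  if (n < 2) stop("window too short for zero-crossing rate")
  s <- ifelse(window >= 0, 1, -1)
  sum(abs(diff(s))) / (2 * n)
}

#' Sample entropy of a window
#'
#' `SampEn(m, r, N) = -log(A/B)` where `B` counts template pairs of length `m`
#' within Chebyshev distance `r` and `A` the pairs still within `r` at length
#' `m + 1`, excluding self-matches. `r` is `r_factor` times the window sample
#' standard deviation. A constant window gives 0 (all templates match); when
#' no `m + 1` match exists the result is `Inf`.
#'
#' @param window numeric vector of length > `m + 1`.
#' @param m template length (default 2).
#' @param r_factor tolerance factor on the window standard deviation.
#' @return non-negative entropy value (possibly `Inf`).
#' @export
feature_sampen <- function(window, m = 2, r_factor = 0.2) {
  n <- length(window)
  if (n <= m + 1) stop("window too short for sample entropy")
  sdev <- stats::sd(window)
  if (sdev == 0) return(0)
  r <- r_factor * sdev
  nt <- n - m                        # templates with an (m+1)-th continuation
  d <- abs(outer(window, window, "-"))
  dm <- d[seq_len(n - 1), seq_len(n - 1)]
  if (m > 1) for (j in seq_len(m - 1))
    dm <- pmax(dm[seq_len(n - 1 - j), seq_len(n - 1 - j)],
               d[(1 + j):(n - 1), (1 + j):(n - 1)][seq_len(n - 1 - j), seq_len(n - 1 - j)])
  # dm now holds max over offsets 0..m-1 on indices 1..n-m+1; restrict to nt
  dm <- dm[seq_len(nt), seq_len(nt)]
  dm1 <- pmax(dm, d[(m + 1):n, (m + 1):n])
  ut <- upper.tri(dm)
  B <- sum(dm[ut] < r)
  A <- sum(dm1[ut] < r)
  if (B == 0 || A == 0) return(Inf)
  -log(A / B)
}

#' Hjorth parameters of a window
#'
#' Activity is the sample variance; mobility is
#' `sqrt(Activity(dx)/Activity(x))` with `dx` the unit-sample first
#' difference; complexity is `Mobility(dx)/Mobility(x)`. For an f Hz sinusoid
#' mobility approaches `2 pi f / fs` and complexity approaches 1.
#'
#' @param window numeric vector of length >= 3.
#' @return named numeric vector `c(act, mob, comp)`; a constant window gives
#'   activity 0 and `NaN` mobility/complexity.
#' @export
feature_hjorth <- function(window) {
  if (length(window) < 3) stop("window too short for Hjorth parameters")
  act <- stats::var(window)
  if (act == 0) return(c(act = 0, mob = NaN, comp = NaN))
  d1 <- diff(window)
  d2 <- diff(d1)
  mob <- sqrt(stats::var(d1) / act)
  mob_d <- sqrt(stats::var(d2) / stats::var(d1))
  c(act = act, mob = mob, comp = mob_d / mob)
}

window_features <- function(w, cfg) {
  h <- feature_hjorth(w)
  c(mav = feature_mav(w), cv = feature_cv(w), zcr = feature_zcr(w),
    sampen = feature_sampen(w, cfg$sampen_m, cfg$sampen_r_factor),
    h)
}

#' Extract the per-window feature matrix for a set of recordings
#'
#' Segments every (preprocessed) recording into windows and computes the seven
#' features per window: mav, cv, zcr, sampen, act, mob, comp. A Tukey-fence
#' outlier screen over the pooled per-feature distributions
#' (`|value - median| > fence * IQR`, any-feature rule) replaces manual
#' box-plot inspection; rows are dropped only in `"drop"` mode, otherwise
#' flagged.
#'
#' @param recordings list of `gyro_recording` objects at a common sampling rate.
#' @param cfg a [window_config()].
#' @return data.frame of class `feature_matrix`: subject_id, group, trial,
#'   window_idx, t_start_s, the seven feature columns, and `outlier_flag`.
#' @export
extract_feature_matrix <- function(recordings, cfg = window_config()) {
  if (inherits(recordings, "gyro_recording")) recordings <- list(recordings)
  fs <- unique(vapply(recordings, `[[`, numeric(1), "fs_hz"))
  if (length(fs) != 1) stop("recordings must share a common sampling rate")
  rows <- lapply(recordings, function(rec) {
    w <- segment_windows(rec, cfg)
    f <- t(apply(w, 1, window_features, cfg = cfg))
    data.frame(subject_id = rec$subject_id, group = rec$group, trial = rec$trial,
               window_idx = seq_len(nrow(w)), t_start_s = attr(w, "t_start_s"),
               f, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  feat_cols <- c("mav", "cv", "zcr", "sampen", "act", "mob", "comp")
  flags <- matrix(FALSE, nrow(out), length(feat_cols))
  zero_var <- character(0)
  for (j in seq_along(feat_cols)) {
    v <- out[[feat_cols[j]]]
    ok <- is.finite(v)
    iqr <- stats::IQR(v[ok])
    if (!is.finite(iqr) || iqr == 0) { zero_var <- c(zero_var, feat_cols[j]); next }
    flags[ok, j] <- abs(v[ok] - stats::median(v[ok])) > cfg$outlier_fence * iqr
  }
  out$outlier_flag <- apply(flags, 1, any)
  if (cfg$outlier_mode == "drop") out <- out[!out$outlier_flag, , drop = FALSE]
  attr(out, "config") <- unclass(cfg)
  attr(out, "zero_variance_features") <- zero_var
  class(out) <- c("feature_matrix", "data.frame")
  out
}

feature_columns <- function() c("mav", "cv", "zcr", "sampen", "act", "mob", "comp")
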