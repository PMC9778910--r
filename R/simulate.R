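#' Tremor regime archetype
#'
#' Describes one short-term motor pattern (STMP) archetype as a narrow-band
#' oscillator with amplitude/frequency jitter and additive broadband noise.
#' Physiological tremor sits around 8-10 Hz at low amplitude and is irregular;
#' parkinsonian rest tremor sits in the 3-6 Hz band at much larger amplitude
#' and is markedly more regular.
#'
#' @param label integer archetype id (1..K).
#' @param freq_band_hz length-2 numeric, dominant tremor band (low, high) in Hz.
#' @param amplitude_dps oscillation amplitude scale in degrees per second.
#' @param amp_jitter relative amplitude-modulation depth in \[0, 1\].
#' @param freq_jitter_hz standard deviation of the slow frequency wander (Hz).
#' @param noise_dps standard deviation of additive broadband sensor noise (dps).
#' @param regularity waveform predictability in \[0, 1\]; 1 is a near-sinusoid,
#'   low values mix in a broadband irregular component.
#' @return An object of class `regime_spec`.
#' @export
regime_spec <- function(label, freq_band_hz, amplitude_dps,
                        amp_jitter = 0.3, freq_jitter_hz = 0.3,
                        noise_dps = 0.1, regularity = 0.5) {
  stopifnot(length(freq_band_hz) == 2)
  if (!(freq_band_hz[1] > 0 && freq_band_hz[1] < freq_band_hz[2]))
    stop("freq_band_hz must satisfy 0 < low < high")
  if (amplitude_dps < 0) stop("amplitude_dps must be >= 0")
  if (amp_jitter < 0 || amp_jitter > 1) stop("amp_jitter must be in [0, 1]")
  if (noise_dps < 0) stop("noise_dps must be >= 0")
  if (regularity < 0 || regularity > 1) stop("regularity must be in [0, 1]")
  structure(list(label = as.integer(label), freq_band_hz = as.numeric(freq_band_hz),
                 amplitude_dps = amplitude_dps, amp_jitter = amp_jitter,
                 freq_jitter_hz = freq_jitter_hz, noise_dps = noise_dps,
                 regularity = regularity),
            class = "regime_spec")
}

#' Default STMP archetypes
#'
#' Three archetypes mirroring the amplitude/regularity ordering seen in rest
#' tremor: (1) low-amplitude irregular 8-10 Hz physiological tremor,
#' (2) intermediate 5-7 Hz tremor, (3) high-amplitude, highly regular 3-6 Hz
#' parkinsonian rest tremor (amplitude > 10x archetype 1).
#'
#' @return list of three [regime_spec()] objects.
#' @export
default_regimes <- function() {
  list(
    regime_spec(1L, c(8, 10), 0.30, amp_jitter = 0.35, freq_jitter_hz = 0.40,
                noise_dps = 0.05, regularity = 0.40),
    regime_spec(2L, c(5, 7),  0.60, amp_jitter = 0.25, freq_jitter_hz = 0.30,
                noise_dps = 0.05, regularity = 0.65),
    regime_spec(3L, c(3, 6),  3.20, amp_jitter = 0.15, freq_jitter_hz = 0.20,
                noise_dps = 0.10, regularity = 0.92)
  )
}

#' Default hidden-regime dwell matrices
#'
#' Row-stochastic 3x3 transition matrices on the 0.5 s regime grid. Healthy
#' controls occupy mainly the low-amplitude archetype and switch more freely
#' (larger off-diagonal mass); the parkinsonian matrix dwells in the
#' high-amplitude archetype.
#'
#' @param group `"HC"` or `"PD"`.
#' @return 3x3 row-stochastic matrix.
#' @export
default_dwell <- function(group = c("HC", "PD")) {
  group <- match.arg(group)
  if (group == "HC") {
    matrix(c(0.92, 0.06, 0.02,
             0.11, 0.85, 0.04,
             0.12, 0.10, 0.78), 3, 3, byrow = TRUE)
  } else {
    matrix(c(0.85, 0.11, 0.04,
             0.05, 0.88, 0.07,
             0.02, 0.04, 0.94), 3, 3, byrow = TRUE)
  }
}

check_stochastic <- function(P, tol = 1e-9) {
  if (!is.matrix(P) || nrow(P) != ncol(P))
    stop("dwell matrix must be square")
  if (any(P < 0)) stop("dwell matrix entries must be non-negative")
  if (any(abs(rowSums(P) - 1) > tol))
    stop("dwell matrix rows must sum to 1")
  invisible(TRUE)
}

stationary_dist <- function(P) {
  k <- nrow(P)
  A <- rbind(t(P) - diag(k), rep(1, k))
  b <- c(rep(0, k), 1)
  pi <- stats::lsfit(A, b, intercept = FALSE)$coefficients
  pi <- pmax(pi, 0)
  pi / sum(pi)
}

# Stationary Ornstein-Uhlenbeck sample path, unit marginal sd.
ou_path <- function(n, dt, tau) {
  a <- exp(-dt / tau)
  s <- sqrt(1 - a^2)
  v <- numeric(n)
  v[1] <- stats::rnorm(1)
  innov <- stats::rnorm(n - 1)
  for (i in seq_len(n - 1)) v[i + 1] <- a * v[i] + s * innov[i]
  v
}

#' Generate one synthetic gyroscope tremor recording
#'
#' Simulates a single-axis angular-velocity trial as a hidden Markov mixture
#' of tremor archetypes. The hidden regime switches on a 0.5 s grid (the
#' analysis window step, so the ground truth aligns with window labels). The
#' signal is the per-regime oscillation (base frequency drawn uniformly in the
#' regime band per trial, slow amplitude and frequency wander), an irregular
#' broadband component scaled by `1 - regularity`, a sub-1 Hz baseline drift,
#' and white sensor noise, optionally clipped and quantized as by the
#' acquisition ADC.
#'
#' @param regimes list of [regime_spec()] objects.
#' @param dwell K x K row-stochastic regime transition matrix on the 0.5 s grid.
#' @param trial_s trial duration in seconds (nominal; default 15).
#' @param fs_hz sampling rate in Hz (default 50).
#' @param drift amplitude (dps) of the slow (< 1 Hz) baseline drift; 0 disables.
#' @param clip_dps saturation bound in dps, or `NULL` for none.
#' @param quantize_bits ADC resolution in bits (full scale +/- `clip_dps`,
#'   or +/- 500 dps when `clip_dps` is `NULL`), or `NULL` for none.
#' @param seed integer seed; identical inputs give identical output.
#' @param subject_id,group,trial identity metadata carried on the recording.
#' @param amp_scale,irregularity_scale subject-level modifiers (severity
#'   modulation; see [generate_cohort()]).
#' @param step_s hidden-regime grid step in seconds (default 0.5).
#' @return A `gyro_recording`: list with `samples`, `fs_hz`, `truth_states`
#'   (hidden regime per 0.5 s step) and identity fields.
#' @export
generate_recording <- function(regimes, dwell, trial_s = 15, fs_hz = 50,
                               drift = 0, clip_dps = NULL, quantize_bits = NULL,
                               seed = 1L, subject_id = "S01", group = "HC",
                               trial = 1L, amp_scale = 1, irregularity_scale = 1,
                               step_s = 0.5) {
  if (length(regimes) == 0) stop("at least one regime is required")
  if (inherits(regimes, "regime_spec")) regimes <- list(regimes)
  check_stochastic(dwell)
  k <- length(regimes)
  if (nrow(dwell) != k) stop("dwell matrix dimension must match regime count")
  fmax <- max(vapply(regimes, function(r) r$freq_band_hz[2], numeric(1)))
  if (fs_hz <= 2 * fmax)
    stop("fs_hz must exceed twice the highest regime frequency (Nyquist)")

  set.seed(as.integer(seed))
  n <- round(trial_s * fs_hz)
  spf <- round(step_s * fs_hz)
  n_steps <- ceiling(n / spf)

  states <- integer(n_steps)
  states[1] <- sample.int(k, 1, prob = stationary_dist(dwell))
  for (t in seq_len(n_steps - 1))
    states[t + 1] <- sample.int(k, 1, prob = dwell[states[t], ])
  s <- rep(states, each = spf)[seq_len(n)]

  amp   <- vapply(regimes, `[[`, numeric(1), "amplitude_dps")[s] * amp_scale
  ajit  <- vapply(regimes, `[[`, numeric(1), "amp_jitter")[s]
  fjit  <- vapply(regimes, `[[`, numeric(1), "freq_jitter_hz")[s]
  nse   <- vapply(regimes, `[[`, numeric(1), "noise_dps")[s]
  reg   <- vapply(regimes, `[[`, numeric(1), "regularity")[s]
  f0 <- vapply(regimes, function(r) stats::runif(1, r$freq_band_hz[1], r$freq_band_hz[2]),
               numeric(1))[s]

  dt <- 1 / fs_hz
  f_inst <- pmax(f0 + fjit * ou_path(n, dt, tau = 0.5), 0.1)
  phase <- 2 * pi * cumsum(f_inst) * dt
  a_mod <- pmax(0, 1 + ajit * ou_path(n, dt, tau = 0.4))
  irr <- (1 - reg) * irregularity_scale * 0.35 * amp * stats::rnorm(n)
  x <- amp * a_mod * sin(phase) + irr + stats::rnorm(n) * nse
  if (drift != 0) x <- x + drift * ou_path(n, dt, tau = 3)

  if (!is.null(clip_dps)) x <- pmin(pmax(x, -clip_dps), clip_dps)
  if (!is.null(quantize_bits)) {
    fsr <- if (is.null(clip_dps)) 500 else clip_dps
    lsb <- 2 * fsr / 2^quantize_bits
    x <- round(x / lsb) * lsb
  }

  structure(list(subject_id = subject_id, group = group, trial = as.integer(trial),
                 axis = "X", fs_hz = fs_hz, trial_s = trial_s, samples = x,
                 truth_states = states, step_s = step_s),
            class = "gyro_recording")
}

#' @export
print.gyro_recording <- function(x, ...) {
  cat(sprintf("gyro_recording %s/%s trial %d: %d samples @ %g Hz (axis %s)\n",
              x$subject_id, x$group, x$trial, length(x$samples), x$fs_hz, x$axis))
  invisible(x)
}

#' Cohort specification for the synthetic tremor study
#'
#' Defaults mirror the emulated study conditions: 12 healthy controls and 14
#' parkinsonian subjects, three 15 s trials each, sampled at 50 Hz with 12-bit
#' quantization over a +/- 500 dps full scale.
#'
#' @param n_hc,n_pd subject counts per group.
#' @param trials_per_subject trials per subject.
#' @param trial_s,fs_hz trial duration (s) and sampling rate (Hz).
#' @param regimes list of [regime_spec()]; shared by both groups.
#' @param dwell_hc,dwell_pd per-group hidden-regime dwell matrices.
#' @param drift baseline drift amplitude in dps.
#' @param clip_dps,quantize_bits saturation bound and ADC bits (`NULL` disables).
#' @param severity_amp,severity_irreg per-unit-severity modulation of subject
#'   amplitude (log-normal multiplier centred on `1 + severity_amp * score`)
#'   and irregularity (multiplier `1 - severity_irreg * score`, floored at
#'   0.5); emulates the clinical gradient where severe tremor is larger and
#'   more regular.
#' @param pd_irreg_factor optional group-level irregularity multiplier
#'   applied to every PD subject (default 1, no group-level effect: strong
#'   group-wide regularity shifts make the embedding organize by group
#'   rather than by motor pattern).
#' @param subject_amp_sdlog log-scale standard deviation of the per-subject
#'   amplitude multiplier (continuous between-subject variability).
#' @param seed master integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_hc = 12, n_pd = 14, trials_per_subject = 3,
                        trial_s = 15, fs_hz = 50, regimes = default_regimes(),
                        dwell_hc = default_dwell("HC"),
                        dwell_pd = default_dwell("PD"),
                        drift = 2, clip_dps = 500, quantize_bits = 12,
                        severity_amp = 0.05, severity_irreg = 0.10,
                        pd_irreg_factor = 1.0,
                        subject_amp_sdlog = 0.06, seed = 1L) {
  if (length(regimes) == 0) stop("regime list must not be empty")
  check_stochastic(dwell_hc); check_stochastic(dwell_pd)
  structure(list(n_hc = n_hc, n_pd = n_pd, trials_per_subject = trials_per_subject,
                 trial_s = trial_s, fs_hz = fs_hz, regimes = regimes,
                 dwell_hc = dwell_hc, dwell_pd = dwell_pd, drift = drift,
                 clip_dps = clip_dps, quantize_bits = quantize_bits,
                 severity_amp = severity_amp, severity_irreg = severity_irreg,
                 pd_irreg_factor = pd_irreg_factor,
                 subject_amp_sdlog = subject_amp_sdlog,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic tremor cohort
#'
#' Simulates every trial of every subject under the cohort specification.
#' Healthy-control subjects follow the HC dwell matrix (biased toward the
#' low-amplitude high-frequency archetype); parkinsonian subjects follow the
#' PD dwell matrix (biased toward the high-amplitude low-frequency archetype).
#' Each PD subject receives a synthetic rest-tremor severity score (0-4, drawn
#' from a clinically plausible mix) that scales tremor amplitude up and
#' irregularity down.
#'
#' @param cohort a [cohort_spec()].
#' @return list with `recordings` (list of `gyro_recording`), `metadata`
#'   (data.frame: subject_id, group, severity) and `truth` (data.frame of
#'   hidden regime per 0.5 s step).
#' @export
generate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  set.seed(cohort$seed)
  n_subj <- cohort$n_hc + cohort$n_pd
  groups <- c(rep("HC", cohort$n_hc), rep("PD", cohort$n_pd))
  ids <- sprintf("%s%02d", groups, c(seq_len(cohort$n_hc), seq_len(cohort$n_pd)))
  # severity mix echoing observed item-20 score distributions: mostly 0,
  # some 1 and 3, rarely 4
  severity <- ifelse(groups == "HC", 0L,
                     sample(c(0L, 1L, 3L, 4L), n_subj, replace = TRUE,
                            prob = c(7, 2, 4, 1) / 14))
  # continuous per-subject amplitude variability centred on the severity trend
  amp_scales <- exp(stats::rnorm(n_subj, log(1 + cohort$severity_amp * severity),
                                 cohort$subject_amp_sdlog))

  recordings <- vector("list", n_subj * cohort$trials_per_subject)
  truth <- vector("list", length(recordings))
  idx <- 0L
  for (i in seq_len(n_subj)) {
    dwell <- if (groups[i] == "HC") cohort$dwell_hc else cohort$dwell_pd
    amp_scale <- amp_scales[i]
    irr_scale <- max(0.5, 1 - cohort$severity_irreg * severity[i]) *
      if (groups[i] == "PD") cohort$pd_irreg_factor else 1
    for (tr in seq_len(cohort$trials_per_subject)) {
      idx <- idx + 1L
      rec_seed <- (cohort$seed + 7919L * i + 104729L * tr) %% .Machine$integer.max
      rec <- generate_recording(cohort$regimes, dwell,
                                trial_s = cohort$trial_s, fs_hz = cohort$fs_hz,
                                drift = cohort$drift, clip_dps = cohort$clip_dps,
                                quantize_bits = cohort$quantize_bits,
                                seed = rec_seed, subject_id = ids[i],
                                group = groups[i], trial = tr,
                                amp_scale = amp_scale,
                                irregularity_scale = irr_scale)
      recordings[[idx]] <- rec
      truth[[idx]] <- data.frame(subject_id = ids[i], trial = tr,
                                 step_idx = seq_along(rec$truth_states),
                                 t_start_s = (seq_along(rec$truth_states) - 1) * rec$step_s,
                                 regime = rec$truth_states)
    }
  }
  list(recordings = recordings,
       metadata = data.frame(subject_id = ids, group = groups, severity = severity),
       truth = do.call(rbind, truth))
}
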