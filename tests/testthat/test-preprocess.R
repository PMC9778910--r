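make_rec <- function(x, fs) {
  structure(list(subject_id = "T01", group = "HC", trial = 1L, axis = "X",
                 fs_hz = fs, trial_s = length(x) / fs, samples = x,
                 truth_states = NULL, step_s = 0.5),
            class = "gyro_recording")
}

test_that("spline resampling produces the documented grid length", {
  rec <- make_rec(rnorm(750), 50)
  out <- resample_spline(rec, 300)
  expect_length(out$samples, 4501)   # floor(15 * 300) + 1
  expect_equal(out$fs_hz, 300)
  expect_error(resample_spline(make_rec(rnorm(3), 50), 300), "4 samples")
})

test_that("spline resampling reproduces a sinusoid and preserves constants", {
  fs <- 50; t <- (0:749) / fs
  rec <- make_rec(sin(2 * pi * 5 * t), fs)
  out <- resample_spline(rec, 300)
  tt <- (seq_along(out$samples) - 1) / 300
  inside <- tt <= max(t)   # exclude the extrapolated tail point(s)
  expect_lt(max(abs(out$samples[inside] - sin(2 * pi * 5 * tt[inside]))), 1e-2)

  cst <- resample_spline(make_rec(rep(2.5, 100), 50), 300)
  expect_equal(cst$samples, rep(2.5, length(cst$samples)), tolerance = 1e-12)
})

test_that("Tukey smoother matches examples and the brute-force 3RS3R oracle", {
  mono <- as.numeric(1:20)
  expect_equal(tukey_smooth(mono), mono)
  spiked <- c(0, 0, 0, 10, 0, 0, 0)
  expect_equal(tukey_smooth(spiked)[4], 0)
  expect_equal(tukey_smooth(c(1, 9)), c(1, 9))   # short input passthrough

  set.seed(31)
  for (rep in 1:200) {
    n <- sample(5:60, 1)
    y <- if (rep %% 2) as.numeric(sample(0:4, n, replace = TRUE)) else
      round(rnorm(n), 1)
    expect_equal(tukey_smooth(y), oracle_3rs3r(y), tolerance = 1e-12)
  }
})

test_that("Tukey smoother is idempotent", {
  set.seed(17)
  for (rep in 1:50) {
    y <- rnorm(sample(10:80, 1))
    s <- tukey_smooth(y)
    expect_identical(tukey_smooth(s), s)
  }
})

test_that("detrending removes a linear ramp and preserves zero", {
  fs <- 300
  ramp <- seq(0, 10, length.out = 3001)
  out <- detrend_signal(ramp, fs, preprocess_config())
  edge <- round(0.5 * fs)
  core <- out[(edge + 1):(length(out) - edge)]
  expect_lt(max(abs(core)), 1e-6 * diff(range(ramp)))
  expect_equal(detrend_signal(rep(0, 1000), fs), rep(0, 1000), tolerance = 1e-12)
})

test_that("high-pass attenuates 0.2 Hz by > 20 dB and passes 5 Hz within 1 dB", {
  fs <- 300
  t <- (0:(fs * 20 - 1)) / fs
  x <- sin(2 * pi * 5 * t) + sin(2 * pi * 0.2 * t)
  out <- detrend_signal(x, fs, preprocess_config())
  core <- out[(2 * fs + 1):(length(out) - 2 * fs)]
  t_core <- t[(2 * fs + 1):(length(out) - 2 * fs)]
  # regression-based amplitude estimates, robust to spectral leakage
  fit5 <- stats::lm(core ~ sin(2 * pi * 5 * t_core) + cos(2 * pi * 5 * t_core))
  a5 <- sqrt(sum(stats::coef(fit5)[2:3]^2))
  fit02 <- stats::lm(core ~ sin(2 * pi * 0.2 * t_core) + cos(2 * pi * 0.2 * t_core))
  a02 <- sqrt(sum(stats::coef(fit02)[2:3]^2))
  expect_lt(20 * log10(a02 / 1), -20)       # 0.2 Hz attenuated by > 20 dB
  expect_lt(abs(20 * log10(a5 / 1)), 1)     # 5 Hz ripple < 1 dB
})

test_that("full preprocessing removes drift and keeps tremor-band content", {
  reg <- regime_spec(1L, c(5, 7), 1.0, amp_jitter = 0.2, freq_jitter_hz = 0.2,
                     noise_dps = 0.05, regularity = 0.8)
  rec <- generate_recording(list(reg), matrix(1, 1, 1), drift = 3, seed = 21L)
  out <- preprocess(rec)
  expect_equal(out$fs_hz, 300)
  expect_lt(abs(mean(out$samples)), 0.01 * stats::sd(out$samples))
  prov <- attr(out, "provenance")
  expect_identical(prov$stages, c("resample", "smooth", "detrend"))
})

test_that("preprocessing a drift-free in-band sinusoid is close to identity", {
  fs <- 300
  t <- (0:(fs * 10 - 1)) / fs
  x <- sin(2 * pi * 6 * t)
  rec <- make_rec(x, fs)
  out <- preprocess(rec)
  edge <- fs
  n <- min(length(out$samples), length(x))
  core <- (edge + 1):(n - edge)
  expect_lt(max(abs(out$samples[core] - x[core])), 0.05)
})

test_that("empty recordings are rejected", {
  expect_error(preprocess(make_rec(numeric(0), 50)), "empty")
})
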