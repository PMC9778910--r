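test_that("window segmentation counts follow the overlap arithmetic", {
  x <- rnorm(4500)
  w <- segment_windows(x, window_config(), fs_hz = 300)
  expect_equal(nrow(w), 29)            # floor((4500 - 300)/150) + 1
  expect_equal(ncol(w), 300)
  expect_equal(attr(w, "step"), 150)

  w0 <- segment_windows(rnorm(1000), window_config(overlap = 0), fs_hz = 100)
  expect_equal(nrow(w0), 10)           # disjoint windows, floor(L/n)
  w1 <- segment_windows(rnorm(300), window_config(), fs_hz = 300)
  expect_equal(nrow(w1), 1)            # L == n boundary
  expect_error(segment_windows(rnorm(100), window_config(), fs_hz = 300),
               "shorter")
})

test_that("feature examples match their closed forms", {
  expect_equal(feature_mav(c(1, -1, 1, -1)), 1.0)
  expect_equal(feature_mav(rep(0, 10)), 0.0)
  t <- (0:2999) / 300
  s <- 1.7 * sin(2 * pi * 5 * t)       # integer number of periods
  expect_equal(feature_mav(s), 2 * 1.7 / pi, tolerance = 1e-3)

  expect_equal(feature_cv(rep(3.2, 10)), 0)
  expect_equal(feature_cv(c(1, 2, 3)), 0.5)
  expect_true(is.nan(feature_cv(c(-1, 1))))

  expect_equal(feature_zcr(c(1, -1, 1, -1)), 0.75)
  expect_equal(feature_zcr(rep(2, 10)), 0)
  set.seed(4)
  s5 <- sin(2 * pi * 5 * t + runif(1, 0, 2 * pi))
  expect_equal(feature_zcr(s5), 2 * 5 / 300, tolerance = 0.15)

  expect_equal(feature_sampen(rep(1, 50)), 0)
  set.seed(8)
  noise <- rnorm(300)
  sine <- sqrt(2) * sin(2 * pi * 5 * (0:299) / 300)  # same variance as noise
  expect_gt(feature_sampen(noise), feature_sampen(sine))

  h <- feature_hjorth(rep(2, 10))
  expect_equal(unname(h["act"]), 0)
  expect_true(is.nan(h["mob"]))
  hs <- feature_hjorth(sin(2 * pi * 5 * t))
  expect_equal(unname(hs["mob"]), 2 * pi * 5 / 300, tolerance = 1e-3)
  expect_equal(unname(hs["comp"]), 1, tolerance = 1e-2)
  ha <- feature_hjorth(3 * sin(2 * pi * 5 * t))
  expect_equal(unname(ha["act"]), 9 / 2, tolerance = 1e-3)
})

test_that("every feature equals its brute-force oracle on random windows", {
  set.seed(123)
  for (rep in 1:100) {
    n <- sample(30:60, 1)
    x <- switch(1 + rep %% 3,
                rnorm(n),
                sin(2 * pi * 4 * (1:n) / n) + 0.3 * rnorm(n),
                round(rnorm(n), 1))              # ties stress SampEn matching
    expect_equal(feature_mav(x), oracle_mav(x), tolerance = 1e-12)
    expect_equal(feature_cv(x), oracle_cv(x), tolerance = 1e-12)
    expect_equal(feature_zcr(x), oracle_zcr(x), tolerance = 1e-12)
    expect_equal(feature_sampen(x), oracle_sampen(x), tolerance = 1e-12)
    expect_equal(feature_hjorth(x), oracle_hjorth(x), tolerance = 1e-12)
  }
})

test_that("feature ranges hold on random windows", {
  set.seed(99)
  for (rep in 1:50) {
    x <- rnorm(sample(20:100, 1))
    expect_gte(feature_zcr(x), 0); expect_lte(feature_zcr(x), 1)
    expect_gte(feature_hjorth(x)["act"], 0)
    se <- feature_sampen(x)
    if (is.finite(se)) expect_gte(se, 0)
  }
})

test_that("the default synthetic cohort yields a 2262-row feature matrix", {
  res <- default_run()
  expect_s3_class(res$features, "feature_matrix")
  expect_equal(nrow(res$features), 2262)   # 26 subjects x 3 trials x 29 windows
  expect_identical(names(res$features)[6:12],
                   c("mav", "cv", "zcr", "sampen", "act", "mob", "comp"))
})

test_that("degenerate identical windows are flagged structurally, not fatal", {
  rec <- structure(list(subject_id = "Z", group = "HC", trial = 1L, axis = "X",
                        fs_hz = 300, trial_s = 5, samples = rep(1, 1500),
                        truth_states = NULL, step_s = 0.5),
                   class = "gyro_recording")
  fm <- extract_feature_matrix(list(rec), window_config())
  expect_equal(nrow(fm), 9)
  expect_true(all(!fm$outlier_flag))
  expect_true(length(attr(fm, "zero_variance_features")) > 0)
})

test_that("feature extraction is deterministic", {
  spec <- small_cohort_spec()
  a <- generate_cohort(spec); b <- generate_cohort(spec)
  fa <- extract_feature_matrix(lapply(a$recordings, preprocess))
  fb <- extract_feature_matrix(lapply(b$recordings, preprocess))
  expect_identical(fa, fb)
})

test_that("windows dominated by the regular high-amplitude regime have lower SampEn", {
  res <- default_run()
  cohort <- res$cohort
  # ground-truth regime per window: pure windows cover two equal steps
  truth <- do.call(rbind, lapply(cohort$recordings, function(r) {
    st <- r$truth_states
    nw <- 29
    data.frame(subject_id = r$subject_id, trial = r$trial,
               window_idx = seq_len(nw),
               regime = ifelse(st[seq_len(nw)] == st[pmin(seq_len(nw) + 1, length(st))],
                               st[seq_len(nw)], NA_integer_))
  }))
  d <- merge(as.data.frame(res$features), truth,
             by = c("subject_id", "trial", "window_idx"))
  m <- tapply(d$sampen, d$regime, mean, na.rm = TRUE)
  expect_gt(m[["1"]], m[["3"]])   # irregular physiological > regular parkinsonian
})
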