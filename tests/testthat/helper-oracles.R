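# Independent brute-force oracles, transcribed directly from the defining
# formulas; deliberately slow and loop-based so they share no code path with
# the package implementation.

oracle_mav <- function(x) sum(abs(x)) / length(x)

oracle_cv <- function(x) {
  n <- length(x)
  mu <- mean(x)   # long-double accumulation; sum(x)/n loses precision when
                  # the mean is near zero by cancellation and CV explodes
  if (mu == 0) return(NaN)
  sqrt(sum((x - mu)^2) / (n - 1)) / mu
}

oracle_zcr <- function(x) {
  n <- length(x)
  sgn <- function(v) if (v >= 0) 1 else -1
  s <- 0
  for (i in 1:(n - 1)) s <- s + abs(sgn(x[i + 1]) - sgn(x[i]))
  s / (2 * n)
}

oracle_sampen <- function(x, m = 2, r_factor = 0.2) {
  n <- length(x)
  mu <- sum(x) / n
  sdev <- sqrt(sum((x - mu)^2) / (n - 1))
  if (sdev == 0) return(0)
  r <- r_factor * sdev
  cheb <- function(i, j, len) {
    d <- 0
    for (o in 0:(len - 1)) d <- max(d, abs(x[i + o] - x[j + o]))
    d
  }
  A <- 0; B <- 0
  nt <- n - m
  for (i in 1:(nt - 1)) for (j in (i + 1):nt) {
    if (cheb(i, j, m) < r) B <- B + 1
    if (cheb(i, j, m + 1) < r) A <- A + 1
  }
  if (B == 0 || A == 0) return(Inf)
  -log(A / B)
}

oracle_hjorth <- function(x) {
  v <- function(u) { mu <- sum(u) / length(u); sum((u - mu)^2) / (length(u) - 1) }
  act <- v(x)
  if (act == 0) return(c(act = 0, mob = NaN, comp = NaN))
  d1 <- x[-1] - x[-length(x)]
  d2 <- d1[-1] - d1[-length(d1)]
  mob <- sqrt(v(d1) / act)
  c(act = act, mob = mob, comp = sqrt(v(d2) / v(d1)) / mob)
}

# Tukey 3RS3R compound smoother: running medians of 3 to convergence,
# splitting of two-point flats at local extrema, medians again, Tukey end rule.
oracle_3rs3r <- local({
  med3 <- function(a, b, c) max(min(a, b), min(max(a, b), c))
  sm3_once <- function(y) {
    n <- length(y)
    z <- y
    for (i in 2:(n - 1)) z[i] <- med3(y[i - 1], y[i], y[i + 1])
    z
  }
  sm3R <- function(y) {
    repeat {
      z <- sm3_once(y)
      if (identical(z, y)) return(y)
      y <- z
    }
  }
  split2 <- function(x) {
    n <- length(x)
    y <- x
    if (n < 6) return(y)
    for (i in 3:(n - 3)) {
      if (x[i] == x[i + 1] && x[i - 1] != x[i] && x[i + 2] != x[i + 1] &&
          sign(x[i - 1] - x[i]) == sign(x[i + 2] - x[i + 1])) {
        y[i] <- med3(x[i], x[i - 1], 3 * x[i - 1] - 2 * x[i - 2])
        y[i + 1] <- med3(x[i + 1], x[i + 2], 3 * x[i + 2] - 2 * x[i + 3])
      }
    }
    y
  }
  ends_tukey <- function(y) {
    n <- length(y)
    y[1] <- med3(y[1], y[2], 3 * y[2] - 2 * y[3])
    y[n] <- med3(y[n], y[n - 1], 3 * y[n - 1] - 2 * y[n - 2])
    y
  }
  onepass <- function(y) ends_tukey(sm3R(split2(sm3R(y))))
  function(y) {
    if (length(y) < 3) return(y)
    repeat {
      z <- onepass(y)
      if (identical(z, y)) return(y)
      y <- z
    }
  }
})

# Exhaustive quadrant scan for the 2-D two-sample statistic.
oracle_ff2d <- function(a, b) {
  quad_frac <- function(pts, x0, y0) {
    dx <- pts[, 1] - x0; dy <- pts[, 2] - y0
    keep <- dx != 0 & dy != 0
    c(sum(dx > 0 & dy > 0 & keep), sum(dx < 0 & dy > 0 & keep),
      sum(dx < 0 & dy < 0 & keep), sum(dx > 0 & dy < 0 & keep)) / nrow(pts)
  }
  dmax_from <- function(origins) {
    d <- 0
    for (i in seq_len(nrow(origins))) {
      fa <- quad_frac(a, origins[i, 1], origins[i, 2])
      fb <- quad_frac(b, origins[i, 1], origins[i, 2])
      d <- max(d, max(abs(fa - fb)))
    }
    d
  }
  (dmax_from(a) + dmax_from(b)) / 2
}

# small helper: seeded 2-D Gaussian blobs
make_blobs <- function(n_per, centers, sd = 0.5, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))))
}

blob_labels <- function(n_per, k) rep(seq_len(k), each = n_per)
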