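#' Fasano-Franceschini two-dimensional two-sample test
#'
#' Multidimensional generalization of the two-sample Kolmogorov-Smirnov test.
#' For every origin point the empirical fractions of the two samples in the
#' four open quadrants around the origin are compared; the statistic is the
#' average of the maximal absolute differences obtained with origins taken
#' from each sample, `D = (D_A + D_B) / 2`. Significance is assessed by a
#' seeded permutation of the pooled sample labels:
#' `p = (1 + #\{D_perm >= D_obs\}) / (1 + n_perm)`.
#'
#' @param points_a,points_b two-column matrices (or `embedded_points`) with at
#'   least 5 rows each.
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer seed for the permutation stream.
#' @return object of class `ff2d_result`: `d_stat`, `p_value`, `n_perm`,
#'   `seed`, sample sizes.
#' @export
ff2d_test <- function(points_a, points_b, n_perm = 1000, seed = 1L) {
  a <- as_coords(points_a)
  b <- as_coords(points_b)
  if (ncol(a) != 2 || ncol(b) != 2) stop("samples must be two-dimensional")
  if (nrow(a) < 5 || nrow(b) < 5) stop("each sample needs at least 5 points")
  x <- c(a[, 1], b[, 1]); y <- c(a[, 2], b[, 2])
  grp <- c(rep(0L, nrow(a)), rep(1L, nrow(b)))
  d_obs <- ff2d_stat_cpp(x, y, grp)
  set.seed(as.integer(seed))
  d_perm <- ff2d_perm_cpp(x, y, grp, as.integer(n_perm))
  p <- (1 + sum(d_perm >= d_obs)) / (1 + n_perm)
  structure(list(d_stat = d_obs, p_value = p, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), n_a = nrow(a), n_b = nrow(b)),
            class = "ff2d_result")
}

#' @export
print.ff2d_result <- function(x, ...) {
  cat(sprintf("Fasano-Franceschini 2-D test: D = %.4f, p = %.4g (%d permutations, n = %d + %d)\n",
              x$d_stat, x$p_value, x$n_perm, x$n_a, x$n_b))
  invisible(x)
}

#' Pairwise Fasano-Franceschini tests between clusters
#'
#' Applies [ff2d_test()] to every distinct pair of clusters in a 2-D map.
#'
#' @param points `embedded_points` or n x 2 matrix.
#' @param labels integer cluster label per point.
#' @param n_perm permutations per pair.
#' @param seed integer seed (incremented per pair for independent streams).
#' @return data.frame: cluster_i, cluster_j, d_stat, p_value.
#' @export
ff2d_pairwise <- function(points, labels, n_perm = 1000, seed = 1L) {
  x <- as_coords(points)
  ks <- sort(unique(labels))
  pairs <- utils::combn(ks, 2)
  out <- data.frame(cluster_i = pairs[1, ], cluster_j = pairs[2, ],
                    d_stat = NA_real_, p_value = NA_real_)
  for (p in seq_len(ncol(pairs))) {
    r <- ff2d_test(x[labels == pairs[1, p], , drop = FALSE],
                   x[labels == pairs[2, p], , drop = FALSE],
                   n_perm = n_perm, seed = seed + p)
    out$d_stat[p] <- r$d_stat
    out$p_value[p] <- r$p_value
  }
  out
}
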