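#' Column-wise z-scoring
#'
#' Standardizes each column to mean 0 and unit sample standard deviation.
#' Constant columns cannot be standardized and raise an error naming the
#' offending column.
#'
#' @param m numeric matrix or data.frame of numeric columns.
#' @return matrix of the same shape with `center`/`scale` attributes.
#' @export
zscore <- function(m) {
  m <- as.matrix(m)
  sds <- apply(m, 2, stats::sd)
  bad <- which(!is.finite(sds) | sds == 0)
  if (length(bad))
    stop("constant (or non-finite) column(s): ",
         paste(colnames(m)[bad] %||% bad, collapse = ", "))
  z <- scale(m)
  out <- z[, , drop = FALSE]
  attr(out, "center") <- attr(z, "scaled:center")
  attr(out, "scale") <- attr(z, "scaled:scale")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Embed feature windows into two dimensions with t-SNE
#'
#' Barnes-Hut t-SNE minimizing the Kullback-Leibler divergence between the
#' high-dimensional and map neighbour distributions. Only the perplexity is
#' pinned (default 10); remaining optimizer settings are the library defaults.
#' The run is seeded and single-threaded, so identical input and seed give
#' identical coordinates.
#'
#' @param z_matrix numeric matrix (rows = windows), typically z-scored features.
#' @param perplexity t-SNE perplexity (default 10).
#' @param seed integer seed.
#' @param max_iter gradient-descent iterations.
#' @param restarts optional number of seeded optimizer restarts, keeping the
#'   map with the lowest final KL divergence. The default is a single run:
#'   harder-converged maps resolve finer within-pattern substructure, which
#'   is counterproductive when the map feeds a cluster-count search.
#' @return object of class `embedded_points`: list with `coords` (n x 2,
#'   columns tsne1/tsne2), `perplexity`, `seed`, `kl` (final KL divergence).
#' @export
embed_2d <- function(z_matrix, perplexity = 10, seed = 1L, max_iter = 1000,
                     restarts = 1) {
  z_matrix <- as.matrix(z_matrix)
  if (nrow(z_matrix) < 3 * perplexity)
    stop("need at least 3 * perplexity rows for the embedding")
  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(as.integer(seed) + 7873L * (r - 1L))
    fit <- Rtsne::Rtsne(z_matrix, dims = 2, perplexity = perplexity,
                        max_iter = max_iter, check_duplicates = FALSE,
                        pca = TRUE, num_threads = 1, verbose = FALSE)
    kl <- unname(utils::tail(fit$itercosts, 1))
    if (is.null(best) || kl < best$kl) best <- list(fit = fit, kl = kl)
  }
  coords <- best$fit$Y
  colnames(coords) <- c("tsne1", "tsne2")
  structure(list(coords = coords, perplexity = perplexity, seed = as.integer(seed),
                 kl = best$kl),
            class = "embedded_points")
}

#' @export
print.embedded_points <- function(x, ...) {
  cat(sprintf("embedded_points: %d points, perplexity %g, final KL %.4f\n",
              nrow(x$coords), x$perplexity, x$kl))
  invisible(x)
}

as_coords <- function(points) {
  if (inherits(points, "embedded_points")) points$coords else as.matrix(points)
}

# k-means++ seeding: first center uniform, then prob proportional to squared
# distance to the nearest chosen center.
kmpp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1, ] <- x[sample.int(n, 1, prob = p), ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j + 1, ], n, ncol(x), byrow = TRUE))^2))
  }
  centers
}

kmeans_pp <- function(x, k, nstart = 10) {
  best <- NULL
  for (s in seq_len(nstart)) {
    for (attempt in 1:5) {
      cc <- kmpp_centers(x, k)
      km <- tryCatch(suppressWarnings(stats::kmeans(x, centers = cc,
                                                    iter.max = 100,
                                                    algorithm = "Lloyd")),
                     error = function(e) NULL)
      if (!is.null(km) && all(km$size > 0)) break
      km <- NULL
    }
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("k-means failed to produce a valid partition")
  best
}

#' Cluster embedded points with seeded k-means
#'
#' k-means with k-means++ initialization and `nstart` restarts on the
#' z-scored 2D map coordinates (the lowest within-cluster sum of squares
#' partition is kept). Deterministic for a fixed seed.
#'
#' @param points an `embedded_points` object or n x 2 matrix.
#' @param k number of clusters (>= 2).
#' @param seed integer seed.
#' @param nstart number of k-means++ restarts.
#' @param zscore_coords standardize the map coordinates first (default TRUE).
#' @return object of class `cluster_model`: `k`, `centers` (on the clustered
#'   scale), `labels`, `tot_withinss`, `seed`.
#' @export
cluster_kmeans <- function(points, k, seed = 1L, nstart = 10,
                           zscore_coords = TRUE) {
  x <- as_coords(points)
  if (k < 2) stop("k must be >= 2")
  if (k > nrow(unique(x))) stop("k exceeds the number of distinct points")
  if (zscore_coords) x <- zscore(x)
  set.seed(as.integer(seed))
  km <- kmeans_pp(x, k, nstart)
  structure(list(k = k, centers = km$centers, labels = as.integer(km$cluster),
                 tot_withinss = km$tot.withinss, seed = as.integer(seed)),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: k = %d, sizes %s, tot within-SS %.3f\n",
              x$k, paste(tabulate(x$labels, x$k), collapse = "/"),
              x$tot_withinss))
  invisible(x)
}

#' Select the number of clusters by silhouette and gap statistic
#'
#' For each candidate k, runs seeded k-means (k-means++ with 10 restarts) and
#' records the mean silhouette width; the gap statistic (uniform reference
#' over the data bounding box, B = `b_ref` references, standard-error rule) is
#' computed over 1..max(k_range). When the two criteria disagree, the
#' silhouette-optimal k is operative and the disagreement is reported.
#'
#' @param points `embedded_points` or numeric matrix.
#' @param k_range candidate cluster counts (default 2:6).
#' @param b_ref number of gap-statistic reference data sets (default 50).
#' @param seed integer seed.
#' @param nstart k-means restarts per candidate.
#' @return list: `k` (operative, silhouette-optimal), `criterion`,
#'   `silhouette_k`, `gap_k`, `silhouette_by_k` and `gap_by_k` data.frames,
#'   `agree` flag.
#' @export
select_k <- function(points, k_range = 2:6, b_ref = 50, seed = 1L, nstart = 10) {
  x <- as_coords(points)
  k_range <- sort(unique(as.integer(k_range)))
  if (nrow(x) < 2 * max(k_range)) stop("too few points for the requested k range")
  if (nrow(unique(x)) < 2) stop("all points coincide; clustering is degenerate")
  z <- zscore(x)
  dz <- stats::dist(z)
  sil <- vapply(k_range, function(k) {
    cm <- cluster_kmeans(z, k, seed = seed + k, nstart = nstart,
                         zscore_coords = FALSE)
    mean(cluster::silhouette(cm$labels, dz)[, "sil_width"])
  }, numeric(1))
  fun <- function(x, k) {
    if (k == 1) return(list(cluster = rep(1L, nrow(x))))
    list(cluster = kmeans_pp(x, k, nstart)$cluster)
  }
  set.seed(as.integer(seed))
  cg <- cluster::clusGap(z, FUNcluster = fun, K.max = max(k_range), B = b_ref,
                         d.power = 2, spaceH0 = "original", verbose = FALSE)
  gap_k <- cluster::maxSE(cg$Tab[, "gap"], cg$Tab[, "SE.sim"],
                          method = "Tibs2001SEmax")
  sil_k <- k_range[which.max(sil)]
  list(k = sil_k, criterion = "silhouette", silhouette_k = sil_k,
       gap_k = as.integer(gap_k), agree = identical(as.integer(gap_k), sil_k),
       silhouette_by_k = data.frame(k = k_range, silhouette = sil),
       gap_by_k = data.frame(k = seq_len(max(k_range)),
                             gap = cg$Tab[, "gap"], se = cg$Tab[, "SE.sim"]))
}

#' Per-dimension normality check of the embedding
#'
#' Lilliefors-corrected one-sample Kolmogorov-Smirnov test of each map
#' dimension against a normal distribution with estimated mean and standard
#' deviation; used to justify the nonparametric cluster-separation test.
#'
#' @param points `embedded_points` or numeric matrix with >= 8 rows.
#' @return named numeric vector of per-dimension p-values.
#' @export
normality_check <- function(points) {
  x <- as_coords(points)
  if (nrow(x) < 8) stop("need at least 8 points for the normality check")
  p <- apply(x, 2, function(v) nortest::lillie.test(v)$p.value)
  names(p) <- colnames(x) %||% paste0("dim", seq_len(ncol(x)))
  p
}
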