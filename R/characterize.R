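#' Per-STMP, per-group feature summary and group comparison
#'
#' For every (feature, STMP) cell, computes the group means and sample
#' standard deviations over window-level values and compares the HC and PD
#' groups with a two-sided Wilcoxon rank-sum (Mann-Whitney) test (normal
#' approximation with tie correction). Window-level values are the test units;
#' no multiplicity adjustment is applied to the reported p-value (a
#' Benjamini-Hochberg column is emitted additionally for transparency). Cells
#' where either group has fewer than 3 windows are marked untestable rather
#' than dropped.
#'
#' @param features a `feature_matrix` (or data.frame with the seven feature
#'   columns plus subject_id, trial, window_idx).
#' @param labels_df labels table: subject_id, trial, window_idx, group, cluster.
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @return data.frame of class `characterization_table`: feature, stmp,
#'   hc_mean, hc_sd, pd_mean, pd_sd, n_hc, n_pd, p_value, p_bh, significant,
#'   testable.
#' @export
characterize_stmps <- function(features, labels_df, alpha = 0.05) {
  d <- merge(as.data.frame(features),
             labels_df[, c("subject_id", "trial", "window_idx", "cluster")],
             by = c("subject_id", "trial", "window_idx"))
  feats <- feature_columns()
  ks <- sort(unique(d$cluster))
  rows <- list()
  for (f in feats) for (k in ks) {
    cell <- d[d$cluster == k, , drop = FALSE]
    hc <- cell[[f]][cell$group == "HC"]
    pd <- cell[[f]][cell$group == "PD"]
    hc <- hc[is.finite(hc)]; pd <- pd[is.finite(pd)]
    if (length(hc) + length(pd) == 0) next
    testable <- length(hc) >= 3 && length(pd) >= 3
    p <- if (testable)
      stats::wilcox.test(hc, pd, exact = FALSE, correct = TRUE)$p.value
    else NA_real_
    rows[[length(rows) + 1]] <- data.frame(
      feature = f, stmp = k,
      hc_mean = if (length(hc)) mean(hc) else NA_real_,
      hc_sd = if (length(hc) > 1) stats::sd(hc) else NA_real_,
      pd_mean = if (length(pd)) mean(pd) else NA_real_,
      pd_sd = if (length(pd) > 1) stats::sd(pd) else NA_real_,
      n_hc = length(hc), n_pd = length(pd),
      p_value = p, testable = testable)
  }
  out <- do.call(rbind, rows)
  out$p_bh <- NA_real_
  out$p_bh[out$testable] <- stats::p.adjust(out$p_value[out$testable], "BH")
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  class(out) <- c("characterization_table", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' Shapiro-Wilk normality gate per cell
#'
#' Shapiro-Wilk p-value per (feature, STMP, group) cell, logged as the
#' justification for the nonparametric group comparison; it does not alter
#' the analysis path.
#'
#' @param values numeric vector for one cell, with 3 <= n <= 5000.
#' @return Shapiro-Wilk p-value.
#' @export
normality_gate <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  stats::shapiro.test(values)$p.value
}

#' Normality gate applied to every (feature, STMP, group) cell
#'
#' @param features a `feature_matrix`.
#' @param labels_df labels table with `cluster` per window.
#' @return data.frame: feature, stmp, group, n, p_shapiro (NA when out of the
#'   valid Shapiro-Wilk range or degenerate).
#' @export
normality_gate_table <- function(features, labels_df) {
  d <- merge(as.data.frame(features),
             labels_df[, c("subject_id", "trial", "window_idx", "cluster")],
             by = c("subject_id", "trial", "window_idx"))
  feats <- feature_columns()
  out <- expand.grid(feature = feats, stmp = sort(unique(d$cluster)),
                     group = sort(unique(d$group)), stringsAsFactors = FALSE)
  out$n <- NA_integer_; out$p_shapiro <- NA_real_
  for (i in seq_len(nrow(out))) {
    v <- d[[out$feature[i]]][d$cluster == out$stmp[i] & d$group == out$group[i]]
    v <- v[is.finite(v)]
    out$n[i] <- length(v)
    if (length(v) >= 3 && length(v) <= 5000 && stats::sd(v) > 0)
      out$p_shapiro[i] <- stats::shapiro.test(v)$p.value
  }
  out
}
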