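#' Full-run configuration
#'
#' One master seed drives every stochastic stage; per-stage seeds are derived
#' by fixed offsets so a run is exactly reproducible from the configuration
#' alone.
#'
#' @param cohort a [cohort_spec()] (its own seed is overridden by the derived
#'   simulation seed unless `keep_cohort_seed = TRUE`).
#' @param preprocess a [preprocess_config()].
#' @param windows a [window_config()].
#' @param perplexity t-SNE perplexity.
#' @param k_range candidate cluster counts.
#' @param b_ref gap-statistic reference sets.
#' @param n_perm permutations for the pairwise cluster tests.
#' @param alpha significance level for the characterization.
#' @param seed master integer seed.
#' @param keep_cohort_seed keep the seed already set in `cohort`.
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(), preprocess = preprocess_config(),
                       windows = window_config(), perplexity = 10,
                       k_range = 2:6, b_ref = 50, n_perm = 1000,
                       alpha = 0.05, seed = 1L, keep_cohort_seed = FALSE) {
  seed <- as.integer(seed)
  if (!keep_cohort_seed) cohort$seed <- seed
  structure(list(cohort = cohort, preprocess = preprocess, windows = windows,
                 perplexity = perplexity, k_range = k_range, b_ref = b_ref,
                 n_perm = n_perm, alpha = alpha, seed = seed),
            class = "run_config")
}

stage_seeds <- function(seed) {
  list(simulate = seed, tsne = seed + 101L, select_k = seed + 211L,
       kmeans = seed + 307L, perm = seed + 401L)
}

#' Run the complete STMP identification and characterization pipeline
#'
#' Stage order: simulate (or accept supplied recordings) -> preprocess ->
#' windowed features -> z-score -> t-SNE -> k selection (silhouette + gap) ->
#' k-means -> canonical STMP numbering -> dynamics (frequency, transitions,
#' persistence) -> pairwise Fasano-Franceschini tests -> group
#' characterization. When `out_dir` is given, every output table is written
#' as CSV together with a manifest (configuration, derived seeds, versions);
#' a rerun with the same configuration is byte-identical.
#'
#' @param config a [run_config()].
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param recordings optional list of raw `gyro_recording`s; skips simulation.
#' @param k optional fixed cluster count; skips model selection.
#' @return list with cohort, features, embedding, selection, model, labels,
#'   dynamics, ff2d, characterization, normality, manifest.
#' @export
run_all <- function(config = run_config(), out_dir = NULL, recordings = NULL,
                    k = NULL) {
  stopifnot(inherits(config, "run_config"))
  seeds <- stage_seeds(config$seed)

  if (is.null(recordings)) {
    cohort <- generate_cohort(config$cohort)
    recordings <- cohort$recordings
  } else {
    cohort <- list(recordings = recordings, metadata = NULL, truth = NULL)
  }

  pre <- lapply(recordings, preprocess, cfg = config$preprocess)
  features <- extract_feature_matrix(pre, config$windows)

  fm <- as.matrix(features[, feature_columns()])
  keep <- rowSums(!is.finite(fm)) == 0
  z <- zscore(fm[keep, , drop = FALSE])
  emb <- embed_2d(z, perplexity = config$perplexity, seed = seeds$tsne)

  selection <- if (is.null(k)) {
    select_k(emb, k_range = config$k_range, b_ref = config$b_ref,
             seed = seeds$select_k)
  } else list(k = as.integer(k), criterion = "fixed")
  model <- cluster_kmeans(emb, selection$k, seed = seeds$kmeans)

  canon <- canonicalize_labels(model$labels, features$mav[keep])
  labels_df <- data.frame(features[keep, c("subject_id", "group", "trial",
                                           "window_idx")],
                          tsne1 = emb$coords[, 1], tsne2 = emb$coords[, 2],
                          cluster = canon$labels, row.names = NULL)

  dynamics <- stmp_dynamics(labels_df, k = selection$k)
  ff2d <- ff2d_pairwise(emb, canon$labels, n_perm = config$n_perm,
                        seed = seeds$perm)
  characterization <- characterize_stmps(features[keep, , drop = FALSE],
                                         labels_df, alpha = config$alpha)
  normality <- list(embedding = normality_check(emb),
                    cells = normality_gate_table(features[keep, , drop = FALSE],
                                                 labels_df))

  manifest <- list(
    package = "stmpr",
    version = as.character(utils::packageVersion("stmpr")),
    seed = config$seed, stage_seeds = seeds,
    k = selection$k, k_criterion = selection$criterion,
    perplexity = config$perplexity, n_perm = config$n_perm,
    alpha = config$alpha,
    cohort = list(n_hc = config$cohort$n_hc, n_pd = config$cohort$n_pd,
                  trials_per_subject = config$cohort$trials_per_subject,
                  trial_s = config$cohort$trial_s, fs_hz = config$cohort$fs_hz,
                  quantize_bits = config$cohort$quantize_bits,
                  clip_dps = config$cohort$clip_dps),
    preprocess = unclass(config$preprocess),
    windows = unclass(config$windows))

  result <- list(cohort = cohort, features = features, embedding = emb,
                 selection = selection, model = model, labels = labels_df,
                 dynamics = dynamics, ff2d = ff2d,
                 characterization = characterization, normality = normality,
                 manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_signal_csv(recordings, file.path(out_dir, "signals.csv"))
    if (!is.null(cohort$truth))
      write_truth_csv(cohort$truth, file.path(out_dir, "truth.csv"))
    write_features_csv(features, file.path(out_dir, "features.csv"))
    write_labels_csv(labels_df, file.path(out_dir, "labels.csv"))
    trans_long <- do.call(rbind, lapply(names(dynamics$transitions), function(g) {
      tm <- dynamics$transitions[[g]]
      data.frame(group = g,
                 from = rep(seq_len(nrow(tm$P)), ncol(tm$P)),
                 to = rep(seq_len(ncol(tm$P)), each = nrow(tm$P)),
                 p = as.vector(tm$P), count = as.vector(tm$counts))
    }))
    utils::write.csv(trans_long, file.path(out_dir, "transitions.csv"),
                     row.names = FALSE)
    utils::write.csv(dynamics$persistence, file.path(out_dir, "persistence.csv"),
                     row.names = FALSE)
    utils::write.csv(dynamics$frequency, file.path(out_dir, "frequency.csv"),
                     row.names = FALSE)
    utils::write.csv(ff2d, file.path(out_dir, "ff2d.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(characterization),
                     file.path(out_dir, "characterization.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  result
}
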