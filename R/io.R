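check_columns <- function(df, expected, path) {
  missing <- setdiff(expected, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s): %s", path, paste(missing, collapse = ", ")))
  invisible(TRUE)
}

#' Write a cohort of recordings to a signal CSV
#'
#' Long-format signal table with columns subject_id, group, trial, t_s,
#' gx_dps (UTF-8, header row, decimal point).
#'
#' @param recordings list of `gyro_recording` objects.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_signal_csv <- function(recordings, path) {
  if (inherits(recordings, "gyro_recording")) recordings <- list(recordings)
  tabs <- lapply(recordings, function(r)
    data.frame(subject_id = r$subject_id, group = r$group, trial = r$trial,
               t_s = (seq_along(r$samples) - 1) / r$fs_hz, gx_dps = r$samples))
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' Read a signal CSV into a list of recordings
#'
#' Validates the schema (subject_id, group, trial, t_s, gx_dps), that `t_s`
#' is strictly increasing and uniformly spaced within each trial, and infers
#' the sampling rate from the time step.
#'
#' @param path input file path.
#' @return list of `gyro_recording` objects.
#' @export
read_signal_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("subject_id", "group", "trial", "t_s", "gx_dps"), path)
  key <- interaction(df$subject_id, df$trial, drop = TRUE)
  fs_all <- numeric(0)
  recs <- lapply(split(df, key), function(d) {
    dt <- diff(d$t_s)
    if (any(dt <= 0))
      stop(sprintf("%s: t_s not strictly increasing in subject %s trial %d",
                   path, d$subject_id[1], d$trial[1]))
    if (max(dt) - min(dt) > 1e-6)
      stop(sprintf("%s: non-uniform sampling in subject %s trial %d",
                   path, d$subject_id[1], d$trial[1]))
    fs <- 1 / stats::median(dt)
    fs_all <<- c(fs_all, fs)
    structure(list(subject_id = d$subject_id[1], group = d$group[1],
                   trial = d$trial[1], axis = "X", fs_hz = fs,
                   trial_s = length(d$gx_dps) / fs, samples = d$gx_dps,
                   truth_states = NULL, step_s = 0.5),
              class = "gyro_recording")
  })
  if (diff(range(fs_all)) > 1e-3)
    stop(sprintf("%s: mixed sampling rates across trials", path))
  unname(recs)
}

#' Write the hidden-regime ground truth to CSV
#' @param truth data.frame from [generate_cohort()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  check_columns(truth, c("subject_id", "trial", "step_idx", "t_start_s", "regime"), "truth")
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' Write / read the window feature table
#' @param features a `feature_matrix`.
#' @param path file path.
#' @return the path (write) or a `feature_matrix` data.frame (read), invisibly
#'   for the writer.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("subject_id", "group", "trial", "window_idx", "t_start_s",
                      feature_columns(), "outlier_flag"), path)
  class(df) <- c("feature_matrix", "data.frame")
  df
}

#' Write / read the window label (map coordinates + cluster) table
#' @param labels_df labels table: subject_id, group, trial, window_idx,
#'   tsne1, tsne2, cluster.
#' @param path file path.
#' @return the path (write) or the labels data.frame (read).
#' @export
write_labels_csv <- function(labels_df, path) {
  check_columns(labels_df, c("subject_id", "group", "trial", "window_idx",
                             "tsne1", "tsne2", "cluster"), "labels")
  utils::write.csv(labels_df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels_csv
#' @export
read_labels_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("subject_id", "group", "trial", "window_idx",
                      "tsne1", "tsne2", "cluster"), path)
  df
}
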