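#' Canonicalize cluster labels into STMP numbers
#'
#' k-means cluster ids are arbitrary; STMPs are numbered by amplitude so that
#' STMP 1 has the lowest mean MAV over its member windows and STMP k the
#' highest (ties broken by the lower original cluster id). Deterministic given
#' its inputs and invariant to permutations of the input cluster ids.
#'
#' @param labels integer cluster label per window.
#' @param mav numeric MAV per window (same order as `labels`).
#' @return list: `labels` (canonical STMP per window), `map` (named vector,
#'   old id -> STMP number), `cluster_mav` (mean MAV per canonical STMP).
#' @export
canonicalize_labels <- function(labels, mav) {
  stopifnot(length(labels) == length(mav))
  ks <- sort(unique(labels))
  means <- vapply(ks, function(k) mean(mav[labels == k]), numeric(1))
  ord <- order(means, ks)
  map <- integer(length(ks))
  map[ord] <- seq_along(ks)
  names(map) <- ks
  list(labels = unname(map[as.character(labels)]),
       map = map,
       cluster_mav = sort(means))
}

# Split a labels data.frame into per-trial ordered label sequences.
label_sequences <- function(labels_df) {
  key <- interaction(labels_df$subject_id, labels_df$trial, drop = TRUE)
  lapply(split(labels_df[order(labels_df$window_idx), , drop = FALSE],
               key[order(labels_df$window_idx)]),
         function(d) structure(d$cluster, group = d$group[1]))
}

#' Group share of each STMP
#'
#' For each STMP, the fraction of its member windows contributed by each
#' group; fractions sum to 1 within an STMP.
#'
#' @param labels_df data.frame with columns `cluster` and `group`.
#' @param k number of STMPs (default: observed maximum).
#' @return data.frame: stmp, group, n, proportion.
#' @export
stmp_frequency <- function(labels_df, k = max(labels_df$cluster)) {
  if (nrow(labels_df) == 0) stop("empty label table")
  tab <- table(factor(labels_df$cluster, levels = seq_len(k)), labels_df$group)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("stmp", "group", "n")
  out$stmp <- as.integer(out$stmp)
  tot <- stats::ave(out$n, out$stmp, FUN = sum)
  out$proportion <- ifelse(tot > 0, out$n / tot, NA_real_)
  out[order(out$stmp, out$group), , drop = FALSE]
}

#' Maximum-likelihood STMP transition matrix
#'
#' Estimates `p_ij = Pr(X_n = j | X_{n-1} = i)` from consecutive window pairs,
#' counted within trials only (sequences are never concatenated across
#' trials). Rows with no observed outgoing transition are flagged and left as
#' `NA` rather than silently zero-filled.
#'
#' @param sequences list of integer label sequences (one per trial), e.g. from
#'   splitting a labels table by trial.
#' @param k number of STMP states.
#' @return object of class `transition_matrix`: `P` (k x k), `counts`,
#'   `unobserved_rows`.
#' @export
transition_matrix <- function(sequences, k) {
  if (is.numeric(sequences)) sequences <- list(sequences)
  if (all(vapply(sequences, length, integer(1)) < 2))
    stop("need at least one sequence of length >= 2")
  counts <- matrix(0, k, k)
  for (s in sequences) {
    if (length(s) < 2) next
    from <- s[-length(s)]; to <- s[-1]
    for (i in seq_along(from)) counts[from[i], to[i]] <- counts[from[i], to[i]] + 1
  }
  rs <- rowSums(counts)
  P <- counts / ifelse(rs > 0, rs, NA_real_)
  structure(list(P = P, counts = counts, unobserved_rows = which(rs == 0)),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("STMP transition matrix (MLE):\n")
  print(round(x$P, 3))
  if (length(x$unobserved_rows))
    cat("rows with no observed transitions:",
        paste(x$unobserved_rows, collapse = ", "), "\n")
  invisible(x)
}

#' Number of permanence blocks of an STMP in a sequence
#'
#' A permanence block is a maximal run of consecutive windows assigned to the
#' same STMP.
#'
#' @param sequence integer label sequence (one trial).
#' @param stmp_i STMP label of interest.
#' @return number of maximal runs of `stmp_i` (0 when absent).
#' @export
permanence_blocks <- function(sequence, stmp_i) {
  if (length(sequence) == 0) return(0L)
  r <- rle(as.vector(sequence))
  sum(r$values == stmp_i)
}

#' Persistence time of an STMP
#'
#' `D(i) = (n_i / r_i) * 0.06`, where `n_i` is the number of member windows of
#' STMP i pooled over the supplied sequences and `r_i` the number of
#' permanence blocks (runs counted within trials, pooled). The 0.06 constant
#' converts the ratio to the millisecond scale used when reporting; when
#' `r_i = 0` the fallback is `D_i = n_i`. With `physical = TRUE` the
#' physically scaled alternative `step_s * n_i / r_i` seconds is returned
#' instead.
#'
#' @param sequences list of integer label sequences (or a single sequence).
#' @param stmp_i STMP label of interest.
#' @param constant unit-conversion constant (default 0.06, milliseconds).
#' @param physical use `step_s * n_i / r_i` seconds instead of the 0.06 scale.
#' @param step_s window step in seconds (used only when `physical = TRUE`).
#' @return list: `n`, `r`, `D`.
#' @export
persistence_time <- function(sequences, stmp_i, constant = 0.06,
                             physical = FALSE, step_s = 0.5) {
  if (is.numeric(sequences)) sequences <- list(sequences)
  n <- sum(vapply(sequences, function(s) sum(s == stmp_i), numeric(1)))
  r <- sum(vapply(sequences, permanence_blocks, numeric(1), stmp_i = stmp_i))
  scale <- if (physical) step_s else constant
  D <- if (r > 0) (n / r) * scale else n
  list(n = n, r = r, D = D)
}

#' Per-group STMP dynamics summary
#'
#' Computes, per group, the transition matrix and the per-STMP persistence
#' table (pooled `n_i`, `r_i`, `D_i`), plus per-subject persistence times for
#' inspection.
#'
#' @param labels_df labels table: subject_id, group, trial, window_idx, cluster.
#' @param k number of STMPs.
#' @param constant persistence-time constant (default 0.06).
#' @return list: `transitions` (named list of `transition_matrix` per group),
#'   `persistence` (data.frame group, stmp, n, r, D_ms), `frequency`
#'   (from [stmp_frequency()]), `persistence_by_subject`.
#' @export
stmp_dynamics <- function(labels_df, k = max(labels_df$cluster), constant = 0.06) {
  seqs <- label_sequences(labels_df)
  grp_of <- vapply(seqs, function(s) attr(s, "group"), character(1))
  groups <- sort(unique(grp_of))
  transitions <- lapply(groups, function(g) transition_matrix(seqs[grp_of == g], k))
  names(transitions) <- groups
  persistence <- do.call(rbind, lapply(groups, function(g) {
    do.call(rbind, lapply(seq_len(k), function(i) {
      p <- persistence_time(seqs[grp_of == g], i, constant = constant)
      data.frame(group = g, stmp = i, n = p$n, r = p$r, D_ms = p$D)
    }))
  }))
  subj <- unique(labels_df[, c("subject_id", "group")])
  persistence_by_subject <- do.call(rbind, lapply(seq_len(nrow(subj)), function(s) {
    sd_df <- labels_df[labels_df$subject_id == subj$subject_id[s], , drop = FALSE]
    sseqs <- label_sequences(sd_df)
    do.call(rbind, lapply(seq_len(k), function(i) {
      p <- persistence_time(sseqs, i, constant = constant)
      data.frame(subject_id = subj$subject_id[s], group = subj$group[s],
                 stmp = i, n = p$n, r = p$r, D_ms = p$D)
    }))
  }))
  list(transitions = transitions, persistence = persistence,
       frequency = stmp_frequency(labels_df, k),
       persistence_by_subject = persistence_by_subject)
}
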