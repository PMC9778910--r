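test_that("canonical STMP numbering sorts clusters by mean member MAV", {
  labels <- c(1, 1, 2, 2, 3, 3)
  mav <- c(20, 22, 0.3, 0.35, 0.6, 0.62)
  out <- canonicalize_labels(labels, mav)
  expect_equal(out$labels, c(3, 3, 1, 1, 2, 2))
  # permuting input ids leaves the canonical labelling unchanged
  perm <- c(2, 2, 3, 3, 1, 1)
  out2 <- canonicalize_labels(perm, mav)
  expect_equal(out2$labels, out$labels)
  # k = 1 is the identity
  expect_equal(canonicalize_labels(rep(1, 4), 1:4)$labels, rep(1, 4))
  # ties break toward the lower original cluster id
  tied <- canonicalize_labels(c(2, 1), c(5, 5))
  expect_equal(tied$labels, c(2, 1))
})

test_that("STMP frequency proportions sum to one within each pattern", {
  df <- data.frame(cluster = c(rep(1, 20), rep(2, 10)),
                   group = c(rep("HC", 10), rep("PD", 10),
                             rep("HC", 5), rep("PD", 5)))
  f <- stmp_frequency(df, k = 2)
  expect_equal(f$proportion[f$stmp == 1], c(0.5, 0.5))
  expect_equal(f$proportion[f$stmp == 2], c(0.5, 0.5))
  one <- stmp_frequency(data.frame(cluster = c(1, 1, 2), group = "PD"), k = 2)
  expect_equal(one$proportion[one$group == "PD"], c(1, 1))
  expect_error(stmp_frequency(df[0, ]), "empty")
})

test_that("transition matrices follow the maximum-likelihood counts", {
  tm <- transition_matrix(list(c(1, 1, 1, 1)), k = 3)
  expect_equal(tm$P[1, ], c(1, 0, 0))
  expect_equal(tm$unobserved_rows, c(2L, 3L))
  expect_true(all(is.na(tm$P[2, ])))

  tm2 <- transition_matrix(list(c(1, 2, 1, 2, 1)), k = 2)
  expect_equal(tm2$P, matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE))

  # sequences never concatenate across trials
  tm3 <- transition_matrix(list(c(1, 1), c(2, 2)), k = 2)
  expect_equal(tm3$counts, diag(c(1, 1)))
  expect_error(transition_matrix(list(1, 2), k = 2), "length >= 2")
})

test_that("permanence blocks count maximal runs", {
  expect_equal(permanence_blocks(c(2, 2, 1, 2), 2), 2)
  expect_equal(permanence_blocks(c(3, 3, 3), 1), 0)
  # a sequence with 20 samples of label 2 spread over 6 maximal runs
  fig_seq <- c(2, 2, 2, 2, 1, 2, 2, 2, 2, 3, 2, 2, 2, 2, 1, 2, 2, 2, 3,
               2, 2, 2, 1, 2, 2, 3)
  expect_equal(sum(fig_seq == 2), 20)
  expect_equal(permanence_blocks(fig_seq, 2), 6)
})

test_that("persistence time follows D = n/r x 0.06 with its stated fallbacks", {
  fig_seq <- c(2, 2, 2, 2, 1, 2, 2, 2, 2, 3, 2, 2, 2, 2, 1, 2, 2, 2, 3,
               2, 2, 2, 1, 2, 2, 3)
  p <- persistence_time(fig_seq, 2)
  expect_equal(p$n, 20); expect_equal(p$r, 6)
  expect_equal(p$D, 0.2)                       # worked example: 20/6 x 0.06

  single <- persistence_time(c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1), 1)
  expect_equal(single$D, 0.6)                  # one block of 10
  absent <- persistence_time(c(3, 3), 1)
  expect_equal(absent$D, 0)                    # n = 0, r = 0 fallback D = n
  phys <- persistence_time(fig_seq, 2, physical = TRUE, step_s = 0.5)
  expect_equal(phys$D, 20 / 6 * 0.5)
})

test_that("persistence identity D x r = n x 0.06 holds and windows are conserved", {
  set.seed(61)
  seqs <- lapply(1:10, function(i) sample(1:3, 25, replace = TRUE))
  total <- 0
  for (i in 1:3) {
    p <- persistence_time(seqs, i)
    if (p$r > 0) expect_equal(p$D * p$r, p$n * 0.06, tolerance = 1e-12)
    total <- total + p$n
  }
  expect_equal(total, 250)
})

test_that("group dynamics tables are consistent on a synthetic label set", {
  set.seed(62)
  df <- do.call(rbind, lapply(1:6, function(s) {
    do.call(rbind, lapply(1:2, function(tr) {
      data.frame(subject_id = sprintf("S%02d", s),
                 group = if (s <= 3) "HC" else "PD", trial = tr,
                 window_idx = 1:20,
                 cluster = sample(1:3, 20, replace = TRUE, prob = c(2, 1, 1)))
    }))
  }))
  dyn <- stmp_dynamics(df, k = 3)
  for (g in c("HC", "PD")) {
    P <- dyn$transitions[[g]]$P
    rs <- rowSums(P)
    expect_true(all(abs(rs[!is.na(rs)] - 1) < 1e-9))
  }
  # sum over STMPs of n equals total windows per group
  agg <- tapply(dyn$persistence$n, dyn$persistence$group, sum)
  expect_equal(unname(agg[["HC"]]), sum(df$group == "HC"))
  expect_equal(unname(agg[["PD"]]), sum(df$group == "PD"))
  expect_equal(sum(dyn$frequency$n), nrow(df))
})
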