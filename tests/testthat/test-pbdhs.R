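test_that("block decomposition counts blocks and leaves per block", {
  # lightweight stand-in for the full regime: 19 channels, short windows
  ev <- make_events(n_channels = 19, n_windows = 20, fs = 10, seed = 1)
  b1 <- block_series(ev, 1)
  expect_length(b1, 20)
  expect_equal(attr(b1, "m"), 19)
  expect_true(all(vapply(b1, function(b) b$n_leaves, 0) == 19))

  b10 <- block_series(ev, 10)
  expect_length(b10, 2)
  expect_equal(b10[[1]]$n_leaves, 190)

  # floor division drops the trailing partial block: 20 %/% 3 = 6
  b3 <- block_series(ev, 3)
  expect_length(b3, 6)

  expect_error(block_series(ev, 21), "fewer windows")
  expect_error(block_series(ev, 0), "positive integer")
})

test_that("dual thresholds: single-block equivalence and the z1-huge limit", {
  ev <- make_events(n_channels = 5, n_windows = 8, fs = 12, seed = 2)
  blocks <- block_series(ev, 8)             # one block covering everything
  expect_length(blocks, 1)
  dt <- dual_threshold_counts(blocks, z1 = 2, z2 = 3)
  expect_equal(dt$global_max_ball, blocks[[1]]$max_ball)

  # with one block, E under z1 equals PUDHS under z = z1 on the same tree
  expect_equal(dt$E[1], compute_pudhs(blocks[[1]], 2)$pudhs)

  # z1 far beyond any ball leaves only the all-zeros branch below threshold
  blocks4 <- block_series(ev, 2)
  dt2 <- dual_threshold_counts(blocks4, z1 = 60, z2 = 60)
  v0 <- vapply(blocks4, function(b) sum(b$ball == -Inf), 0)
  expect_equal(dt2$E, as.integer(v0))
  expect_true(all(v0 >= 1))                 # codes convention: one all-zeros leaf

  # identical blocks give identical (E, E1)
  two <- blocks4[c(1, 1)]
  attr(two, "block_windows") <- 2L
  dt3 <- dual_threshold_counts(two, 2, 2)
  expect_equal(dt3$E[1], dt3$E[2])
  expect_equal(dt3$E1[1], dt3$E1[2])
})

test_that("E and E1 stay within [0, m] across regimes", {
  for (bw in c(1, 2, 4)) {
    ev <- make_events(n_channels = 6, n_windows = 8, fs = 15, seed = bw)
    blocks <- block_series(ev, bw)
    for (z1 in c(1, 3)) for (z2 in c(1, 3)) {
      dt <- dual_threshold_counts(blocks, z1, z2)
      expect_true(all(dt$E >= 0 & dt$E <= dt$m))
      expect_true(all(dt$E1 >= 0 & dt$E1 <= dt$m))
    }
  }
})

test_that("histograms tabulate E values with conservation", {
  fake <- structure(list(m = 19L, n_blocks = 3L, block_windows = 1L,
                         max_ball = c(4, 4, 4), global_max_ball = 4,
                         E = c(2L, 2L, 5L), E1 = c(0L, 1L, 19L),
                         z1 = 1L, z2 = 1L), class = "dh_blockseries")
  h <- histograms(fake)
  expect_equal(h$F[2], 2)
  expect_equal(h$F[5], 1)
  expect_equal(sum(h$F), 3)
  expect_equal(h$F1[1], 1)
  expect_equal(h$F1[19], 1)
  expect_equal(sum(h$F1) + h$n_zero_E1, 3)   # E1 = 0 falls in no bin

  fake$E <- c(0L, 0L, 0L)
  expect_true(all(histograms(fake)$F == 0))
})

test_that("PBDHS reproduces the hand-worked 10/7 example and its bounds", {
  F <- c(4, 0, rep(0, 17))
  F1 <- c(0, 0, 1, 3, rep(0, 15))
  expect_equal(compute_pbdhs(F, F1, p = c(1, 2), p1 = c(3, 4)), 10 / 7)

  # equal products give exactly 1; a single bin gives exactly 1
  expect_equal(compute_pbdhs(rep(2, 5), rep(3, 5), p = 1:3, p1 = 1:3), 1)
  expect_equal(compute_pbdhs(F, F1, p = 1, p1 = 3), 1)

  expect_error(compute_pbdhs(F, F1, p = integer(0), p1 = integer(0)), "empty")
  expect_error(compute_pbdhs(F, F1, p = c(1, 25), p1 = c(1, 2)), "1..m")
  h <- histograms(structure(list(m = 19L, n_blocks = 2L, block_windows = 1L,
                                 max_ball = c(3, 3), global_max_ball = 3,
                                 E = c(1L, 1L), E1 = c(2L, 2L),
                                 z1 = 1L, z2 = 1L), class = "dh_blockseries"))
  expect_gte(compute_pbdhs(h, p = c(1, 2), p1 = c(2, 3)), 1)
})

test_that("PBDHS >= 1 over random histograms", {
  set.seed(10)
  for (i in 1:50) {
    m <- sample(5:30, 1)
    F <- rpois(m, 2); F1 <- rpois(m, 2)
    h <- sample(1:m, 1)
    v <- compute_pbdhs(F, F1, p = sample.int(m, h), p1 = sample.int(m, h))
    expect_gte(v, 1)
  }
})

test_that("the randomized search is deterministic and separates a separable cohort", {
  co <- make_cohort(n_per_group = 3, duration = 6, fs = 50,
                    couplings = c(a = 0.95, b = 0.05), seed = 11)
  blocks <- lapply(co, function(s)
    block_series(segment_events(s$recording), 2))
  labels <- vapply(co, `[[`, "", "label")
  run <- function() search_pbdhs(blocks, labels, z1_range = 1:3,
                                 z2_range = 1:3, h = 4, n_reps = 20, seed = 5)
  r1 <- run(); r2 <- run()
  expect_identical(r1$best, r2$best)
  expect_identical(r1$per_subject, r2$per_subject)
  expect_equal(nrow(r1$auc_grid), 9)
  expect_true(all(r1$auc_grid$best_auc_sum <= 1))   # one pair -> max 1
  expect_gte(r1$best$summed_auc, 0.5)

  # three groups sum three pairwise AUCs, bounded by 3
  co3 <- make_cohort(n_per_group = 2, duration = 4, fs = 50,
                     couplings = c(a = 0.9, b = 0.5, c = 0.1), seed = 12)
  blocks3 <- lapply(co3, function(s) block_series(segment_events(s$recording), 1))
  r3 <- search_pbdhs(blocks3, vapply(co3, `[[`, "", "label"),
                     z1_range = 1:2, z2_range = 1:2, h = 3, n_reps = 5,
                     seed = 6)
  expect_length(r3$pairs, 3)
  expect_lte(r3$best$summed_auc, 3)

  expect_error(search_pbdhs(blocks, rep("a", length(blocks)),
                            n_reps = 2, seed = 1), "2 labeled groups")
  expect_error(search_pbdhs(blocks[1:3], c("a", "a", "b"),
                            n_reps = 2, seed = 1), ">= 2 subjects")
})
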