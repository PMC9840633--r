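# Block dendrogram analysis. The event series is cut into consecutive
# blocks of block_windows windows (m = n_channels x block_windows events
# each), each block is Ward-clustered and 2-adically coded, and every block
# dendrogram is summarized by two sub-threshold branch counts:
#   E  - branches with Vi below the intra-block threshold 2^(block max ball - z1)
#   E1 - branches with Vi below the series-wide threshold 2^(global max ball - z2)
# Histograms F/F1 of the E/E1 values over bins 1..m feed the PBDHS statistic
# max((F(p)+1)(F1(p1)+1)) / mean((F(p)+1)(F1(p1)+1)) over h randomly chosen
# bin centres p, p1.

#' Decompose an event series into coded block dendrograms
#'
#' @param events A `dh_events` (row order: all electrodes of window 1, then
#'   window 2, ...; see [segment_events()]).
#' @param block_windows Windows per block (typically 1, 3, 5 or 10; any
#'   >= 1 accepted). A trailing partial block is dropped (floor division).
#' @return List of `dh_coded`, one per block, with attributes
#'   `block_windows` and `m` (leaves per block).
#' @export
block_series <- function(events, block_windows = 1L) {
  stopifnot(inherits(events, "dh_events"))
  if (block_windows < 1 || block_windows != round(block_windows))
    stop("block_windows must be a positive integer")
  block_windows <- as.integer(block_windows)
  n_blocks <- events$n_windows %/% block_windows
  if (n_blocks < 1)
    stop("fewer windows (", events$n_windows, ") than one block (",
         block_windows, ")")
  m <- events$n_channels * block_windows
  blocks <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    rows <- ((b - 1L) * m + 1L):(b * m)
    blocks[[b]] <- assign_codes(build_tree(events$events[rows, , drop = FALSE]))
  }
  attr(blocks, "block_windows") <- block_windows
  attr(blocks, "m") <- m
  blocks
}

#' Dual-threshold sub-branch counts over a block series
#'
#' Per block, `E` counts branches below the block's own intra-system
#' threshold `2^(block max_ball - z1)`; `E1` counts branches below the
#' inter-system threshold `2^(global max_ball - z2)` anchored at the maximal
#' ball over all blocks of the series. Strict inequality; exact ball
#' arithmetic.
#'
#' @param blocks List of `dh_coded` from [block_series()].
#' @param z1,z2 Natural numbers (intra- and inter-system exponents).
#' @return A `dh_blockseries`: `m`, `n_blocks`, `block_windows`,
#'   `max_ball` (per block), `global_max_ball`, `E`, `E1`, `z1`, `z2`.
#' @export
dual_threshold_counts <- function(blocks, z1, z2) {
  if (length(blocks) < 1) stop("empty block series")
  for (zz in c(z1, z2))
    if (!is.numeric(zz) || zz < 1 || zz != round(zz))
      stop("z1 and z2 must be natural numbers >= 1")
  mb <- vapply(blocks, function(b) b$max_ball, 0)
  gmb <- max(mb)
  E <- vapply(seq_along(blocks), function(i)
    sum(blocks[[i]]$ball < mb[i] - z1), 0)
  E1 <- vapply(seq_along(blocks), function(i)
    sum(blocks[[i]]$ball < gmb - z2), 0)
  m <- blocks[[1]]$n_leaves
  structure(list(m = m, n_blocks = length(blocks),
                 block_windows = attr(blocks, "block_windows"),
                 max_ball = mb, global_max_ball = gmb,
                 E = as.integer(E), E1 = as.integer(E1),
                 z1 = as.integer(z1), z2 = as.integer(z2)),
            class = "dh_blockseries")
}

#' Histograms of E and E1 over bins 1..m
#'
#' `F[b]` is the number of blocks whose `E` equals bin centre `b`
#' (`b = 1..m`); likewise `F1` for `E1`. Blocks with a zero count fall in no
#' bin (bins start at 1); their number is reported for conservation checks.
#'
#' @param result A `dh_blockseries` from [dual_threshold_counts()].
#' @return A `dh_pbdhs_hist`: `F`, `F1` (length-m integer vectors), `m`,
#'   `n_blocks`, `n_zero_E`, `n_zero_E1`.
#' @export
histograms <- function(result) {
  stopifnot(inherits(result, "dh_blockseries"))
  structure(list(F = tabulate(result$E, nbins = result$m),
                 F1 = tabulate(result$E1, nbins = result$m),
                 m = result$m, n_blocks = result$n_blocks,
                 n_zero_E = sum(result$E == 0),
                 n_zero_E1 = sum(result$E1 == 0)),
            class = "dh_pbdhs_hist")
}

#' The PBDHS statistic from histograms and selected bin centres
#'
#' Over the `h` selected bins, forms the elementwise products
#' `(F(p)+1) * (F1(p1)+1)` and returns their max divided by their mean
#' (always >= 1; equal to 1 when all products agree).
#'
#' @param F,F1 Histogram vectors over bins 1..m, or a `dh_pbdhs_hist` as `F`
#'   (then `F1` may be omitted).
#' @param p,p1 Bin-centre index vectors of equal length `h`, values in 1..m.
#' @return The PBDHS (a number >= 1).
#' @export
compute_pbdhs <- function(F, F1 = NULL, p, p1) {
  if (inherits(F, "dh_pbdhs_hist")) { F1 <- F$F1; F <- F$F }
  m <- length(F)
  if (length(F1) != m) stop("F and F1 must have equal length")
  if (length(p) == 0 || length(p1) == 0) stop("empty bin selection")
  if (length(p) != length(p1)) stop("p and p1 must have equal length h")
  if (any(p < 1 | p > m) || any(p1 < 1 | p1 > m))
    stop("bin centres must lie in 1..m = 1..", m)
  prod <- (F[p] + 1) * (F1[p1] + 1)
  max(prod) / mean(prod)
}

#' PBDHS sampling configuration
#' @param z1,z2 Natural numbers (threshold exponents).
#' @param h Number of sampled bin centres.
#' @param p,p1 Bin-centre vectors of length `h`.
#' @param seed Integer seed that produced the draw.
#' @return A validated `dh_pbdhs_config`.
#' @export
pbdhs_config <- function(z1, z2, h, p, p1, seed = NA_integer_) {
  if (h < 1) stop("h must be >= 1")
  if (length(p) != h || length(p1) != h) stop("p and p1 must have length h")
  structure(list(z1 = as.integer(z1), z2 = as.integer(z2), h = as.integer(h),
                 p = as.integer(p), p1 = as.integer(p1),
                 seed = as.integer(seed)),
            class = "dh_pbdhs_config")
}

# per-subject histogram matrices for one (z1, z2); subjects x m
subject_histograms <- function(summaries, z1, z2) {
  ns <- length(summaries)
  m <- summaries[[1]]$m
  Fm <- matrix(0L, ns, m); F1m <- matrix(0L, ns, m)
  for (s in seq_len(ns)) {
    sm <- summaries[[s]]
    E <- vapply(seq_along(sm$balls), function(i)
      sum(sm$balls[[i]] < sm$max_ball[i] - z1), 0)
    E1 <- vapply(seq_along(sm$balls), function(i)
      sum(sm$balls[[i]] < sm$global_max_ball - z2), 0)
    Fm[s, ] <- tabulate(E, nbins = m)
    F1m[s, ] <- tabulate(E1, nbins = m)
  }
  list(F = Fm, F1 = F1m)
}

# lightweight per-subject summary retaining only what the search needs
summarize_blocks <- function(blocks) {
  balls <- lapply(blocks, function(b) b$ball)
  mb <- vapply(blocks, function(b) b$max_ball, 0)
  list(balls = balls, max_ball = mb, global_max_ball = max(mb),
       m = blocks[[1]]$n_leaves)
}

#' Randomized AUC-maximizing PBDHS parameter search
#'
#' For every `(z1, z2)` combination and every repetition, draws one pair of
#' bin-centre vectors `(p, p1)` (uniform, without replacement from 1..m) and
#' applies the same draw to every subject, so PBDHS values are comparable
#' across subjects; computes all pairwise-group ROC AUCs of the per-subject
#' PBDHS values and their sum; returns the configuration maximizing the
#' summed AUC. Fully reproducible given `seed`.
#'
#' @param block_results List, one element per subject, each a list of
#'   `dh_coded` from [block_series()] (equal `m` across subjects).
#' @param labels Group label per subject (>= 2 groups, each >= 2 subjects).
#' @param z1_range,z2_range Integer vectors of exponents (default 1:8,
#'   giving the 64 standard combinations).
#' @param h Number of sampled bin centres per draw (default 10).
#' @param n_reps Draws per (z1, z2) combination (default 10000; raise
#'   toward 1e6 for exhaustive searches).
#' @param seed Integer seed.
#' @return A list: `best` (`dh_pbdhs_config` plus `summed_auc`),
#'   `per_subject` (data frame `subject`, `label`, `pbdhs` at the best
#'   configuration), `auc_grid` (best summed AUC per (z1, z2)), `pairs`
#'   (the group pairs entering the sum).
#' @export
search_pbdhs <- function(block_results, labels, z1_range = 1:8,
                         z2_range = 1:8, h = 10, n_reps = 10000, seed = 1L) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  labels <- as.character(labels)
  if (length(block_results) != length(labels))
    stop("one label per subject required")
  groups <- unique(labels)
  if (length(groups) < 2) stop("need at least 2 labeled groups")
  if (any(table(labels) < 2))
    stop("every group needs >= 2 subjects for a defined AUC")
  summaries <- lapply(block_results, summarize_blocks)
  m <- summaries[[1]]$m
  if (any(vapply(summaries, function(s) s$m, 0) != m))
    stop("all subjects must share the same block size m")
  if (h < 1 || h > m) stop("h must be in 1..m")
  pair_idx <- utils::combn(groups, 2, simplify = FALSE)
  grp_of <- lapply(pair_idx, function(pr)
    list(a = which(labels == pr[1]), b = which(labels == pr[2])))

  best <- list(auc = -Inf)
  grid <- expand.grid(z1 = z1_range, z2 = z2_range)
  grid$best_auc_sum <- NA_real_
  with_seed(seed, {
    for (g in seq_len(nrow(grid))) {
      z1 <- grid$z1[g]; z2 <- grid$z2[g]
      hm <- subject_histograms(summaries, z1, z2)
      Fp1 <- hm$F + 1L; F1p1 <- hm$F1 + 1L
      combo_best <- -Inf
      for (r in seq_len(n_reps)) {
        p <- sample.int(m, h); p1 <- sample.int(m, h)
        P <- Fp1[, p, drop = FALSE] * F1p1[, p1, drop = FALSE]
        mx <- P[, 1]
        if (h > 1) for (j in 2:h) mx <- pmax(mx, P[, j])
        pbdhs <- mx / rowMeans(P)
        auc_sum <- 0
        for (pr in grp_of)
          auc_sum <- auc_sum + auc_rank(pbdhs[pr$a], pbdhs[pr$b])
        if (auc_sum > combo_best) combo_best <- auc_sum
        if (auc_sum > best$auc) {
          best <- list(auc = auc_sum, z1 = z1, z2 = z2, p = p, p1 = p1,
                       pbdhs = pbdhs)
        }
      }
      grid$best_auc_sum[g] <- combo_best
    }
  })
  cfg <- pbdhs_config(best$z1, best$z2, h, best$p, best$p1, seed)
  cfg$summed_auc <- best$auc
  list(best = cfg,
       per_subject = data.frame(subject = seq_along(labels), label = labels,
                                pbdhs = best$pbdhs),
       auc_grid = grid,
       pairs = pair_idx)
}
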