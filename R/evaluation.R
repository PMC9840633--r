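# Mann-Whitney AUC of y (positive) vs x (negative); ties count half
auc_rank <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  (sum(r[(nx + 1):(nx + ny)]) - ny * (ny + 1) / 2) / (nx * ny)
}

#' ROC curve and AUC for a binary grouping
#'
#' AUC via the Mann-Whitney identity (ties counted one half). The raw
#' orientation is reported (AUC >= 0.5 is not forced); `auc_flipped` is a
#' convenience field. A two-sided p-value from the large-sample
#' normal approximation of the Mann-Whitney statistic (with tie correction)
#' is attached.
#'
#' @param scores Numeric scores, one per subject.
#' @param labels Binary labels (logical, 0/1, or a two-level factor whose
#'   second level is positive).
#' @return A `dh_roc`: `auc`, `auc_flipped`, `n_pos`, `n_neg`, `p_value`,
#'   and `curve` (data frame of `fpf`, `tpf` from (0,0) to (1,1)).
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels)) {
    if (nlevels(labels) != 2) stop("factor labels must have exactly 2 levels")
    labels <- labels == levels(labels)[2]
  }
  labels <- as.logical(labels)
  if (any(is.na(labels)) || any(!is.finite(scores)))
    stop("scores and labels must be finite and binary")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present (got ", n_pos, " positive, ",
         n_neg, " negative)")
  auc <- auc_rank(scores[!labels], scores[labels])

  # curve: sweep threshold over unique scores in decreasing order
  thr <- sort(unique(scores), decreasing = TRUE)
  tpf <- vapply(thr, function(t) sum(scores[labels] >= t) / n_pos, 0)
  fpf <- vapply(thr, function(t) sum(scores[!labels] >= t) / n_neg, 0)
  curve <- data.frame(fpf = c(0, fpf, 1), tpf = c(0, tpf, 1))

  # normal approximation with tie correction
  N <- n_pos + n_neg
  ties <- table(scores)
  sig2 <- n_pos * n_neg / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  U <- auc * n_pos * n_neg
  p <- if (sig2 <= 0) 1 else 2 * stats::pnorm(-abs((U - n_pos * n_neg / 2) / sqrt(sig2)))
  structure(list(auc = auc, auc_flipped = max(auc, 1 - auc),
                 n_pos = n_pos, n_neg = n_neg, p_value = p, curve = curve),
            class = "dh_roc")
}

#' @export
print.dh_roc <- function(x, ...) {
  cat(sprintf("<dh_roc> AUC = %.4f (flipped %.4f), n+ = %d, n- = %d, p = %.3g\n",
              x$auc, x$auc_flipped, x$n_pos, x$n_neg, x$p_value))
  invisible(x)
}

#' Random-grouping null control
#'
#' Repeatedly partitions the pooled values at random into groups of the
#' given sizes and computes every pairwise AUC; since random grouping
#' destroys label information, the mean AUC calibrates to 0.5. Reports raw
#' SD (multiply by 3 for the plotting convention).
#'
#' @param values Pooled numeric values (length must equal `sum(group_sizes)`).
#' @param group_sizes Integer group sizes (>= 2 groups).
#' @param n_iter Number of random partitions (default 10000).
#' @param seed Integer seed.
#' @return Data frame, one row per unordered group pair: `size_a`, `size_b`,
#'   `mean_auc`, `sd_auc`, `n_iter`.
#' @export
random_grouping_null <- function(values, group_sizes, n_iter = 10000,
                                 seed = 1L) {
  if (length(group_sizes) < 2) stop("need at least 2 group sizes")
  if (sum(group_sizes) != length(values))
    stop("sum(group_sizes) = ", sum(group_sizes), " must equal length(values) = ",
         length(values))
  k <- length(group_sizes)
  bounds <- cumsum(c(0, group_sizes))
  pairs <- utils::combn(k, 2, simplify = FALSE)
  acc <- matrix(0, n_iter, length(pairs))
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      perm <- sample(values)
      grp <- lapply(seq_len(k), function(g) perm[(bounds[g] + 1):bounds[g + 1]])
      for (j in seq_along(pairs))
        acc[it, j] <- auc_rank(grp[[pairs[[j]][1]]], grp[[pairs[[j]][2]]])
    }
  })
  data.frame(size_a = vapply(pairs, function(p) group_sizes[p[1]], 0),
             size_b = vapply(pairs, function(p) group_sizes[p[2]], 0),
             mean_auc = colMeans(acc),
             sd_auc = apply(acc, 2, stats::sd),
             n_iter = n_iter)
}

#' Welch power spectral density estimate
#'
#' Hann-windowed segments with overlap, one-sided density in
#' (input units)^2 per Hz.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param seg_s Segment length in seconds (default 2; shortened when the
#'   signal is shorter).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return List with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, seg_s = 2, overlap = 0.5) {
  L <- min(length(x), as.integer(round(seg_s * fs)))
  if (L < 4) stop("signal too short for a spectral estimate")
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  nf <- L %/% 2 + 1L
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + L - 1L)] * w
    sp <- abs(stats::fft(seg))^2
    acc <- acc + sp[1:nf]
  }
  psd <- acc / (length(starts) * fs * sum(w^2))
  # one-sided: double all bins except DC and (for even L) Nyquist
  dbl <- rep(2, nf); dbl[1] <- 1
  if (L %% 2 == 0) dbl[nf] <- 1
  list(freq = (0:(nf - 1)) * fs / L, psd = psd * dbl)
}

#' Mean band power per channel
#'
#' Welch-estimated power integrated over the five canonical EEG bands for
#' every channel of a recording. Bands reaching above the Nyquist frequency
#' are truncated with a warning.
#'
#' @param rec A [recording()] (normally already [preprocess()]ed).
#' @param bands Named list of `c(low, high)` Hz pairs (default [eeg_bands()]).
#' @param seg_s,overlap Welch parameters (2-s Hann segments, 50% overlap).
#' @return Data frame: `subject`, `channel`, `band`, `low_hz`, `high_hz`,
#'   `power` (integrated, microvolt^2).
#' @export
band_power <- function(rec, bands = eeg_bands(), seg_s = 2, overlap = 0.5) {
  stopifnot(inherits(rec, "dh_recording"))
  nyq <- rec$fs / 2
  rows <- list()
  for (ch in seq_len(nrow(rec$data))) {
    est <- welch_psd(rec$data[ch, ], rec$fs, seg_s, overlap)
    df <- est$freq[2] - est$freq[1]
    for (b in seq_along(bands)) {
      lo <- bands[[b]][1]; hi <- bands[[b]][2]
      if (hi > nyq) {
        if (ch == 1) warning("band ", names(bands)[b], " truncated at the ",
                             "Nyquist frequency (", nyq, " Hz)")
        hi <- nyq
      }
      sel <- est$freq >= lo & est$freq < hi
      rows[[length(rows) + 1L]] <- data.frame(
        subject = rec$subject_id, channel = rec$channel_labels[ch],
        band = names(bands)[b], low_hz = lo, high_hz = hi,
        power = sum(est$psd[sel]) * df, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
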