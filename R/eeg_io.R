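#' Multichannel recording container
#'
#' @param data Numeric matrix, channels x samples, amplitudes in microvolts.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Optional character vector, one per channel.
#' @param subject_id Subject identifier string.
#' @return A `dh_recording`.
#' @export
recording <- function(data, fs, channel_labels = NULL, subject_id = "") {
  data <- as.matrix(data)
  if (nrow(data) < 2) stop("recording must have at least 2 channels")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be > 0")
  if (ncol(data) <= fs) stop("recording must hold more than 1 s of data (",
                             ncol(data), " samples at fs=", fs, ")")
  if (any(!is.finite(data))) stop("recording contains non-finite samples")
  if (is.null(channel_labels)) channel_labels <- paste0("Ch", seq_len(nrow(data)))
  if (length(channel_labels) != nrow(data))
    stop("channel_labels length must match channel count")
  structure(list(data = data, fs = fs,
                 channel_labels = as.character(channel_labels),
                 subject_id = as.character(subject_id)),
            class = "dh_recording")
}

#' @export
print.dh_recording <- function(x, ...) {
  cat(sprintf("<dh_recording> %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

#' Write a recording as a channels-by-samples CSV
#' @param rec A [recording()].
#' @param path Output path. Rows are channels; the first column holds labels.
#' @return Invisibly, `path`.
#' @export
write_recording_csv <- function(rec, path) {
  df <- data.frame(channel = rec$channel_labels, rec$data, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a recording from EDF or CSV
#'
#' CSV files are channels-by-samples; a non-numeric first column is taken as
#' channel labels and a non-numeric first line as a header. EDF sampling rate
#' comes from the file; CSV needs `fs`.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"edf"` or `"csv"`.
#' @param fs Sampling rate for CSV input (ignored for EDF).
#' @param subject_id Optional subject id; defaults to the file stem.
#' @return A [recording()].
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv"), fs = 500,
                           subject_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read recording: file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (is.null(subject_id))
    subject_id <- tools::file_path_sans_ext(basename(path))
  if (format == "edf") {
    rec <- read_edf(path, subject_id = subject_id)
  } else {
    first <- readLines(path, n = 1)
    has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, ",")[[1]][2])))
    df <- utils::read.csv(path, header = has_header, check.names = FALSE)
    labels <- NULL
    if (!is.numeric(df[[1]])) { labels <- as.character(df[[1]]); df[[1]] <- NULL }
    rec <- recording(as.matrix(df), fs = fs, channel_labels = labels,
                     subject_id = subject_id)
  }
  rec
}

# symmetric (zero-phase) frequency response applied by Fourier multiplication;
# hp: Butterworth-magnitude high-pass, notch: Gaussian dip centred on the
# mains frequency
fft_filter <- function(x, fs, hp_hz, notch_hz, hp_order, notch_q) {
  n <- length(x)
  f <- seq(0, fs - fs / n, length.out = n)
  f_fold <- pmin(f, fs - f)
  H <- rep(1, n)
  if (!is.null(hp_hz) && hp_hz > 0) {
    Hhp <- ifelse(f_fold == 0, 0,
                  1 / sqrt(1 + (hp_hz / pmax(f_fold, 1e-12))^(2 * hp_order)))
    H <- H * Hhp
  }
  if (!is.null(notch_hz) && notch_hz > 0) {
    sigma <- (notch_hz / notch_q) / 2
    H <- H * (1 - exp(-0.5 * ((f_fold - notch_hz) / sigma)^2))
  }
  Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / n
}

#' Preprocess a recording (zero-phase high-pass and mains notch)
#'
#' Applies, per channel, a zero-phase 1 Hz high-pass and a 50 Hz notch by
#' symmetric frequency-domain multiplication (no phase distortion by
#' construction). Either filter can be disabled with `NULL`.
#'
#' @param rec A [recording()].
#' @param hp_hz High-pass cutoff in Hz (default 1); `NULL` disables.
#' @param notch_hz Notch centre in Hz (default 50); `NULL` disables.
#' @param hp_order Butterworth magnitude order of the high-pass (default 4).
#' @param notch_q Notch quality factor; bandwidth is `notch_hz / notch_q`
#'   (default 30).
#' @return A [recording()] of identical shape.
#' @export
preprocess <- function(rec, hp_hz = 1, notch_hz = 50, hp_order = 4,
                       notch_q = 30) {
  stopifnot(inherits(rec, "dh_recording"))
  if (!is.null(notch_hz) && rec$fs <= 2 * notch_hz)
    stop("fs = ", rec$fs, " Hz is too low for a ", notch_hz, " Hz notch ",
         "(need fs > ", 2 * notch_hz, ")")
  out <- rec
  for (ch in seq_len(nrow(rec$data)))
    out$data[ch, ] <- fft_filter(rec$data[ch, ], rec$fs, hp_hz, notch_hz,
                                 hp_order, notch_q)
  out
}

#' Resample a recording (Fourier method)
#'
#' @param rec A [recording()].
#' @param fs_out Target sampling rate in Hz.
#' @return A [recording()] at `fs_out`.
#' @export
resample_recording <- function(rec, fs_out) {
  stopifnot(inherits(rec, "dh_recording"))
  if (fs_out == rec$fs) return(rec)
  n <- ncol(rec$data)
  n_out <- as.integer(round(n * fs_out / rec$fs))
  out <- matrix(0, nrow(rec$data), n_out)
  for (ch in seq_len(nrow(rec$data))) {
    X <- stats::fft(rec$data[ch, ])
    Y <- complex(real = numeric(n_out), imaginary = numeric(n_out))
    keep <- min(n, n_out) %/% 2
    Y[1:(keep + 1)] <- X[1:(keep + 1)]
    if (keep > 0) Y[(n_out - keep + 1):n_out] <- X[(n - keep + 1):n]
    out[ch, ] <- Re(stats::fft(Y, inverse = TRUE)) / n
  }
  recording(out, fs = fs_out, channel_labels = rec$channel_labels,
            subject_id = rec$subject_id)
}

#' Segment a recording into one-second event vectors
#'
#' Cuts each channel into consecutive non-overlapping windows of `window_s`
#' seconds starting at `offset_s`; each (electrode, window) pair becomes one
#' event row. Row order is electrode-major within each window and
#' window-major overall: rows are (window 1: all electrodes), (window 2: all
#' electrodes), ... This frozen convention makes the block decomposition used
#' by [block_series()] a contiguous row slice.
#'
#' @param rec A [recording()].
#' @param window_s Window length in seconds (default 1).
#' @param total_s Total analyzed span in seconds; default uses the longest
#'   whole multiple of `window_s` available after `offset_s`.
#' @param offset_s Start offset in seconds (default 0).
#' @return A `dh_events` with fields `events` (n_events x window_len),
#'   `index` (data frame of 1-based electrode/window), `fs`, `window_s`,
#'   `n_channels`, `n_windows`.
#' @export
segment_events <- function(rec, window_s = 1, total_s = NULL, offset_s = 0) {
  stopifnot(inherits(rec, "dh_recording"))
  fs <- rec$fs
  L <- window_s * fs
  if (abs(L - round(L)) > 1e-9) stop("window_s * fs must be an integer")
  L <- as.integer(round(L))
  avail_s <- ncol(rec$data) / fs
  if (is.null(total_s))
    total_s <- floor((avail_s - offset_s) / window_s) * window_s
  n_windows <- total_s / window_s
  if (abs(n_windows - round(n_windows)) > 1e-9)
    stop("total_s must be a whole number of windows")
  n_windows <- as.integer(round(n_windows))
  if (n_windows < 1) stop("no complete window available")
  need <- offset_s + total_s
  if (need > avail_s + 1e-9)
    stop("recording too short: need ", need, " s (offset ", offset_s,
         " + total ", total_s, ") but only ", avail_s, " s available")
  nch <- nrow(rec$data)
  off <- as.integer(round(offset_s * fs))
  events <- matrix(0, nch * n_windows, L)
  for (w in seq_len(n_windows)) {
    cols <- (off + (w - 1L) * L + 1L):(off + w * L)
    events[(w - 1L) * nch + seq_len(nch), ] <- rec$data[, cols]
  }
  index <- data.frame(
    electrode = rep(seq_len(nch), times = n_windows),
    window = rep(seq_len(n_windows), each = nch))
  structure(list(events = events, index = index, fs = fs, window_s = window_s,
                 n_channels = nch, n_windows = n_windows,
                 channel_labels = rec$channel_labels,
                 subject_id = rec$subject_id),
            class = "dh_events")
}

#' @export
print.dh_events <- function(x, ...) {
  cat(sprintf("<dh_events> %d events (%d channels x %d windows) of length %d @ %g Hz\n",
              nrow(x$events), x$n_channels, x$n_windows, ncol(x$events), x$fs))
  invisible(x)
}
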