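# Minimal European Data Format (EDF) support: 16-bit integer samples,
# one-second data records, ASCII headers. Covers what the pipeline needs
# (multichannel scalp EEG in physical microvolts); no pre-installed R or
# Python package in this stack reads EDF, so the format is implemented here.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)  # left-justified, space-padded
}

edf_num <- function(x, width) edf_pad(format(x, trim = TRUE, scientific = FALSE, digits = 8), width)

#' Write a recording as EDF
#'
#' 16-bit EDF with one-second data records and per-channel symmetric physical
#' ranges in microvolts. The recording must contain a whole number of seconds
#' and `fs` must be an integer.
#'
#' @param rec A [recording()].
#' @param path Output file path.
#' @param annotation_channel If `TRUE`, append a dummy "EDF Annotations"
#'   signal (as EDF+ files carry); used to exercise reader label filtering.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(rec, path, annotation_channel = FALSE) {
  stopifnot(inherits(rec, "dh_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires integer fs")
  fs <- as.integer(round(fs))
  n <- ncol(rec$data)
  if (n %% fs != 0) stop("EDF writer requires a whole number of seconds (",
                         n, " samples at fs=", fs, ")")
  n_rec <- n %/% fs
  nch <- nrow(rec$data)
  ns <- nch + if (annotation_channel) 1L else 0L

  pmaxs <- apply(abs(rec$data), 1, max)
  pmaxs[pmaxs == 0] <- 1
  dig <- matrix(0L, nch, n)
  for (ch in seq_len(nch))
    dig[ch, ] <- as.integer(round(rec$data[ch, ] / pmaxs[ch] * 32767))

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL)
  wr(edf_pad("0", 8))
  wr(edf_pad(rec$subject_id, 80))
  wr(edf_pad("dhsig synthetic recording", 80))
  wr(edf_pad("01.01.00", 8)); wr(edf_pad("00.00.00", 8))
  wr(edf_num(256L * (1L + ns), 8))
  wr(edf_pad("", 44))
  wr(edf_num(n_rec, 8))
  wr(edf_num(1L, 8))
  wr(edf_num(ns, 4))

  labels <- rec$channel_labels
  if (annotation_channel) labels <- c(labels, "EDF Annotations")
  for (l in labels) wr(edf_pad(l, 16))
  for (i in seq_len(ns)) wr(edf_pad("", 80))                    # transducer
  for (i in seq_len(ns)) wr(edf_pad(if (i <= nch) "uV" else "", 8))
  for (i in seq_len(ns)) wr(edf_num(if (i <= nch) -pmaxs[i] else -1, 8))
  for (i in seq_len(ns)) wr(edf_num(if (i <= nch) pmaxs[i] else 1, 8))
  for (i in seq_len(ns)) wr(edf_num(-32767L, 8))
  for (i in seq_len(ns)) wr(edf_num(32767L, 8))
  for (i in seq_len(ns)) wr(edf_pad("", 80))                    # prefiltering
  for (i in seq_len(ns)) wr(edf_num(if (i <= nch) fs else 10L, 8))
  for (i in seq_len(ns)) wr(edf_pad("", 32))

  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(nch))
      writeBin(dig[ch, idx], con, size = 2, endian = "little")
    if (annotation_channel)
      writeBin(integer(10), con, size = 2, endian = "little")
  }
  invisible(path)
}

# labels treated as non-EEG bookkeeping signals and dropped on read
edf_label_blacklist <- function(labels) {
  grepl("annotation|status|marker|event", tolower(trimws(labels)))
}

#' Read an EDF file
#'
#' Parses the ASCII header, drops annotation/status signals by label
#' blacklist, rescales digital values to physical units, and requires all
#' remaining signals to share one sampling rate.
#'
#' @param path EDF file path.
#' @param subject_id Optional subject id; defaults to the header patient field.
#' @return A [recording()].
#' @export
read_edf <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("cannot read EDF: file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  patient <- rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes (recomputed from ns)
  rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (is.na(ns) || ns < 1 || is.na(n_rec) || n_rec < 1)
    stop("not a parseable EDF header: ", path)
  rdv <- function(width, ns) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdv(16, ns); rdv(80, ns)
  rdv(8, ns)  # physical dimension
  pmin_ <- as.numeric(rdv(8, ns)); pmax_ <- as.numeric(rdv(8, ns))
  dmin_ <- as.numeric(rdv(8, ns)); dmax_ <- as.numeric(rdv(8, ns))
  rdv(80, ns)
  spr <- as.integer(rdv(8, ns)); rdv(32, ns)

  keep <- !edf_label_blacklist(labels)
  if (!any(keep)) stop("EDF has no EEG channels after label filtering: ", path)
  fs_all <- spr[keep] / rec_dur
  if (length(unique(fs_all)) != 1)
    stop("EDF channels have mixed sampling rates; not supported")
  fs <- fs_all[1]

  data <- matrix(0, sum(keep), n_rec * spr[which(keep)[1]])
  row_of <- cumsum(keep)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      vals <- readBin(con, integer(), n = spr[i], size = 2, endian = "little")
      if (!keep[i]) next
      phys <- (vals - dmin_[i]) * (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i]) + pmin_[i]
      data[row_of[i], ((r - 1) * spr[i] + 1):(r * spr[i])] <- phys
    }
  }
  recording(data, fs = fs, channel_labels = labels[keep],
            subject_id = if (is.null(subject_id)) patient else subject_id)
}
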