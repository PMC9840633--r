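#' Canonical EEG frequency bands
#'
#' Band edges (Hz) used throughout the package: delta 0.5-4, theta 4-8,
#' alpha 8-12, beta 12-30, gamma 30-100.
#' @return Named list of `c(low, high)` pairs in Hz.
#' @export
eeg_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12),
       beta = c(12, 30), gamma = c(30, 100))
}

# 10-20 labels for the standard 19-electrode montage
ten_twenty_labels <- function(n_channels) {
  std <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
           "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
  if (n_channels == length(std)) std else paste0("Ch", seq_len(n_channels))
}

#' Configuration for the synthetic EEG generator
#'
#' Describes one synthetic recording: channel count, sampling rate, duration,
#' the relative power of the five canonical bands, the inter-channel coupling
#' (the fraction of band-limited signal shared across channels, which equals
#' the expected pairwise correlation of the oscillatory part), a slow
#' nonstationary drift amplitude, and additive white sensor noise.
#'
#' @param n_channels Number of channels (default 19, the 10-20 montage).
#' @param fs Sampling rate in Hz (default 500).
#' @param duration Recording length in seconds (default 500); `duration * fs`
#'   must be a whole number of samples.
#' @param group_label Cohort label attached to recordings made from this
#'   configuration.
#' @param coupling Fraction in \[0, 1\] of each band-limited oscillation that
#'   is shared across channels.
#' @param nonstationarity Amplitude of a slow (< 0.1 Hz) drift, as a fraction
#'   of the oscillatory signal SD.
#' @param band_weights Nonnegative relative amplitudes of the five canonical
#'   bands, in the order of [eeg_bands()].
#' @param noise_sd White-noise SD in microvolts.
#' @param amplitude_sd Target SD of the summed oscillatory signal in
#'   microvolts (default 50, a typical resting scalp EEG scale).
#' @param seed Integer seed; the generator is bit-reproducible given the seed.
#' @return A validated `dh_synth_config` list.
#' @export
synth_config <- function(n_channels = 19L, fs = 500, duration = 500,
                         group_label = "control", coupling = 0.5,
                         nonstationarity = 0.1,
                         band_weights = c(delta = 1, theta = 0.8, alpha = 1.2,
                                          beta = 0.6, gamma = 0.3),
                         noise_sd = 2, amplitude_sd = 50, seed = 1L) {
  cfg <- list(n_channels = as.integer(n_channels), fs = fs, duration = duration,
              group_label = as.character(group_label), coupling = coupling,
              nonstationarity = nonstationarity,
              band_weights = as.numeric(band_weights), noise_sd = noise_sd,
              amplitude_sd = amplitude_sd, seed = as.integer(seed))
  class(cfg) <- "dh_synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  bad <- function(field, why) stop("invalid synth config: field '", field,
                                   "' ", why, call. = FALSE)
  if (!is.numeric(cfg$n_channels) || cfg$n_channels < 2) bad("n_channels", "must be >= 2")
  if (!is.numeric(cfg$fs) || cfg$fs <= 0) bad("fs", "must be > 0")
  if (!is.numeric(cfg$duration) || cfg$duration <= 0) bad("duration", "must be > 0")
  n <- cfg$duration * cfg$fs
  if (abs(n - round(n)) > 1e-8) bad("duration", "times fs must be an integer number of samples")
  if (!is.numeric(cfg$coupling) || cfg$coupling < 0 || cfg$coupling > 1) bad("coupling", "must be in [0, 1]")
  if (!is.numeric(cfg$nonstationarity) || cfg$nonstationarity < 0) bad("nonstationarity", "must be >= 0")
  if (length(cfg$band_weights) != length(eeg_bands())) bad("band_weights", "must have one weight per canonical band")
  if (any(cfg$band_weights < 0) || all(cfg$band_weights == 0)) bad("band_weights", "must be >= 0 with at least one positive")
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd < 0) bad("noise_sd", "must be >= 0")
  if (!is.numeric(cfg$seed) || is.na(cfg$seed)) bad("seed", "must be an integer")
  invisible(cfg)
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

# unit-SD noise band-limited to (f1, f2] Hz by Fourier masking; returns zeros
# if the band holds no resolvable frequency bin
band_noise <- function(n, f1, f2, fs) {
  w <- stats::rnorm(n)
  f <- seq(0, fs - fs / n, length.out = n)
  f_fold <- pmin(f, fs - f)
  keep <- f_fold > f1 & f_fold <= f2
  if (!any(keep)) {
    # fall back to the single lowest nonzero bin (very short recordings)
    keep <- f_fold > 0 & f_fold <= min(f_fold[f_fold > 0]) + 1e-12
    if (!any(keep)) return(numeric(n))
  }
  s <- stats::fft(w)
  s[!keep] <- 0
  x <- Re(stats::fft(s, inverse = TRUE)) / n
  sdx <- stats::sd(x)
  if (sdx > 0) x / sdx else x
}

#' Generate one synthetic EEG-like recording
#'
#' Each channel is a weighted sum of band-limited noise oscillations (one per
#' canonical band), composed of a component shared across channels (scaled by
#' `coupling`) and an independent component, plus a slow drift scaled by
#' `nonstationarity` and white sensor noise. Bit-identical output for a fixed
#' configuration.
#'
#' @param cfg A [synth_config()].
#' @return A [recording()] (`dh_recording`).
#' @examples
#' rec <- generate_recording(synth_config(duration = 2, seed = 1))
#' dim(rec$data)
#' @export
generate_recording <- function(cfg) {
  validate_synth_config(cfg)
  n <- as.integer(round(cfg$duration * cfg$fs))
  nch <- cfg$n_channels
  bands <- eeg_bands()
  with_seed(cfg$seed, {
    osc <- matrix(0, nch, n)
    for (b in seq_along(bands)) {
      wgt <- cfg$band_weights[b]
      if (wgt == 0) next
      lohi <- bands[[b]]
      shared <- band_noise(n, lohi[1], min(lohi[2], cfg$fs / 2), cfg$fs)
      for (ch in seq_len(nch)) {
        if (cfg$coupling >= 1) {
          comp <- shared
        } else {
          indep <- band_noise(n, lohi[1], min(lohi[2], cfg$fs / 2), cfg$fs)
          comp <- sqrt(cfg$coupling) * shared + sqrt(1 - cfg$coupling) * indep
        }
        osc[ch, ] <- osc[ch, ] + wgt * comp
      }
    }
    sc <- stats::sd(as.numeric(osc))
    if (sc > 0) osc <- osc * (cfg$amplitude_sd / sc)
    data <- osc
    if (cfg$nonstationarity > 0) {
      for (ch in seq_len(nch))
        data[ch, ] <- data[ch, ] + cfg$nonstationarity * cfg$amplitude_sd *
          band_noise(n, 0, 0.1, cfg$fs)
    }
    if (cfg$noise_sd > 0)
      data <- data + matrix(stats::rnorm(nch * n, sd = cfg$noise_sd), nch, n)
    recording(data, fs = cfg$fs,
              channel_labels = ten_twenty_labels(nch),
              subject_id = paste0(cfg$group_label, "_s", cfg$seed))
  })
}

# deterministic per-subject seed below 2^31, mixed from master seed and
# (group, subject) position
derive_seed <- function(master, group, subject) {
  s <- (as.double(master) %% 2147483647) * 48271 + group * 100003 + subject * 7919
  as.integer(s %% 2147483646 + 1)
}

#' Generate a labeled synthetic cohort
#'
#' @param group_cfgs List of groups, each a `list(cfg = <synth_config>,
#'   n = <n_subjects>)`. The group label is taken from `cfg$group_label`.
#' @param seed Master integer seed; per-subject seeds are derived
#'   deterministically from it and the (group, subject) position.
#' @return A `dh_cohort`: list of `list(recording, label, subject_id)`.
#' @export
generate_cohort <- function(group_cfgs, seed = 1L) {
  if (length(group_cfgs) == 0) stop("empty group list")
  out <- list()
  for (g in seq_along(group_cfgs)) {
    grp <- group_cfgs[[g]]
    if (is.null(grp$cfg) || is.null(grp$n) || grp$n < 1)
      stop("each group needs a cfg and n_subjects >= 1")
    validate_synth_config(grp$cfg)
    for (s in seq_len(grp$n)) {
      cfg <- grp$cfg
      cfg$seed <- derive_seed(seed, g, s)
      rec <- generate_recording(cfg)
      rec$subject_id <- sprintf("%s_%03d", cfg$group_label, s)
      out[[length(out) + 1L]] <- list(recording = rec,
                                      label = cfg$group_label,
                                      subject_id = rec$subject_id)
    }
  }
  class(out) <- "dh_cohort"
  out
}

#' Write a cohort to disk with a manifest
#'
#' Writes one file per recording (EDF or CSV) plus `manifest.csv` with
#' columns `path,label`.
#'
#' @param cohort A `dh_cohort` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @param format `"edf"` or `"csv"`.
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort <- function(cohort, dir, format = c("edf", "csv")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(subj) {
    fn <- file.path(dir, paste0(subj$subject_id, ".", format))
    if (format == "edf") write_edf(subj$recording, fn)
    else write_recording_csv(subj$recording, fn)
    data.frame(path = fn, label = subj$label, fs = subj$recording$fs,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
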