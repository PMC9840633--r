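#' Personal universal DH signature (PUDHS)
#'
#' Counts the branches of a coded dendrogram whose 2-adic value lies
#' strictly below the personal threshold `T = 2^(max_ball - z)`, where
#' `max_ball` is the tree's maximal 2-adic ball and `z` is a global natural
#' number shared by all subjects. Since `T` is a power of two, `Vi < T` is
#' exactly equivalent to `ball(Vi) < max_ball - z`, so the count is computed
#' in exact integer (ball) arithmetic at any tree depth. Topologically,
#' PUDHS is the number of sub-dendrograms the threshold line dissects.
#'
#' @param coded A `dh_coded` from [assign_codes()].
#' @param z Natural number (the free model parameter, typically 1-8).
#' @return A `dh_pudhs`: `z`, `max_ball`, `threshold_exponent`
#'   (`max_ball - z`, the exact representation of `T`), `threshold`
#'   (`2^exponent`, `Inf` if not representable), `pudhs`, `n_leaves`.
#' @export
compute_pudhs <- function(coded, z) {
  stopifnot(inherits(coded, "dh_coded"))
  if (!is.numeric(z) || length(z) != 1 || z < 1 || z != round(z))
    stop("z must be a natural number >= 1")
  if (coded$n_leaves < 2) stop("coded tree must have at least 2 leaves")
  e <- coded$max_ball - z
  if (z >= coded$max_ball + 1)
    warning("z = ", z, " >= max_ball + 1 = ", coded$max_ball + 1,
            ": threshold <= 1, only the all-zeros branch counts")
  structure(list(z = as.integer(z), max_ball = coded$max_ball,
                 threshold_exponent = e, threshold = 2^e,
                 pudhs = sum(coded$ball < e),
                 n_leaves = coded$n_leaves),
            class = "dh_pudhs")
}

#' @export
print.dh_pudhs <- function(x, ...) {
  cat(sprintf("<dh_pudhs> PUDHS = %d of %d leaves (max_ball %s, z = %d, T = 2^%s)\n",
              x$pudhs, x$n_leaves, format(x$max_ball), x$z,
              format(x$threshold_exponent)))
  invisible(x)
}

#' PUDHS for every subject of a cohort
#'
#' Runs preprocess -> segment -> Ward tree -> 2-adic coding -> PUDHS per
#' subject. Per-subject failures are recorded and skipped with a warning;
#' the run continues and the failure list is attached to the result.
#'
#' @param cohort A `dh_cohort` from [generate_cohort()], or any list of
#'   `list(recording = <dh_recording>, label = <chr>, subject_id = <chr>)`.
#' @param z Global natural number passed to [compute_pudhs()].
#' @param window_s,total_s,offset_s Passed to [segment_events()].
#' @param preprocess Logical; apply [preprocess()] first (default TRUE).
#' @param hp_hz,notch_hz Filter settings when preprocessing.
#' @param verbose Log per-subject progress via `message()`.
#' @return Data frame with one row per successful subject: `subject`,
#'   `label`, `n_leaves`, `max_ball`, `threshold_exponent`, `pudhs`.
#'   Attribute `"failures"` lists skipped subjects and their errors.
#' @export
pudhs_cohort <- function(cohort, z = 4, window_s = 1, total_s = NULL,
                         offset_s = 0, preprocess = TRUE, hp_hz = 1,
                         notch_hz = 50, verbose = FALSE) {
  rows <- list(); failures <- list()
  for (i in seq_along(cohort)) {
    subj <- cohort[[i]]
    sid <- if (!is.null(subj$subject_id)) subj$subject_id else paste0("subject_", i)
    res <- tryCatch({
      rec <- subj$recording
      if (preprocess) rec <- preprocess(rec, hp_hz = hp_hz, notch_hz = notch_hz)
      ev <- segment_events(rec, window_s = window_s, total_s = total_s,
                           offset_s = offset_s)
      coded <- assign_codes(build_tree(ev))
      p <- compute_pudhs(coded, z)
      if (verbose) message(sprintf("[pudhs] %s: %d leaves, PUDHS = %d",
                                   sid, p$n_leaves, p$pudhs))
      data.frame(subject = sid, label = subj$label, n_leaves = p$n_leaves,
                 max_ball = p$max_ball,
                 threshold_exponent = p$threshold_exponent, pudhs = p$pudhs,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("subject ", sid, " failed and was skipped: ",
              conditionMessage(e), call. = FALSE)
      failures[[length(failures) + 1L]] <<- list(subject = sid,
                                                 error = conditionMessage(e))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  if (length(rows) == 0) stop("every subject failed; no PUDHS computed")
  out <- do.call(rbind, rows)
  attr(out, "failures") <- failures
  out
}

#' PUDHS scan over a range of z
#'
#' @param coded A `dh_coded`.
#' @param z_range Integer vector of z values (default 1:8).
#' @return Data frame `z`, `threshold_exponent`, `pudhs`.
#' @export
pudhs_scan <- function(coded, z_range = 1:8) {
  do.call(rbind, lapply(z_range, function(z) {
    p <- suppressWarnings(compute_pudhs(coded, z))
    data.frame(z = z, threshold_exponent = p$threshold_exponent,
               pudhs = p$pudhs)
  }))
}
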