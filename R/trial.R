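#' Construct an sEMG trial recording
#'
#' A trial holds one multi-channel task recording from the paretic upper limb:
#' a samples-by-channels matrix in mV, the sampling rate, operator-marked
#' pause intervals, and the participant/session identity. Channels are a
#' subset of the four task muscles: extensor digitorum (ED), flexor digitorum
#' (FD), biceps brachii (BIC) and triceps brachii (TRI).
#'
#' Pause intervals are half-open `[start, end)` in seconds and must lie inside
#' the trial and be non-overlapping after sorting.
#'
#' @param signal Numeric matrix, samples by channels, in mV.
#' @param channels Character vector of muscle labels, one per signal column.
#' @param sampling_rate Sampling rate in Hz (default 1000).
#' @param participant_id,session,trial_index Identity of the recording;
#'   `session` is `"pre"` or `"post"`.
#' @param pauses List of `c(start_s, end_s)` pause intervals (may be empty).
#' @param task_label Free-text task description.
#' @return An object of class `semg_trial`.
#' @export
semg_trial <- function(signal, channels,
                       sampling_rate = 1000,
                       participant_id = "P01", session = c("pre", "post"),
                       trial_index = 1L, pauses = list(),
                       task_label = "reach") {
  session <- match.arg(session)
  signal <- as_signal_matrix(signal)
  if (nrow(signal) < 1) abort_semg("trial must contain at least one sample.", "format")
  if (length(channels) != ncol(signal))
    abort_semg("`channels` must name every signal column.", "format")
  if (anyDuplicated(channels))
    abort_semg("channel labels must be unique.", "format")
  if (trial_index < 1) abort_semg("`trial_index` must be >= 1.", "format")
  colnames(signal) <- channels
  duration <- nrow(signal) / sampling_rate
  pauses <- lapply(pauses, function(p) {
    p <- as.numeric(p)
    if (length(p) != 2 || p[1] >= p[2] || p[1] < 0 || p[2] > duration + 1e-9)
      abort_semg("each pause must be [start_s, end_s) inside the trial.", "format")
    p
  })
  if (length(pauses) > 1) {
    ord <- order(vapply(pauses, `[`, numeric(1), 1))
    pauses <- pauses[ord]
    starts <- vapply(pauses, `[`, numeric(1), 1)
    ends <- vapply(pauses, `[`, numeric(1), 2)
    if (any(starts[-1] < ends[-length(ends)]))
      abort_semg("pause intervals must not overlap.", "format")
  }
  structure(
    list(participant_id = as.character(participant_id), session = session,
         trial_index = as.integer(trial_index),
         sampling_rate = sampling_rate, channels = as.character(channels),
         signal = signal, pauses = pauses, task_label = task_label),
    class = "semg_trial"
  )
}

#' @export
print.semg_trial <- function(x, ...) {
  cat(sprintf("<semg_trial> %s/%s trial %d: %d samples x %d channels (%s) @ %g Hz, %d pause(s)\n",
              x$participant_id, x$session, x$trial_index, nrow(x$signal),
              ncol(x$signal), paste(x$channels, collapse = ","),
              x$sampling_rate, length(x$pauses)))
  invisible(x)
}

#' Read one sEMG trial from a signal CSV and a JSON metadata sidecar
#'
#' The signal file is a CSV with a `time_s` column followed by one column per
#' channel (mV). The metadata JSON declares `participant_id`, `session`,
#' `trial_index`, `sampling_rate_hz`, `channels` (ordering authority),
#' `pauses` (list of `[start_s, end_s]`) and `task_label`.
#'
#' @param signal_path Path to the signal CSV.
#' @param meta_path Path to the metadata JSON.
#' @return A validated [semg_trial()]; channel order follows the metadata.
#' @export
read_trial <- function(signal_path, meta_path) {
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  needed <- c("participant_id", "session", "trial_index", "sampling_rate_hz",
              "channels")
  missing_keys <- setdiff(needed, names(meta))
  if (length(missing_keys))
    abort_semg(paste0("metadata is missing key(s): ",
                      paste(missing_keys, collapse = ", ")), "format")
  dat <- utils::read.csv(signal_path, check.names = FALSE)
  if (!"time_s" %in% names(dat))
    abort_semg("signal CSV must contain a `time_s` column.", "format")
  absent <- setdiff(meta$channels, names(dat))
  if (length(absent))
    abort_semg(paste0("signal CSV lacks channel column(s): ",
                      paste(absent, collapse = ", ")), "format")
  fs <- meta$sampling_rate_hz
  dt <- diff(dat$time_s)
  if (length(dt) && max(abs(dt - 1 / fs)) > 1e-6 / fs + 1e-12)
    abort_semg("time column is not uniform at the declared sampling rate (1 ppm tolerance).",
               "sampling")
  pauses <- meta$pauses
  if (is.null(pauses) || (is.data.frame(pauses) && nrow(pauses) == 0)) pauses <- list()
  if (is.matrix(pauses) || is.data.frame(pauses))
    pauses <- lapply(seq_len(nrow(pauses)), function(i) as.numeric(pauses[i, ]))
  semg_trial(
    signal = as.matrix(dat[meta$channels]),
    channels = meta$channels,
    sampling_rate = fs,
    participant_id = meta$participant_id,
    session = meta$session,
    trial_index = meta$trial_index,
    pauses = pauses,
    task_label = meta$task_label %||% ""
  )
}

#' Write an sEMG trial to a signal CSV and a JSON metadata sidecar
#'
#' Inverse of [read_trial()]; the pair round-trips through `read_trial()`.
#'
#' @param trial A [semg_trial()].
#' @param signal_path,meta_path Output paths.
#' @return `trial`, invisibly.
#' @export
write_trial <- function(trial, signal_path, meta_path) {
  stopifnot(inherits(trial, "semg_trial"))
  n <- nrow(trial$signal)
  time_s <- sprintf("%.6f", (seq_len(n) - 1) / trial$sampling_rate)
  cols <- c(list(time_s = time_s),
            lapply(seq_along(trial$channels),
                   function(j) sprintf("%.6f", trial$signal[, j])))
  names(cols) <- c("time_s", trial$channels)
  utils::write.csv(as.data.frame(cols, check.names = FALSE), signal_path,
                   row.names = FALSE, quote = FALSE)
  meta <- list(
    participant_id = trial$participant_id, session = trial$session,
    trial_index = trial$trial_index, sampling_rate_hz = trial$sampling_rate,
    channels = trial$channels,
    pauses = if (length(trial$pauses)) trial$pauses else list(),
    task_label = trial$task_label
  )
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(trial)
}

#' Remove operator-marked pauses from a trial
#'
#' Splits the recording at every pause and drops the paused samples, returning
#' the ordered non-pause segments. Segments are never concatenated across a
#' pause boundary: splicing would create artificial discontinuities that
#' inflate the turning-count features (ZC, SSC, WL). A sample at index `i`
#' (1-based) covers time `(i - 1) / fs` and is removed when that time falls in
#' a half-open pause `[start, end)`.
#'
#' @param trial A [semg_trial()].
#' @return List of samples-by-channels matrices, each with a `start_sample`
#'   attribute giving its 0-based offset in the original recording. The total
#'   number of retained samples plus excised samples equals the trial length.
#' @export
excise_pauses <- function(trial) {
  stopifnot(inherits(trial, "semg_trial"))
  n <- nrow(trial$signal)
  fs <- trial$sampling_rate
  keep <- rep(TRUE, n)
  t0 <- (seq_len(n) - 1) / fs
  for (p in trial$pauses)
    keep[t0 >= p[1] - 1e-12 & t0 < p[2] - 1e-12] <- FALSE
  if (!any(keep))
    abort_semg("pauses cover the entire trial; nothing retained.", "empty_result")
  runs <- rle(keep)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  segs <- list()
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    seg <- trial$signal[starts[k]:ends[k], , drop = FALSE]
    attr(seg, "start_sample") <- starts[k] - 1L
    segs[[length(segs) + 1]] <- seg
  }
  segs
}
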