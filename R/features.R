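#' Time-domain sEMG features
#'
#' The five classic time-domain features computed per epoch and channel.
#' `mav`, `rms` and `wl` are magnitude-related (group I, mV); `zc` and `ssc`
#' are motor-unit-firing-related counts (group II). Definitions, with `x(t)`
#' the epoch series of `T` samples:
#'
#' * `mav`: mean absolute value, `(1/T) sum |x(t)|`.
#' * `rms`: root mean square, `sqrt((1/T) sum x(t)^2)`.
#' * `zc`: number of sign oppositions of consecutive samples whose amplitude
#'   step also reaches `deadband`: counts `t` with `x(t) * x(t+1) < 0` and
#'   `|x(t) - x(t+1)| >= deadband`. A sample exactly at zero never counts as a
#'   crossing by itself.
#' * `ssc`: number of slope-sign changes: counts interior `t` with
#'   `(x(t) - x(t-1)) * (x(t) - x(t+1)) > 0` and both steps at least
#'   `deadband`. The inequality is strict, so a constant series has no
#'   turning points.
#' * `wl`: normalized waveform length, `(1/T) sum |x(t+1) - x(t)|`. Note the
#'   normalization by the epoch length `T`.
#'
#' @param x Numeric series (one epoch, one channel).
#' @param deadband Minimum amplitude step for a crossing/turn to count
#'   (default 0).
#' @return A scalar: mV for `mav`, `rms`, `wl`; an integer count for `zc`
#'   (in `[0, T-1]`) and `ssc` (in `[0, T-2]`).
#' @examples
#' mav(c(1, -1, 2, -2))  # 1.5
#' rms(c(3, 4, 0, 0))    # 2.5
#' zc(c(1, -1, 1, -1))   # 3
#' ssc(c(0, 1, 0, 1, 0)) # 3
#' wl(c(0, 1, 2, 3))     # 0.75
#' @name semg_features
NULL

#' @rdname semg_features
#' @export
mav <- function(x) {
  if (length(x) < 1) abort_semg("mav needs at least 1 sample.", "length")
  mean(abs(x))
}

#' @rdname semg_features
#' @export
rms <- function(x) {
  if (length(x) < 1) abort_semg("rms needs at least 1 sample.", "length")
  sqrt(mean(x^2))
}

#' @rdname semg_features
#' @export
zc <- function(x, deadband = 0) {
  if (length(x) < 2) abort_semg("zc needs at least 2 samples.", "length")
  a <- x[-length(x)]
  b <- x[-1]
  sum(a * b < 0 & abs(a - b) >= deadband)
}

#' @rdname semg_features
#' @export
ssc <- function(x, deadband = 0) {
  if (length(x) < 3) abort_semg("ssc needs at least 3 samples.", "length")
  T_len <- length(x)
  d1 <- x[2:(T_len - 1)] - x[1:(T_len - 2)]
  d2 <- x[2:(T_len - 1)] - x[3:T_len]
  sum(d1 * d2 > 0 & abs(d1) >= deadband & abs(d2) >= deadband)
}

#' @rdname semg_features
#' @export
wl <- function(x) {
  if (length(x) < 2) abort_semg("wl needs at least 2 samples.", "length")
  sum(abs(diff(x))) / length(x)
}

# canonical orderings used everywhere a vector layout matters
SEMG_FEATURES <- c("MAV", "ZC", "SSC", "RMS", "WL")
SEMG_CHANNELS <- c("ED", "FD", "BIC", "TRI")

canonical_features <- function(features) {
  features <- toupper(features)
  bad <- setdiff(features, SEMG_FEATURES)
  if (length(bad))
    abort_semg(paste0("unknown feature(s): ", paste(bad, collapse = ", ")), "value")
  if (!length(features)) abort_semg("feature set must be non-empty.", "value")
  SEMG_FEATURES[SEMG_FEATURES %in% features]
}

canonical_channels <- function(channels) {
  channels <- toupper(channels)
  bad <- setdiff(channels, SEMG_CHANNELS)
  if (length(bad))
    abort_semg(paste0("unknown channel(s): ", paste(bad, collapse = ", ")), "channel")
  if (!length(channels)) abort_semg("channel set must be non-empty.", "channel")
  SEMG_CHANNELS[SEMG_CHANNELS %in% channels]
}

feature_column_names <- function(channels, features) {
  as.vector(vapply(channels, function(ch) paste(ch, features, sep = "_"),
                   character(length(features))))
}

single_feature <- function(x, feature, deadband = 0) {
  switch(feature,
         MAV = mav(x), ZC = zc(x, deadband), SSC = ssc(x, deadband),
         RMS = rms(x), WL = wl(x))
}

#' Assemble the model input vector for one epoch
#'
#' Concatenates the selected features over the selected channels in canonical
#' channel-major, feature-minor order (channels ED, FD, BIC, TRI; features
#' MAV, ZC, SSC, RMS, WL). Four channels with all five features give the
#' 20-element input vector of the full model.
#'
#' @param epoch An epoch from [segment_epochs()] or a T-by-channels matrix
#'   with channel column names.
#' @param features Feature subset (any order; canonicalized).
#' @param channels Channel subset (any order; canonicalized). Default: all
#'   channels present in the epoch.
#' @param deadband Amplitude deadband for `zc`/`ssc` (default 0).
#' @return Named numeric vector of length `length(channels) * length(features)`.
#' @export
build_feature_vector <- function(epoch, features = SEMG_FEATURES,
                                 channels = NULL, deadband = 0) {
  if (inherits(epoch, "semg_epoch")) epoch <- epoch$data
  x <- as_signal_matrix(epoch)
  features <- canonical_features(features)
  channels <- canonical_channels(channels %||% colnames(x))
  absent <- setdiff(channels, colnames(x))
  if (length(absent))
    abort_semg(paste0("epoch lacks channel(s): ", paste(absent, collapse = ", ")),
               "channel")
  vals <- unlist(lapply(channels, function(ch)
    vapply(features, function(f) single_feature(x[, ch], f, deadband), numeric(1))))
  stats::setNames(vals, feature_column_names(channels, features))
}

# vectorized per-segment feature table: all epochs of one contiguous segment
# at once (columns of `win` are epochs); exactly matches the scalar functions
segment_feature_table <- function(seg, fs, epoch_ms, step_ms, features,
                                  channels, deadband = 0) {
  T_len <- as.integer(round(epoch_ms * fs / 1000))
  step <- as.integer(round(step_ms * fs / 1000))
  L <- nrow(seg)
  if (L < T_len) return(NULL)
  starts <- seq.int(0L, L - T_len, by = step)
  idx <- outer(seq_len(T_len), starts, `+`)
  out <- matrix(NA_real_, nrow = length(starts),
                ncol = length(channels) * length(features))
  colnames(out) <- feature_column_names(channels, features)
  for (ch in channels) {
    win <- matrix(seg[, ch][idx], nrow = T_len)
    for (f in features) {
      v <- switch(f,
        MAV = colMeans(abs(win)),
        RMS = sqrt(colMeans(win^2)),
        WL  = colSums(abs(win[-1, , drop = FALSE] - win[-T_len, , drop = FALSE])) / T_len,
        ZC  = {
          a <- win[-T_len, , drop = FALSE]; b <- win[-1, , drop = FALSE]
          colSums(a * b < 0 & abs(a - b) >= deadband)
        },
        SSC = {
          m <- win[2:(T_len - 1), , drop = FALSE]
          d1 <- m - win[1:(T_len - 2), , drop = FALSE]
          d2 <- m - win[3:T_len, , drop = FALSE]
          colSums(d1 * d2 > 0 & abs(d1) >= deadband & abs(d2) >= deadband)
        })
      out[, paste(ch, f, sep = "_")] <- v
    }
  }
  list(starts = starts, values = out)
}

#' Extract per-epoch features from one trial or a cohort of trials
#'
#' Runs the full preprocessing and feature pipeline: pause excision, zero-phase
#' filtering of each contiguous segment, overlapping-epoch segmentation, and
#' per-epoch, per-channel time-domain features. Returns one row per epoch with
#' `<MUSCLE>_<FEATURE>` columns in canonical order.
#'
#' @param trials A [semg_trial()] or a list of them.
#' @param features Feature subset (default all five).
#' @param channels Channel subset (default all channels of each trial).
#' @param filter A [filter_spec()]; applied per contiguous segment.
#' @param extra_lowpass_hz Optional additional zero-phase 4th-order low-pass
#'   (used by the MAS cutoff sweep). A cutoff at or above Nyquist is a no-op.
#' @param epoch_ms,step_ms Epoch geometry, see [segment_epochs()].
#' @param deadband Amplitude deadband for `zc`/`ssc`.
#' @param wss If `TRUE`, adds a `wss_pass` column: `TRUE` when every channel
#'   of the epoch passes [check_wss()] (informational; nothing is excluded).
#' @return A tibble with columns `participant_id`, `session`, `trial_index`,
#'   `segment`, `start_sample`, then one column per channel-feature pair.
#' @export
extract_features <- function(trials, features = SEMG_FEATURES, channels = NULL,
                             filter = filter_spec(), extra_lowpass_hz = NULL,
                             epoch_ms = 400, step_ms = 200, deadband = 0,
                             wss = FALSE) {
  if (inherits(trials, "semg_trial")) trials <- list(trials)
  features <- canonical_features(features)
  purrr::map_dfr(trials, function(trial) {
    chs <- canonical_channels(channels %||% trial$channels)
    absent <- setdiff(chs, trial$channels)
    if (length(absent))
      abort_semg(paste0("trial lacks channel(s): ", paste(absent, collapse = ", ")),
                 "channel")
    fs <- trial$sampling_rate
    segs <- excise_pauses(trial)
    rows <- list()
    for (s in seq_along(segs)) {
      seg <- segs[[s]]
      if (nrow(seg) <= 3 * filter$order) next
      filt <- apply_filters(seg, fs, filter)
      if (!is.null(extra_lowpass_hz) && extra_lowpass_hz < fs / 2) {
        lp <- signal::butter(4, extra_lowpass_hz / (fs / 2), type = "low")
        filt <- zero_phase_filter(lp$b, lp$a, filt)
        colnames(filt) <- colnames(seg)
      }
      tab <- segment_feature_table(filt, fs, epoch_ms, step_ms, features, chs,
                                   deadband)
      if (is.null(tab)) next
      df <- tibble::as_tibble(as.data.frame(tab$values))
      df <- tibble::add_column(df, segment = s, start_sample = tab$starts,
                               .before = 1)
      if (wss) {
        T_len <- as.integer(round(epoch_ms * fs / 1000))
        df$wss_pass <- vapply(tab$starts, function(st)
          all(check_wss(filt[(st + 1):(st + T_len), chs, drop = FALSE])),
          logical(1))
      }
      rows[[length(rows) + 1]] <- df
    }
    if (!length(rows)) return(tibble::tibble())
    dplyr::bind_rows(rows) |>
      tibble::add_column(participant_id = trial$participant_id,
                         session = trial$session,
                         trial_index = trial$trial_index, .before = 1)
  })
}
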