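#' Segment contiguous signal segments into overlapping analysis epochs
#'
#' Within each contiguous (pause-free) segment, windows of `epoch_ms` start at
#' 0, `step_ms`, 2 x `step_ms`, ... samples while the window still fits.
#' Windows never span a segment boundary. With the defaults (400 ms windows,
#' 200 ms step at 1000 Hz) each epoch holds T = 400 samples and consecutive
#' epochs overlap by 50%.
#'
#' @param segments A samples-by-channels matrix or a list of them (e.g. the
#'   output of [excise_pauses()]).
#' @param fs Sampling rate in Hz.
#' @param epoch_ms Epoch length in milliseconds (default 400).
#' @param step_ms Step between epoch starts in milliseconds (default 200).
#' @return List of epochs; each is a list with `data` (T-by-channels matrix),
#'   `start_sample` (0-based offset within its segment, a multiple of the
#'   step) and `segment` (segment index).
#' @examples
#' segs <- list(matrix(rnorm(1000), ncol = 1))
#' length(segment_epochs(segs, fs = 1000))  # 4 epochs: starts 0,200,400,600
#' @export
segment_epochs <- function(segments, fs, epoch_ms = 400, step_ms = 200) {
  if (epoch_ms <= step_ms || step_ms <= 0)
    abort_semg("need `epoch_ms` > `step_ms` > 0.", "parameter")
  if (!is.list(segments)) segments <- list(segments)
  T_len <- as.integer(round(epoch_ms * fs / 1000))
  step <- as.integer(round(step_ms * fs / 1000))
  out <- list()
  for (s in seq_along(segments)) {
    seg <- as_signal_matrix(segments[[s]])
    L <- nrow(seg)
    if (L < T_len) next
    starts <- seq.int(0L, L - T_len, by = step)
    for (st in starts) {
      out[[length(out) + 1]] <- structure(
        list(data = seg[(st + 1):(st + T_len), , drop = FALSE],
             start_sample = as.integer(st), segment = s),
        class = "semg_epoch")
    }
  }
  if (!length(out))
    abort_semg(sprintf("no segment is long enough for one %d-sample epoch.", T_len),
               "empty_result")
  out
}

#' Check an epoch for wide-sense stationarity
#'
#' Operationalizes the requirement that an epoch's mean and autocorrelation be
#' time-invariant: the epoch is split into `n_subwindows` equal sub-windows,
#' and a channel passes when (a) a one-way location test across sub-windows is
#' not significant at `alpha`, and (b) every pair of sub-window
#' autocorrelation profiles (lags 0..`n_lags`) has normalized inner product
#' of at least `similarity`. The flag is informational: epochs are not
#' excluded on failure.
#'
#' @param epoch A T-by-channels matrix or an epoch from [segment_epochs()].
#' @param n_subwindows Number of equal sub-windows (default 4); must divide T.
#' @param alpha Significance level for the location test (default 0.05).
#' @param n_lags Autocorrelation lags compared (default 20).
#' @param similarity Minimum pairwise cosine similarity of autocorrelation
#'   profiles (default 0.7).
#' @return Named logical vector, one flag per channel.
#' @export
check_wss <- function(epoch, n_subwindows = 4, alpha = 0.05,
                      n_lags = 20, similarity = 0.7) {
  if (inherits(epoch, "semg_epoch")) epoch <- epoch$data
  x <- as_signal_matrix(epoch)
  if (n_subwindows < 2)
    abort_semg("`n_subwindows` must be at least 2.", "parameter")
  T_len <- nrow(x)
  if (T_len %% n_subwindows != 0)
    abort_semg("epoch length must be divisible by `n_subwindows`.", "parameter")
  w <- T_len / n_subwindows
  grp <- rep(seq_len(n_subwindows), each = w)
  res <- apply(x, 2, function(col) {
    sds <- tapply(col, grp, stats::sd)
    if (all(sds < 1e-12)) {
      # (near-)constant: mean and autocorrelation trivially time-invariant
      return(stats::sd(col) < 1e-12)
    }
    p_loc <- tryCatch(stats::oneway.test(col ~ factor(grp), var.equal = TRUE)$p.value,
                      error = function(e) 0)
    if (is.na(p_loc) || p_loc < alpha) return(FALSE)
    prof <- vapply(seq_len(n_subwindows), function(k) {
      sub <- col[grp == k]
      if (stats::sd(sub) < 1e-12) return(c(1, rep(0, n_lags)))
      as.numeric(stats::acf(sub, lag.max = n_lags, plot = FALSE,
                            demean = TRUE)$acf)
    }, numeric(n_lags + 1))
    for (i in seq_len(n_subwindows - 1)) {
      for (j in (i + 1):n_subwindows) {
        num <- sum(prof[, i] * prof[, j])
        den <- sqrt(sum(prof[, i]^2) * sum(prof[, j]^2))
        if (num / den < similarity) return(FALSE)
      }
    }
    TRUE
  })
  stats::setNames(as.logical(res), colnames(x))
}
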