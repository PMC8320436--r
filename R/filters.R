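#' Filter chain specification for sEMG preprocessing
#'
#' Describes the standard offline sEMG conditioning chain: a Butterworth
#' high-pass, an optional Butterworth low-pass, and a mains notch. All stages
#' are applied zero-phase (forward-backward), so burst timing is preserved.
#' When `lowpass_hz` is at or above the Nyquist frequency of the signal the
#' low-pass stage is skipped: a Butterworth edge at Nyquist is numerically
#' degenerate and the stage would be a no-op anyway.
#'
#' @param highpass_hz High-pass cutoff in Hz (default 10).
#' @param lowpass_hz Low-pass cutoff in Hz (default 500). May equal the
#'   Nyquist frequency, in which case the stage is skipped at apply time.
#' @param order Butterworth order for both band edges; one of 2, 4, 6, 8.
#' @param notch_hz Mains notch center frequency in Hz (default 50). `NULL`
#'   disables the notch.
#' @param notch_q Notch quality factor; the -3 dB bandwidth is
#'   `notch_hz / notch_q` (default 30, about 1.7 Hz at 50 Hz).
#' @return An object of class `filter_spec`.
#' @examples
#' filter_spec()                     # 10-500 Hz band-pass + 50 Hz notch
#' filter_spec(lowpass_hz = 200)     # MAS-oriented narrower band
#' @export
filter_spec <- function(highpass_hz = 10, lowpass_hz = 500, order = 4,
                        notch_hz = 50, notch_q = 30) {
  if (!order %in% c(2, 4, 6, 8))
    abort_semg("`order` must be one of 2, 4, 6, 8.", "parameter")
  if (!is.numeric(highpass_hz) || highpass_hz <= 0)
    abort_semg("`highpass_hz` must be positive.", "parameter")
  if (!is.numeric(lowpass_hz) || lowpass_hz <= highpass_hz)
    abort_semg("`lowpass_hz` must exceed `highpass_hz`.", "parameter")
  if (!is.null(notch_hz) && notch_q <= 0)
    abort_semg("`notch_q` must be positive.", "parameter")
  structure(
    list(highpass_hz = highpass_hz, lowpass_hz = lowpass_hz, order = order,
         notch_hz = notch_hz, notch_q = notch_q),
    class = "filter_spec"
  )
}

# RBJ biquad notch: exact spectral null at f0, -3 dB bandwidth f0/Q
notch_coefficients <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  al <- sin(w0) / (2 * q)
  list(b = c(1, -2 * cos(w0), 1) / (1 + al),
       a = c(1, -2 * cos(w0) / (1 + al), (1 - al) / (1 + al)))
}

# zero-phase filtering with odd-reflection padding (keeps edge transients out
# of the data; signal::filtfilt pads nothing and rings badly at a narrow notch)
zero_phase_filter <- function(b, a, x, npad = 500L) {
  x <- as_signal_matrix(x)
  n <- nrow(x)
  npad <- as.integer(min(npad, n - 1L))
  apply(x, 2, function(col) {
    if (npad > 0) {
      head_pad <- 2 * col[1] - col[(npad + 1):2]
      tail_pad <- 2 * col[n] - col[(n - 1):(n - npad)]
      padded <- c(head_pad, col, tail_pad)
    } else padded <- col
    fwd <- as.numeric(signal::filter(b, a, padded))
    bwd <- rev(as.numeric(signal::filter(b, a, rev(fwd))))
    if (npad > 0) bwd[(npad + 1):(npad + n)] else bwd
  })
}

#' Apply the preprocessing filter chain to a signal segment
#'
#' Applies, in order: zero-phase Butterworth high-pass, zero-phase Butterworth
#' low-pass (skipped when the cutoff is at or above Nyquist), and a zero-phase
#' biquad notch. Shape is preserved.
#'
#' @param segment Numeric vector or samples-by-channels matrix, in mV.
#' @param fs Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Filtered signal with the same shape as `segment`.
#' @examples
#' fs <- 1000
#' x <- sin(2 * pi * 100 * seq(0, 1, by = 1 / fs))
#' y <- apply_filters(x, fs, filter_spec())
#' @export
apply_filters <- function(segment, fs, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  was_vector <- is.null(dim(segment))
  x <- as_signal_matrix(segment)
  if (nrow(x) <= 3 * spec$order)
    abort_semg(sprintf(
      "segment of %d samples is too short for stable order-%d filtering (need > %d).",
      nrow(x), spec$order, 3 * spec$order), "length")
  nyq <- fs / 2
  if (spec$highpass_hz >= nyq)
    abort_semg("high-pass cutoff must be below the Nyquist frequency.", "parameter")
  hp <- signal::butter(spec$order, spec$highpass_hz / nyq, type = "high")
  x <- zero_phase_filter(hp$b, hp$a, x)
  if (spec$lowpass_hz < nyq) {
    lp <- signal::butter(spec$order, spec$lowpass_hz / nyq, type = "low")
    x <- zero_phase_filter(lp$b, lp$a, x)
  }
  if (!is.null(spec$notch_hz) && spec$notch_hz < nyq) {
    nc <- notch_coefficients(spec$notch_hz, fs, spec$notch_q)
    x <- zero_phase_filter(nc$b, nc$a, x)
  }
  if (was_vector) drop(x) else {
    colnames(x) <- colnames(as_signal_matrix(segment))
    dimnames(x) <- dimnames(segment) %||% dimnames(x)
    x
  }
}
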