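#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a trial's channel traces
#'
#' @param object A [semg_trial()].
#' @param max_points Approximate number of points drawn per channel (the
#'   signal is thinned for display; default 5000).
#' @param ... Unused.
#' @return A ggplot object: one facet per channel, pauses shaded.
#' @exportS3Method ggplot2::autoplot
autoplot.semg_trial <- function(object, max_points = 5000, ...) {
  n <- nrow(object$signal)
  stride <- max(1L, floor(n / max_points))
  idx <- seq.int(1L, n, by = stride)
  df <- tibble::tibble(
    time_s = rep((idx - 1) / object$sampling_rate, ncol(object$signal)),
    mv = as.vector(object$signal[idx, ]),
    channel = factor(rep(object$channels, each = length(idx)),
                     levels = object$channels)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$mv)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "time (s)", y = "sEMG (mV)",
                  title = sprintf("%s / %s, trial %d", object$participant_id,
                                  object$session, object$trial_index))
  for (pa in object$pauses)
    p <- p + ggplot2::annotate("rect", xmin = pa[1], xmax = pa[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.15)
  p
}

#' Plot mapped against manual scores for a cross-validation run
#'
#' @param object A `semg_cv` object from [run_cv()].
#' @param ... Unused.
#' @return A ggplot object: pooled mapped vs manual scores with the identity
#'   line, colored by session.
#' @exportS3Method ggplot2::autoplot
autoplot.semg_cv <- function(object, ...) {
  ggplot2::ggplot(object$pooled,
                  ggplot2::aes(x = .data$manual, y = .data$mapped,
                               colour = .data$session)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = paste("manual", object$scale), y = paste("mapped", object$scale),
      title = sprintf("%s: mean per-fold r = %.2f (pooled r = %.2f)",
                      object$scale, object$r, object$r_pooled))
}

#' Plot a sweep result
#'
#' @param object A `semg_sweep` object.
#' @param ... Unused.
#' @return A ggplot object: r against the swept parameter, one line per
#'   scale where applicable.
#' @exportS3Method ggplot2::autoplot
autoplot.semg_sweep <- function(object, ...) {
  tab <- object$table
  xvar <- intersect(c("n_hidden", "cutoff_hz", "fraction", "combination"),
                    names(tab))[1]
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data[[xvar]], y = .data$r))
  if ("scale" %in% names(tab))
    p <- p + ggplot2::aes(colour = .data$scale, group = .data$scale)
  if (xvar == "combination")
    p <- p + ggplot2::geom_col(position = "dodge") +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  else p <- p + ggplot2::geom_line() + ggplot2::geom_point()
  p + ggplot2::labs(y = "Pearson r", title = object$kind)
}

#' @export
plot.semg_trial <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.semg_cv <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.semg_sweep <- function(x, ...) print(autoplot(x, ...))
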