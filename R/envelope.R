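#' Linear envelope of an sEMG segment
#'
#' Full-wave rectification followed by a zero-phase 2nd-order Butterworth
#' low-pass (default 6 Hz), the standard linear-envelope recipe. Numerical
#' undershoot is clipped at 0. The result is un-normalized; see
#' [normalize_session()].
#'
#' @param segment Numeric vector or samples-by-channels matrix (mV).
#' @param fs Sampling rate in Hz.
#' @param lp_hz Envelope low-pass cutoff in Hz (default 6).
#' @return Envelope with the same shape as `segment`, non-negative.
#' @export
compute_envelope <- function(segment, fs, lp_hz = 6) {
  was_vector <- is.null(dim(segment))
  x <- as_signal_matrix(segment)
  if (nrow(x) <= 12)
    abort_semg("segment too short for envelope filtering.", "length")
  lp <- signal::butter(2, lp_hz / (fs / 2), type = "low")
  env <- zero_phase_filter(lp$b, lp$a, abs(x))
  env[env < 0] <- 0
  colnames(env) <- colnames(x)
  if (was_vector) drop(env) else env
}

#' Normalize envelopes by the session-wise maximum of a muscle
#'
#' Every envelope of one muscle recorded in one session is divided by the
#' maximum envelope value that muscle reached anywhere in the session, so the
#' session-wide maximum becomes exactly 1.
#'
#' @param envelopes A numeric vector or a list of numeric vectors (all trials
#'   of one muscle in one session).
#' @return Same structure as `envelopes`, scaled into `[0, 1]`.
#' @export
normalize_session <- function(envelopes) {
  single <- !is.list(envelopes)
  if (single) envelopes <- list(envelopes)
  mx <- max(vapply(envelopes, max, numeric(1)))
  if (!is.finite(mx) || mx <= 0)
    abort_semg("all-zero session: cannot normalize envelopes.", "degenerate_normalization")
  out <- lapply(envelopes, function(e) e / mx)
  if (single) out[[1]] else out
}

#' Muscle activation level
#'
#' Time-average of a muscle's normalized linear envelope over a trial
#' (discretized as the sample mean). With a session-normalized envelope the
#' value lies in `[0, 1]`; values near 1 indicate near-continuous activity at
#' the session maximum.
#'
#' @param env Normalized envelope series.
#' @return Scalar in `[0, 1]`.
#' @export
activation_level <- function(env) {
  if (length(env) < 1) abort_semg("empty envelope.", "length")
  mean(env)
}

#' Co-contraction index of a muscle pair
#'
#' Time-average of the overlapping activity of two muscles' normalized linear
#' envelopes. The default overlap is the pointwise minimum (area-of-overlap
#' reading), which makes the index symmetric and bounded above by the smaller
#' activation level; `method = "product"` uses the pointwise product instead.
#'
#' @param env_i,env_j Normalized envelope series of equal length.
#' @param method `"min"` (default) or `"product"`.
#' @return Scalar in `[0, 1]`.
#' @export
cocontraction_index <- function(env_i, env_j, method = c("min", "product")) {
  method <- match.arg(method)
  if (length(env_i) != length(env_j))
    abort_semg("envelopes must have equal length.", "alignment")
  if (!length(env_i)) abort_semg("empty envelope.", "length")
  if (method == "min") mean(pmin(env_i, env_j)) else mean(env_i * env_j)
}

default_ci_pairs <- function(channels) {
  all_pairs <- utils::combn(channels, 2, simplify = FALSE)
  all_pairs
}

#' Per-participant sEMG parameters: activation levels and co-contraction
#'
#' Computes, for every participant-session, the session-normalized activation
#' level of each muscle and the co-contraction index of each muscle pair,
#' averaged over the session's trials. Signals are pause-excised and filtered
#' per contiguous segment before envelope extraction.
#'
#' @param trials List of [semg_trial()] objects (typically a whole cohort).
#' @param filter A [filter_spec()] applied before envelope extraction.
#' @param lp_hz Envelope low-pass cutoff in Hz (default 6).
#' @param method Overlap rule for [cocontraction_index()].
#' @return A tibble with one row per participant-session: `AL_<MUSCLE>`
#'   columns and `CI_<M1>_<M2>` columns for every muscle pair present.
#' @export
semg_parameters <- function(trials, filter = filter_spec(), lp_hz = 6,
                            method = c("min", "product")) {
  method <- match.arg(method)
  if (inherits(trials, "semg_trial")) trials <- list(trials)
  # per-trial envelopes, grouped by participant-session
  info <- purrr::map(trials, function(trial) {
    segs <- excise_pauses(trial)
    envs <- lapply(segs, function(seg) {
      filt <- apply_filters(seg, trial$sampling_rate, filter)
      compute_envelope(filt, trial$sampling_rate, lp_hz)
    })
    env <- do.call(rbind, envs)
    colnames(env) <- trial$channels
    list(participant_id = trial$participant_id, session = trial$session,
         channels = trial$channels, env = env)
  })
  keys <- vapply(info, function(z) paste(z$participant_id, z$session, sep = "\r"),
                 character(1))
  purrr::map_dfr(unique(keys), function(k) {
    grp <- info[keys == k]
    chs <- canonical_channels(Reduce(intersect, lapply(grp, `[[`, "channels")))
    # session-wise maximum per muscle across all trials of the session
    mx <- vapply(chs, function(ch)
      max(vapply(grp, function(z) max(z$env[, ch]), numeric(1))), numeric(1))
    if (any(mx <= 0))
      abort_semg("a muscle has an all-zero session; cannot normalize.",
                 "degenerate_normalization")
    al <- vapply(chs, function(ch)
      mean(vapply(grp, function(z) activation_level(z$env[, ch] / mx[ch]),
                  numeric(1))), numeric(1))
    pairs <- default_ci_pairs(chs)
    ci <- vapply(pairs, function(p)
      mean(vapply(grp, function(z)
        cocontraction_index(z$env[, p[1]] / mx[p[1]], z$env[, p[2]] / mx[p[2]],
                            method = method), numeric(1))), numeric(1))
    names(ci) <- vapply(pairs, function(p) paste("CI", p[1], p[2], sep = "_"),
                        character(1))
    row <- c(as.list(stats::setNames(al, paste0("AL_", chs))), as.list(ci))
    tibble::tibble(participant_id = grp[[1]]$participant_id,
                   session = grp[[1]]$session, !!!row)
  })
}

#' Paired pre/post comparison of sEMG parameters
#'
#' For every numeric parameter column, pairs participants across the two
#' sessions and reports Shapiro-Wilk normality p-values per session, the
#' paired t-test statistic and p-value, per-session means and SDs, and
#' significance stars (0.05 / 0.01 / 0.001). A zero-variance paired
#' difference is flagged as degenerate instead of tested.
#'
#' @param params Output of [semg_parameters()] (or any tibble with
#'   `participant_id`, `session` and numeric parameter columns) containing
#'   both sessions.
#' @return A tibble with one row per parameter.
#' @export
compare_sessions <- function(params) {
  num_cols <- setdiff(names(params)[vapply(params, is.numeric, logical(1))],
                      c("trial_index"))
  pre <- dplyr::filter(params, .data$session == "pre")
  post <- dplyr::filter(params, .data$session == "post")
  ids <- intersect(pre$participant_id, post$participant_id)
  if (length(ids) < 3)
    abort_semg("need at least 3 paired participants.", "sample_size")
  pre <- pre[match(ids, pre$participant_id), ]
  post <- post[match(ids, post$participant_id), ]
  purrr::map_dfr(num_cols, function(col) {
    a <- pre[[col]]
    b <- post[[col]]
    d <- b - a
    degenerate <- stats::sd(d) < 1e-12
    sh_p_pre <- if (stats::sd(a) > 1e-12) stats::shapiro.test(a)$p.value else NA_real_
    sh_p_post <- if (stats::sd(b) > 1e-12) stats::shapiro.test(b)$p.value else NA_real_
    if (degenerate) {
      stat <- if (all(abs(d) < 1e-12)) 0 else NA_real_
      pv <- if (all(abs(d) < 1e-12)) 1 else NA_real_
    } else {
      tt <- stats::t.test(b, a, paired = TRUE)
      stat <- unname(tt$statistic)
      pv <- tt$p.value
    }
    tibble::tibble(
      parameter = col, n = length(ids),
      mean_pre = mean(a), sd_pre = stats::sd(a),
      mean_post = mean(b), sd_post = stats::sd(b),
      shapiro_p_pre = sh_p_pre, shapiro_p_post = sh_p_post,
      statistic = stat, p_value = pv,
      stars = significance_stars(pv), degenerate = degenerate
    )
  })
}
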