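#' Assign epochs to cross-validation folds within each trial
#'
#' Within every trial the epochs are shuffled (seeded) and partitioned into
#' `n_folds` near-equal disjoint blocks; fold `k`'s test set is block `k`
#' from every trial, so with 5 folds 80% of the epochs of each trial train
#' the model and 20% test it, and over the folds every epoch is tested
#' exactly once. Block sizes differ by at most one (larger blocks first:
#' 49 epochs give 10, 10, 10, 10, 9).
#'
#' @param features Epoch feature tibble from [extract_features()] (needs
#'   `participant_id`, `session`, `trial_index`).
#' @param n_folds Number of folds (default 5).
#' @param seed RNG seed for the within-trial shuffle.
#' @return `features` with an integer `fold` column appended.
#' @export
make_folds <- function(features, n_folds = 5, seed = 1L) {
  if (n_folds < 2) abort_semg("`n_folds` must be at least 2.", "parameter")
  key <- paste(features$participant_id, features$session,
               features$trial_index, sep = "\r")
  fold <- integer(nrow(features))
  with_local_seed(seed, {
    for (k in unique(key)) {
      rows <- which(key == k)
      m <- length(rows)
      if (m < n_folds) {
        first <- features[rows[1], ]
        abort_semg(sprintf(
          "trial %s/%s/%s has %d epochs; need at least %d for %d-fold splitting.",
          first$participant_id, first$session, first$trial_index, m, n_folds,
          n_folds), "split")
      }
      sizes <- rep(m %/% n_folds, n_folds)
      extra <- m %% n_folds
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
      fold[rows[sample.int(m)]] <- rep(seq_len(n_folds), times = sizes)
    }
  })
  dplyr::mutate(features, fold = fold)
}

# join per-epoch targets for one clinical scale onto the feature table
epoch_targets <- function(features, scores, scale) {
  if (!scale %in% names(scores))
    abort_semg(paste0("scores table lacks column ", scale), "value")
  sc <- scores[c("participant_id", "session", scale)]
  tgt <- if (grepl("^MAS", scale)) encode_mas(sc[[scale]]) else
    as.numeric(sc[[scale]])
  sc$.target <- tgt
  out <- dplyr::left_join(features, sc[c("participant_id", "session", ".target")],
                          by = c("participant_id", "session"))
  if (anyNA(out$.target))
    abort_semg("some epochs have no matching clinical score.", "coverage")
  out
}

cv_feature_columns <- function(features, feature_set, channels) {
  feature_set <- canonical_features(feature_set)
  if (is.null(channels)) {
    present <- unique(sub("_.*$", "", grep("^(ED|FD|BIC|TRI)_", names(features),
                                           value = TRUE)))
    channels <- canonical_channels(present)
  } else channels <- canonical_channels(channels)
  cols <- feature_column_names(channels, feature_set)
  absent <- setdiff(cols, names(features))
  if (length(absent))
    abort_semg(paste0("feature table lacks column(s): ",
                      paste(absent, collapse = ", ")), "channel")
  list(cols = cols, channels = channels, feature_set = feature_set)
}

participant_level <- function(df) {
  dplyr::summarise(dplyr::group_by(df, .data$participant_id, .data$session),
                   mapped = mean(.data$.pred), manual = .data$.target[1],
                   n_epochs = dplyr::n(), .groups = "drop")
}

# pearson between mapped and manual scores; a network collapsed to a constant
# output carries no linear association, so it scores r = 0 instead of erroring
mapped_pearson <- function(mapped, manual) {
  if (stats::sd(mapped) < 1e-15)
    return(tibble::tibble(r = 0, t = 0, df = length(mapped) - 2, p = 1,
                          stars = "", n = length(mapped)))
  pearson(mapped, manual)
}

#' Five-fold cross-validated mapping of sEMG features to a clinical scale
#'
#' For each fold, a network is trained on the fold's training epochs and the
#' held-out epochs of every participant-session are mapped and averaged into
#' a final mapped score; the fold's Pearson r is computed between mapped and
#' manual scores over the participant-sessions. The headline `r` is the mean
#' per-fold r (with its t-transform p-value at `n - 2` df); the
#' pooled-prediction correlation `r_pooled` (every epoch predicted by the
#' model of the fold holding it out) is also reported.
#'
#' @param features Epoch feature tibble from [extract_features()].
#' @param scores Clinical score tibble (`participant_id`, `session`, scale
#'   columns; MAS as grade strings).
#' @param scale Target scale name, e.g. `"FMA_SE"`.
#' @param feature_set Features used as inputs (default the selected
#'   MAV, SSC, RMS, ZC combination).
#' @param channels Muscle channels used (default: all present in `features`).
#' @param n_hidden Hidden-layer size (default 15).
#' @param n_folds Number of folds (default 5).
#' @param seed Seed for fold assignment and weight initialization.
#' @param config A [bpnn_config()]; its seed is offset per fold.
#' @return An object of class `semg_cv`; see [tidy.semg_cv()] and
#'   [glance.semg_cv()].
#' @export
run_cv <- function(features, scores, scale,
                   feature_set = c("MAV", "SSC", "RMS", "ZC"),
                   channels = NULL, n_hidden = 15, n_folds = 5, seed = 1L,
                   config = bpnn_config()) {
  sel <- cv_feature_columns(features, feature_set, channels)
  df <- epoch_targets(features, scores, scale)
  if (length(unique(df$participant_id)) < 3)
    abort_semg("need at least 3 participants.", "sample_size")
  manual_ps <- dplyr::distinct(df, .data$participant_id, .data$session,
                               .data$.target)
  if (stats::sd(manual_ps$.target) < 1e-15)
    abort_semg("manual scores are constant across participants.",
               "undefined_correlation")
  df <- make_folds(df, n_folds = n_folds, seed = seed)
  fold_stats <- list()
  pooled <- list()
  for (k in seq_len(n_folds)) {
    train <- df[df$fold != k, ]
    test <- df[df$fold == k, ]
    cfg <- config
    cfg$seed <- config$seed + k - 1L
    model <- bpnn_train(as.matrix(train[sel$cols]), train$.target,
                        n_hidden = n_hidden, target_range = scale, config = cfg)
    test$.pred <- predict(model, as.matrix(test[sel$cols]))
    per_ps <- participant_level(test)
    pr <- mapped_pearson(per_ps$mapped, per_ps$manual)
    fold_stats[[k]] <- tibble::tibble(fold = k, r = pr$r, p = pr$p, n = pr$n)
    pooled[[k]] <- test[c("participant_id", "session", ".pred", ".target")]
  }
  per_fold <- dplyr::bind_rows(fold_stats)
  r_mean <- mean(per_fold$r)
  n_pts <- per_fold$n[1]
  t_stat <- r_mean * sqrt((n_pts - 2) / max(1 - r_mean^2, 1e-15))
  p_mean <- 2 * stats::pt(-abs(t_stat), df = n_pts - 2)
  pooled_ps <- participant_level(dplyr::bind_rows(pooled))
  pr_pool <- mapped_pearson(pooled_ps$mapped, pooled_ps$manual)
  structure(list(
    scale = scale, r = r_mean, p = p_mean, n = n_pts,
    per_fold = per_fold,
    pooled = pooled_ps,
    r_pooled = pr_pool$r, p_pooled = pr_pool$p,
    n_hidden = n_hidden, feature_set = sel$feature_set,
    channels = sel$channels, n_folds = n_folds, seed = seed
  ), class = "semg_cv")
}

#' @export
print.semg_cv <- function(x, ...) {
  cat(sprintf("<semg_cv> %s: mean per-fold r = %.3f (p = %.2g%s, n = %d), pooled r = %.3f\n",
              x$scale, x$r, x$p, significance_stars(x$p), x$n, x$r_pooled))
  cat(sprintf("  %d folds, %d hidden nodes, features %s over %s\n",
              x$n_folds, x$n_hidden, paste(x$feature_set, collapse = "+"),
              paste(x$channels, collapse = ",")))
  invisible(x)
}

#' Tidy per-fold cross-validation results
#'
#' @param x A `semg_cv` object.
#' @param ... Unused.
#' @return Tibble with one row per fold: `fold`, `r`, `p`, `n`.
#' @exportS3Method generics::tidy
tidy.semg_cv <- function(x, ...) x$per_fold

#' One-row summary of a cross-validation run
#'
#' @param x A `semg_cv` object.
#' @param ... Unused.
#' @return Tibble with the headline mean per-fold `r` and `p`, the pooled
#'   `r_pooled`/`p_pooled`, and the configuration.
#' @exportS3Method generics::glance
glance.semg_cv <- function(x, ...) {
  tibble::tibble(scale = x$scale, r = x$r, p = x$p, n = x$n,
                 r_pooled = x$r_pooled, p_pooled = x$p_pooled,
                 n_folds = x$n_folds, n_hidden = x$n_hidden,
                 features = paste(x$feature_set, collapse = "+"),
                 channels = paste(x$channels, collapse = ","))
}

#' Mismatched-session generalization test
#'
#' Trains on every epoch of the training session (no fold splitting) and maps
#' the other session's epochs, probing generalization across the intervention
#' shift. On improving cohorts the model extrapolates beyond its training
#' range and the mapped scores fall below the manual ones (negative bias).
#'
#' @inheritParams run_cv
#' @param train_session,test_session Session labels (default pre -> post).
#' @return An object of class `semg_mismatch` with `r`, `p`, `bias_mean`
#'   (mean mapped minus manual) and the per-participant table.
#' @export
mismatched_test <- function(features, scores, scale,
                            feature_set = c("MAV", "SSC", "RMS", "ZC"),
                            channels = NULL, n_hidden = 15, seed = 1L,
                            train_session = "pre", test_session = "post",
                            config = bpnn_config()) {
  sel <- cv_feature_columns(features, feature_set, channels)
  df <- epoch_targets(features, scores, scale)
  train <- df[df$session == train_session, ]
  test <- df[df$session == test_session, ]
  if (!nrow(train) || !nrow(test))
    abort_semg("both sessions must be present in the feature table.", "coverage")
  cfg <- config
  cfg$seed <- seed
  model <- bpnn_train(as.matrix(train[sel$cols]), train$.target,
                      n_hidden = n_hidden, target_range = scale, config = cfg)
  test$.pred <- predict(model, as.matrix(test[sel$cols]))
  per_ps <- participant_level(test)
  pr <- mapped_pearson(per_ps$mapped, per_ps$manual)
  structure(list(
    scale = scale, r = pr$r, p = pr$p, n = pr$n,
    bias_mean = mean(per_ps$mapped - per_ps$manual),
    by_participant = dplyr::mutate(per_ps, bias = .data$mapped - .data$manual),
    train_session = train_session, test_session = test_session,
    n_hidden = n_hidden, feature_set = sel$feature_set, channels = sel$channels
  ), class = "semg_mismatch")
}

#' @export
print.semg_mismatch <- function(x, ...) {
  cat(sprintf("<semg_mismatch> %s (%s -> %s): r = %.3f (p = %.2g), mean bias = %.2f\n",
              x$scale, x$train_session, x$test_session, x$r, x$p, x$bias_mean))
  invisible(x)
}
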