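new_semg_sweep <- function(kind, table, selected, extra = list()) {
  structure(c(list(kind = kind, table = table, selected = selected), extra),
            class = "semg_sweep")
}

#' @export
print.semg_sweep <- function(x, ...) {
  cat(sprintf("<semg_sweep> %s (selected: %s)\n", x$kind,
              paste(x$selected, collapse = ", ")))
  print(x$table)
  invisible(x)
}

#' Tidy a sweep result
#'
#' @param x A `semg_sweep` object.
#' @param ... Unused.
#' @return The sweep table (one row per grid point and scale).
#' @exportS3Method generics::tidy
tidy.semg_sweep <- function(x, ...) x$table

#' Hidden-layer size search
#'
#' Cross-validates the mapping for every hidden-layer size in `grid` against
#' each scale in `scales` and selects the smallest size whose correlation
#' exceeds `r_threshold` (very strong correlation) on every scale; when no
#' size clears the threshold, the size with the best mean r is selected (ties
#' resolved toward fewer nodes).
#'
#' @inheritParams run_cv
#' @param grid Hidden-layer sizes to evaluate.
#' @param scales Clinical scales evaluated jointly (default both FMA
#'   subscores).
#' @param r_threshold Selection threshold on r (default 0.9).
#' @return A `semg_sweep` with the r table and the `selected` size.
#' @export
hidden_node_search <- function(features, scores,
                               grid = c(10, 15, 20, 30, 40, 50, 100, 150, 200),
                               scales = c("FMA_SE", "FMA_WH"),
                               feature_set = c("MAV", "ZC", "SSC", "RMS", "WL"),
                               channels = NULL, n_folds = 5, seed = 1L,
                               r_threshold = 0.9, config = bpnn_config()) {
  if (!length(grid)) abort_semg("`grid` must be non-empty.", "parameter")
  tab <- purrr::map_dfr(grid, function(h) {
    purrr::map_dfr(scales, function(sc) {
      cv <- run_cv(features, scores, sc, feature_set = feature_set,
                   channels = channels, n_hidden = h, n_folds = n_folds,
                   seed = seed, config = config)
      tibble::tibble(n_hidden = h, scale = sc, r = cv$r, p = cv$p)
    })
  })
  wide <- tidyr::pivot_wider(tab, id_cols = "n_hidden", names_from = "scale",
                             values_from = "r")
  rmat <- as.matrix(wide[setdiff(names(wide), "n_hidden")])
  ok <- apply(rmat, 1, function(z) all(z > r_threshold))
  selected <- if (any(ok)) min(wide$n_hidden[ok]) else
    wide$n_hidden[order(-rowMeans(rmat), wide$n_hidden)][1]
  new_semg_sweep("hidden_node_search", tab, selected)
}

#' The feature-combination grid
#'
#' The 26 evaluated input sets: each single feature, and every combination
#' holding at least one magnitude feature (MAV, RMS, WL) and one firing
#' feature (ZC, SSC), up to the full five-feature set.
#'
#' @return List of 26 character vectors in canonical feature order.
#' @export
semg_feature_combinations <- function() {
  singles <- as.list(SEMG_FEATURES)
  grp1 <- c("MAV", "RMS", "WL")
  grp2 <- c("ZC", "SSC")
  mixed <- list()
  for (k1 in 1:3) for (k2 in 1:2) {
    for (a in utils::combn(grp1, k1, simplify = FALSE))
      for (b in utils::combn(grp2, k2, simplify = FALSE)) {
        combo <- canonical_features(c(a, b))
        if (length(combo) < 5) mixed[[length(mixed) + 1]] <- combo
      }
  }
  c(singles, mixed, list(SEMG_FEATURES))
}

#' Feature-combination search
#'
#' Cross-validates every input set from [semg_feature_combinations()] against
#' each scale and selects the combination with the best mean r over the
#' scales (ties resolved toward fewer features).
#'
#' @inheritParams run_cv
#' @param scales Clinical scales evaluated jointly.
#' @param combinations List of feature sets (default the 26-set grid).
#' @return A `semg_sweep`; `selected` is the winning combination label.
#' @export
feature_combination_search <- function(features, scores,
                                       scales = c("FMA_SE", "FMA_WH"),
                                       combinations = semg_feature_combinations(),
                                       channels = NULL, n_hidden = 15,
                                       n_folds = 5, seed = 1L,
                                       config = bpnn_config()) {
  tab <- purrr::map_dfr(combinations, function(fs) {
    fs <- canonical_features(fs)
    label <- paste(fs, collapse = "+")
    purrr::map_dfr(scales, function(sc) {
      cv <- run_cv(features, scores, sc, feature_set = fs, channels = channels,
                   n_hidden = n_hidden, n_folds = n_folds, seed = seed,
                   config = config)
      tibble::tibble(combination = label, n_features = length(fs),
                     scale = sc, r = cv$r, p = cv$p)
    })
  })
  best <- tab |>
    dplyr::group_by(.data$combination, .data$n_features) |>
    dplyr::summarise(mean_r = mean(.data$r), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_r), .data$n_features)
  new_semg_sweep("feature_combination_search", tab, best$combination[1])
}

#' MAS low-pass cutoff-frequency sweep
#'
#' Re-runs preprocessing with an additional 4th-order zero-phase low-pass at
#' each cutoff and cross-validates the mapping to a MAS joint. Slow
#' involuntary contracture activity of a spastic muscle concentrates at low
#' frequencies, so restricting the band changes how visible that activity is
#' to the features. A cutoff at or above Nyquist is applied as a no-op and
#' flagged in the table.
#'
#' @inheritParams run_cv
#' @param trials List of [semg_trial()] objects (raw; re-filtered per cutoff).
#' @param cutoffs Low-pass cutoffs in Hz (default 80, 150, 200, 300, 400, 500).
#' @param joint MAS scale mapped (default `"MAS_elbow"`).
#' @param filter Base [filter_spec()] applied before the extra low-pass.
#' @return A `semg_sweep` with the per-cutoff r table and the argmax cutoff.
#' @export
mas_cutoff_sweep <- function(trials, scores,
                             cutoffs = c(80, 150, 200, 300, 400, 500),
                             joint = "MAS_elbow",
                             feature_set = c("MAV", "SSC", "RMS", "ZC"),
                             channels = NULL, n_hidden = 15, n_folds = 5,
                             seed = 1L, filter = filter_spec(),
                             config = bpnn_config()) {
  if (!length(cutoffs)) abort_semg("`cutoffs` must be non-empty.", "parameter")
  fs_hz <- trials[[1]]$sampling_rate
  tab <- purrr::map_dfr(cutoffs, function(co) {
    applied <- co < fs_hz / 2
    feats <- extract_features(trials, features = feature_set,
                              channels = channels, filter = filter,
                              extra_lowpass_hz = if (applied) co else NULL)
    cv <- run_cv(feats, scores, joint, feature_set = feature_set,
                 channels = channels, n_hidden = n_hidden, n_folds = n_folds,
                 seed = seed, config = config)
    tibble::tibble(cutoff_hz = co, r = cv$r, p = cv$p,
                   lowpass_applied = applied)
  })
  new_semg_sweep("mas_cutoff_sweep", tab,
                 tab$cutoff_hz[which.max(tab$r)], list(joint = joint))
}

#' Training-proportion sweep (internal generalization)
#'
#' Evaluates the mapping when a given fraction of each trial's epochs trains
#' the model and the complement tests it. The canonical 80% fraction routes
#' through the standard 5-fold protocol; other fractions average `n_reps`
#' seeded epoch-level splits.
#'
#' @inheritParams run_cv
#' @param fractions Training fractions in (0, 1).
#' @param n_reps Repeated splits averaged per non-0.8 fraction (default 5).
#' @param session Optional session filter (e.g. `"post"` for the
#'   post-intervention internal-generalization protocol).
#' @return A `semg_sweep` with one row per fraction.
#' @export
proportion_sweep <- function(features, scores, scale,
                             fractions = c(0.5, 0.6, 0.7, 0.8, 0.9),
                             n_reps = 5, session = NULL,
                             feature_set = c("MAV", "SSC", "RMS", "ZC"),
                             channels = NULL, n_hidden = 15, seed = 1L,
                             config = bpnn_config()) {
  if (any(fractions <= 0 | fractions >= 1))
    abort_semg("training fractions must lie strictly inside (0, 1).", "parameter")
  if (!is.null(session)) features <- features[features$session == session, ]
  sel <- cv_feature_columns(features, feature_set, channels)
  df <- epoch_targets(features, scores, scale)
  key <- paste(df$participant_id, df$session, df$trial_index, sep = "\r")
  tab <- purrr::map_dfr(fractions, function(f) {
    if (isTRUE(all.equal(f, 0.8))) {
      cv <- run_cv(features, scores, scale, feature_set = feature_set,
                   channels = channels, n_hidden = n_hidden, n_folds = 5,
                   seed = seed, config = config)
      return(tibble::tibble(fraction = f, r = cv$r, p = cv$p, n_reps = 5L))
    }
    rs <- vapply(seq_len(n_reps), function(rep) {
      split <- with_local_seed(seed + rep - 1L, {
        train_rows <- logical(nrow(df))
        for (k in unique(key)) {
          rows <- which(key == k)
          n_train <- max(1L, min(length(rows) - 1L, round(f * length(rows))))
          train_rows[sample(rows, n_train)] <- TRUE
        }
        train_rows
      })
      cfg <- config
      cfg$seed <- seed + rep - 1L
      model <- bpnn_train(as.matrix(df[split, sel$cols]), df$.target[split],
                          n_hidden = n_hidden, target_range = scale,
                          config = cfg)
      test <- df[!split, ]
      test$.pred <- predict(model, as.matrix(test[sel$cols]))
      per_ps <- participant_level(test)
      mapped_pearson(per_ps$mapped, per_ps$manual)$r
    }, numeric(1))
    r_mean <- mean(rs)
    n_pts <- length(unique(paste(df$participant_id, df$session)))
    t_stat <- r_mean * sqrt((n_pts - 2) / max(1 - r_mean^2, 1e-15))
    tibble::tibble(fraction = f, r = r_mean,
                   p = 2 * stats::pt(-abs(t_stat), df = n_pts - 2),
                   n_reps = as.integer(n_reps))
  })
  new_semg_sweep("proportion_sweep", tab, tab$fraction[which.max(tab$r)])
}

#' Muscle-subset mapping run
#'
#' Retrains the mapping using only a muscle subset: the proximal pair
#' (BIC, TRI) for FMA-SE, the distal pair (ED, FD) for FMA-WH, or all four
#' channels for any scale. With two channels and four features the input
#' layer has eight nodes.
#'
#' @inheritParams run_cv
#' @param subset Channel subset, e.g. `c("BIC", "TRI")`.
#' @return A `semg_cv` object for the subset run.
#' @export
muscle_subset_run <- function(features, scores, subset, scale,
                              feature_set = c("MAV", "SSC", "RMS", "ZC"),
                              n_hidden = 15, n_folds = 5, seed = 1L,
                              config = bpnn_config()) {
  subset <- canonical_channels(subset)
  valid <- (setequal(subset, c("BIC", "TRI")) && scale == "FMA_SE") ||
    (setequal(subset, c("ED", "FD")) && scale == "FMA_WH") ||
    setequal(subset, SEMG_CHANNELS)
  if (!valid)
    abort_semg(paste0("subset {", paste(subset, collapse = ","),
                      "} is not paired with scale ", scale,
                      " (BIC,TRI -> FMA_SE; ED,FD -> FMA_WH; or all four)."),
               "configuration")
  run_cv(features, scores, scale, feature_set = feature_set,
         channels = subset, n_hidden = n_hidden, n_folds = n_folds,
         seed = seed, config = config)
}
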