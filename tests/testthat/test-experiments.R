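test_that("MAS grades encode numerically with 1+ as 1.4", {
  expect_equal(encode_mas("1+"), 1.4)
  expect_equal(encode_mas(c("0", "1", "2", "3", "4")), c(0, 1, 2, 3, 4))
  expect_error(encode_mas("5"), class = "semgmap_value_error")
  expect_error(encode_mas("1plus"), class = "semgmap_value_error")
})

test_that("pearson matches the product-moment formula and flags constants", {
  expect_equal(pearson(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson(c(1, 2, 3), c(6, 4, 2))$r, -1)
  res <- pearson(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$r, 0.8)
  expect_equal(res$df, 2)
  # naive two-pass formula oracle on random vectors
  withr::with_seed(6, {
    for (i in 1:20) {
      x <- rnorm(15); y <- rnorm(15)
      num <- sum((x - mean(x)) * (y - mean(y)))
      den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      expect_equal(pearson(x, y)$r, num / den, tolerance = 1e-12)
      # p agrees with the exact t transform used by cor.test
      expect_equal(pearson(x, y)$p, stats::cor.test(x, y)$p.value,
                   tolerance = 1e-12)
    }
  })
  expect_error(pearson(rep(1, 5), 1:5), class = "semgmap_undefined_correlation_error")
  expect_error(pearson(1:2, 1:2), class = "semgmap_sample_size_error")
})

test_that("fold assignment is balanced, exhaustive, disjoint, deterministic", {
  feats <- tibble::tibble(participant_id = "P01", session = "pre",
                          trial_index = 1L, v = rnorm(49))
  f1 <- make_folds(feats, n_folds = 5, seed = 3)
  expect_equal(sort(as.integer(table(f1$fold)), decreasing = TRUE),
               c(10L, 10L, 10L, 10L, 9L))
  expect_equal(as.integer(table(f1$fold))[5], 9L)  # larger blocks first
  # determinism
  f2 <- make_folds(feats, n_folds = 5, seed = 3)
  expect_identical(f1$fold, f2$fold)
  expect_false(identical(f1$fold, make_folds(feats, n_folds = 5, seed = 4)$fold))
  # every epoch in exactly one test fold, per trial
  multi <- small_features()
  mf <- make_folds(multi, n_folds = 5, seed = 1)
  counts <- dplyr::count(mf, .data$participant_id, .data$session,
                         .data$trial_index, .data$fold)
  spread <- dplyr::summarise(
    dplyr::group_by(counts, .data$participant_id, .data$session, .data$trial_index),
    d = max(.data$n) - min(.data$n), k = dplyr::n(), .groups = "drop")
  expect_true(all(spread$d <= 1))
  expect_true(all(spread$k == 5))
  # undersized trial is named in the error
  tiny <- tibble::tibble(participant_id = "P09", session = "pre",
                         trial_index = 2L, v = rnorm(3))
  expect_error(make_folds(tiny, n_folds = 5), "P09",
               class = "semgmap_split_error")
})

test_that("run_cv recovers a noiseless monotone feature-score link", {
  withr::with_seed(25, {
    ids <- sprintf("S%02d", 1:10)
    u <- seq(0.2, 0.9, length.out = 10)
    feats <- purrr::map_dfr(seq_along(ids), function(i) {
      tibble::tibble(participant_id = ids[i], session = "pre", trial_index = 1L,
                     segment = 1L, start_sample = 0:19 * 200L,
                     ED_MAV = u[i] + rnorm(20, sd = 0.01),
                     ED_RMS = 2 * u[i] + rnorm(20, sd = 0.01),
                     ED_ZC = rnorm(20), ED_SSC = rnorm(20))
    })
    scores <- tibble::tibble(participant_id = ids, session = "pre",
                             FMA_SE = round(42 * (1 - u)))
    cv <- run_cv(feats, scores, "FMA_SE", n_hidden = 5, seed = 2,
                 config = fast_config())
    expect_gt(cv$r, 0.99)
    expect_lt(cv$p, 0.001)
    expect_equal(nrow(cv$per_fold), 5)
    expect_equal(nrow(cv$pooled), 10)
    expect_true(all(cv$pooled$mapped >= 0 & cv$pooled$mapped <= 42))
    # same seed reproduces the result exactly
    cv2 <- run_cv(feats, scores, "FMA_SE", n_hidden = 5, seed = 2,
                  config = fast_config())
    expect_identical(cv$r, cv2$r)
    # constant manual scores are rejected
    scores$FMA_SE <- 20L
    expect_error(run_cv(feats, scores, "FMA_SE", config = fast_config()),
                 class = "semgmap_undefined_correlation_error")
  })
})

test_that("feature combination grid enumerates the 26 candidate input sets", {
  combos <- semg_feature_combinations()
  expect_length(combos, 26)
  labels <- vapply(combos, paste, character(1), collapse = "+")
  expect_false(anyDuplicated(labels) > 0)
  expect_true("MAV+ZC+SSC+RMS" %in% labels)   # the selected combination
  expect_true("MAV+ZC+SSC+RMS+WL" %in% labels)
  expect_equal(sum(vapply(combos, length, integer(1)) == 1), 5)
  # every non-single has at least one magnitude and one firing feature
  multi <- combos[vapply(combos, length, integer(1)) > 1]
  expect_true(all(vapply(multi, function(fs)
    any(fs %in% c("MAV", "RMS", "WL")) && any(fs %in% c("ZC", "SSC")),
    logical(1))))
})

test_that("grid searches run and select sensibly on a small cohort", {
  feats <- small_features()
  scores <- small_cohort()$scores
  hs <- hidden_node_search(feats, scores, grid = c(4, 8), seed = 1,
                           config = fast_config())
  expect_equal(nrow(hs$table), 4)  # 2 grid points x 2 scales
  expect_true(hs$selected %in% c(4, 8))
  expect_s3_class(tidy(hs), "tbl_df")
  # trivial single-point grid selects itself
  hs1 <- hidden_node_search(feats, scores, grid = 15,
                            scales = "FMA_SE", seed = 1, config = fast_config())
  expect_equal(hs1$selected, 15)
  expect_error(hidden_node_search(feats, scores, grid = numeric(0)),
               class = "semgmap_parameter_error")
})

test_that("proportion sweep validates fractions and covers the grid", {
  feats <- small_features()
  scores <- small_cohort()$scores
  ps <- proportion_sweep(feats, scores, "FMA_SE", fractions = c(0.5, 0.8),
                         n_reps = 2, session = "post", n_hidden = 5,
                         seed = 1, config = fast_config())
  expect_equal(ps$table$fraction, c(0.5, 0.8))
  expect_true(all(is.finite(ps$table$r)))
  expect_error(proportion_sweep(feats, scores, "FMA_SE", fractions = 1),
               class = "semgmap_parameter_error")
})

test_that("muscle subsets are validated against their paired scale", {
  feats <- small_features()
  scores <- small_cohort()$scores
  expect_error(muscle_subset_run(feats, scores, c("BIC", "TRI"), "FMA_WH"),
               class = "semgmap_configuration_error")
  sub <- muscle_subset_run(feats, scores, c("BIC", "TRI"), "FMA_SE",
                           n_hidden = 5, seed = 1, config = fast_config())
  expect_equal(sub$channels, c("BIC", "TRI"))
  # 2 channels x 4 features = 8 input nodes
  expect_length(semgmap:::feature_column_names(sub$channels, sub$feature_set), 8)
})

test_that("clinical scale comparison uses the right paired tests", {
  ids <- sprintf("P%02d", 1:8)
  withr::with_seed(30, {
    scores <- tibble::tibble(
      participant_id = rep(ids, 2),
      session = rep(c("pre", "post"), each = 8),
      FMA_SE = c(sample(10:25, 8), sample(26:40, 8)),
      FMA_WH = c(sample(4:10, 8, replace = TRUE), sample(12:20, 8)),
      MAS_elbow = c(rep("2", 8), rep("1", 8)),
      MAS_wrist = c(rep("1+", 8), rep("1", 8)),
      MAS_finger = rep("2", 16)   # all tied
    )
  })
  expect_warning(cmp <- compare_clinical_sessions(scores), "tied")
  fma <- cmp[cmp$scale == "FMA_SE", ]
  expect_equal(fma$test, "paired t")
  expect_lt(fma$p_value, 0.05)
  expect_gt(fma$mean_post, fma$mean_pre)
  mas <- cmp[cmp$scale == "MAS_elbow", ]
  expect_equal(mas$test, "wilcoxon signed-rank")
  expect_lt(mas$p_value, 0.05)
  expect_lt(mas$mean_post, mas$mean_pre)
  expect_equal(cmp$mean_pre[cmp$scale == "MAS_wrist"], 1.4)
  expect_true(is.na(cmp$p_value[cmp$scale == "MAS_finger"]))
  # identical sessions: nothing significant
  same <- scores
  same[same$session == "post", c("FMA_SE", "FMA_WH")] <-
    same[same$session == "pre", c("FMA_SE", "FMA_WH")]
  same$MAS_elbow <- "1"; same$MAS_wrist <- "1"; same$MAS_finger <- "1"
  suppressWarnings(cmp0 <- compare_clinical_sessions(same))
  expect_true(all(cmp0$p_value[cmp0$scale %in% c("FMA_SE", "FMA_WH")] == 1))
})
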