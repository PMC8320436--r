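test_that("score assignment respects the latent boundaries and directions", {
  spec <- cohort_spec()
  lo <- assign_scores(0, spec = spec, jitter = FALSE)
  expect_equal(lo$FMA_SE, 42L)
  expect_equal(lo$FMA_WH, 24L)
  expect_equal(lo$MAS_elbow, "0")
  hi <- assign_scores(1, spec = spec, jitter = FALSE)
  expect_equal(hi$FMA_SE, 0L)
  expect_equal(hi$MAS_elbow, "3")
  expect_equal(hi$MAS_finger, "3")
  # cohort defaults: FMA improves after the intervention
  coh <- small_cohort()
  agg <- dplyr::summarise(dplyr::group_by(coh$scores, .data$session),
                          fma = mean(.data$FMA_SE + .data$FMA_WH))
  expect_gt(agg$fma[agg$session == "post"], agg$fma[agg$session == "pre"])
  # all scores inside their scales, MAS capped at 3
  expect_true(all(coh$scores$FMA_SE >= 0 & coh$scores$FMA_SE <= 42))
  expect_true(all(coh$scores$FMA_WH >= 0 & coh$scores$FMA_WH <= 24))
  expect_true(all(encode_mas(coh$scores$MAS_elbow) <= 3))
})

test_that("signal amplitude scales with the generator couplings", {
  base <- cohort_spec(trial_duration_s = 6, seed = 5, max_pauses = 0)
  sc <- assign_scores(0.5, spec = base, jitter = FALSE)
  sc$MAS_elbow <- "0"; sc$MAS_wrist <- "0"; sc$MAS_finger <- "0"
  t1 <- withr::with_seed(100, synth_trial("P01", "pre", 1, 0.5, sc, base))
  dbl <- base
  dbl$base_amplitude_mv <- 2 * base$base_amplitude_mv
  t2 <- withr::with_seed(100, synth_trial("P01", "pre", 1, 0.5, sc, dbl))
  ratio <- rms(as.vector(t2$signal)) / rms(as.vector(t1$signal))
  expect_lt(abs(ratio - 2), 0.1)
  # zero couplings leave pure sensor noise
  off <- base
  off$base_amplitude_mv <- 0
  t0 <- withr::with_seed(100, synth_trial("P01", "pre", 1, 0.5, sc, off))
  expect_lt(abs(rms(as.vector(t0$signal)) / off$sensor_noise_mv - 1), 0.05)
})

test_that("high MAS concentrates signal power below 200 Hz", {
  spec <- cohort_spec(trial_duration_s = 6, seed = 5, max_pauses = 0)
  low_frac <- function(mas) {
    sc <- assign_scores(0.5, spec = spec, jitter = FALSE)
    sc$MAS_elbow <- mas
    trial <- withr::with_seed(200, synth_trial("P01", "pre", 1, 0.5, sc, spec))
    x <- trial$signal[, "BIC"]
    spec_est <- stats::spec.pgram(x, spans = 31, plot = FALSE)
    f_hz <- spec_est$freq * spec$fs
    sum(spec_est$spec[f_hz < 200]) / sum(spec_est$spec)
  }
  expect_gt(low_frac("3"), low_frac("0") + 0.1)
})

test_that("cohort generation is reproducible and round-trips through disk", {
  spec <- cohort_spec(n_participants = 2, trials_per_session = 2,
                      trial_duration_s = 4, seed = 77)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  coh1 <- generate_cohort(spec, dir = dir1)
  coh2 <- generate_cohort(spec, dir = dir2)
  expect_length(coh1$trials, 2 * 2 * 2)
  expect_equal(nrow(coh1$scores), 4)
  # same seed -> byte-identical files
  f1 <- list.files(dir1, full.names = TRUE)
  f2 <- list.files(dir2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  for (k in seq_along(f1))
    expect_identical(readLines(f1[k]), readLines(f2[k]))
  # every generated trial reads back cleanly
  csvs <- grep("_t\\d+\\.csv$", f1, value = TRUE)
  for (csv in csvs) {
    trial <- read_trial(csv, sub("\\.csv$", ".json", csv))
    expect_s3_class(trial, "semg_trial")
    expect_equal(trial$channels, c("ED", "FD", "BIC", "TRI"))
  }
  # manifest carries the latent truth
  expect_true(all(c("u", "gain") %in% names(coh1$manifest)))
  expect_equal(nrow(coh1$manifest), 4)
})

test_that("impairment couples monotonically to features and co-contraction", {
  coh <- small_cohort()
  feats <- small_features()
  params <- cached("small_params", semg_parameters(coh$trials))
  by_ps <- dplyr::summarise(
    dplyr::group_by(feats, .data$participant_id, .data$session),
    mav = mean(.data$BIC_MAV + .data$FD_MAV + .data$ED_MAV + .data$TRI_MAV),
    .groups = "drop")
  merged <- dplyr::inner_join(by_ps, coh$manifest,
                              by = c("participant_id", "session"))
  merged <- dplyr::inner_join(merged, coh$scores,
                              by = c("participant_id", "session"))
  # worse impairment -> more pathological activation -> lower FMA
  expect_lt(stats::cor(merged$mav, merged$FMA_SE), -0.5)
  pj <- dplyr::inner_join(params, coh$manifest,
                          by = c("participant_id", "session"))
  expect_gt(stats::cor(pj$CI_BIC_TRI, pj$u), 0.5)
})
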