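# shared fixtures; heavy objects are built once per test run and cached
.semg_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .semg_cache, inherits = FALSE))
    assign(name, expr, envir = .semg_cache)
  get(name, envir = .semg_cache, inherits = FALSE)
}

# a small but complete cohort used by most integration tests:
# 8 participants x 2 sessions x 2 trials x 10 s
small_spec <- function(seed = 11L) {
  cohort_spec(n_participants = 8, trials_per_session = 2,
              trial_duration_s = 10, seed = seed)
}

small_cohort <- function() cached("small_cohort", generate_cohort(small_spec()))

small_features <- function() cached("small_features", {
  extract_features(small_cohort()$trials)
})

fast_config <- function(seed = 1L) bpnn_config(max_iter = 30, seed = seed)

# a single flat trial built from an explicit matrix
make_trial <- function(signal, fs = 1000, pauses = list(), session = "pre",
                       channels = NULL) {
  signal <- if (is.null(dim(signal))) matrix(signal, ncol = 1) else signal
  channels <- channels %||% c("ED", "FD", "BIC", "TRI")[seq_len(ncol(signal))]
  semg_trial(signal, channels = channels, sampling_rate = fs,
             session = session, pauses = pauses)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# naive loop oracles for the five time-domain features
oracle_mav <- function(x) { s <- 0; for (v in x) s <- s + abs(v); s / length(x) }
oracle_rms <- function(x) { s <- 0; for (v in x) s <- s + v^2; sqrt(s / length(x)) }
oracle_zc <- function(x, dead = 0) {
  n <- 0
  for (t in seq_len(length(x) - 1))
    if (x[t] * x[t + 1] < 0 && abs(x[t] - x[t + 1]) >= dead) n <- n + 1
  n
}
oracle_ssc <- function(x, dead = 0) {
  n <- 0
  for (t in 2:(length(x) - 1)) {
    d1 <- x[t] - x[t - 1]
    d2 <- x[t] - x[t + 1]
    if (d1 * d2 > 0 && abs(d1) >= dead && abs(d2) >= dead) n <- n + 1
  }
  n
}
oracle_wl <- function(x) {
  s <- 0
  for (t in seq_len(length(x) - 1)) s <- s + abs(x[t + 1] - x[t])
  s / length(x)
}

# synthetic feature table with no signal-score link, for null calibration
null_feature_table <- function(n_participants = 15, n_epochs = 15, seed = 1) {
  withr::with_seed(seed, {
    ids <- sprintf("N%02d", seq_len(n_participants))
    feats <- purrr::map_dfr(ids, function(id) {
      tibble::tibble(participant_id = id, session = "pre", trial_index = 1L,
                     segment = 1L,
                     start_sample = seq_len(n_epochs) * 200L - 200L,
                     ED_MAV = rnorm(n_epochs), ED_RMS = rnorm(n_epochs),
                     ED_ZC = rnorm(n_epochs), ED_SSC = rnorm(n_epochs))
    })
    scores <- tibble::tibble(participant_id = ids, session = "pre",
                             FMA_SE = sample(5:40, n_participants, replace = TRUE))
    list(features = feats, scores = scores)
  })
}

# full-size study cohort (the generator defaults) shared by the acceptance
# tests; built once per test run
study_cohort <- function() cached("study_cohort", generate_cohort(cohort_spec()))

study_features <- function() cached("study_features", {
  extract_features(study_cohort()$trials,
                   features = c("MAV", "SSC", "RMS", "ZC"))
})

# training budget used for the evaluation protocols in tests
eval_config <- function(seed = 1L) bpnn_config(max_iter = 40, seed = seed)

study_cv <- function(scale) {
  cached(paste0("study_cv_", scale),
         run_cv(study_features(), study_cohort()$scores, scale,
                n_hidden = 15, seed = 1, config = eval_config()))
}
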