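#' Specification of a synthetic stroke cohort
#'
#' Defines the study conditions emulated by the generator: 29 participants
#' assessed pre and post a rehabilitation intervention, three reaching-task
#' trials per session, four sEMG channels at 1000 Hz. A single latent
#' impairment `u` in `[0, 1]` per participant-session drives everything:
#' clinical scores decrease in `u` (FMA) or increase (MAS), and the signal
#' model couples `u` to amplitude, tonic (continuous) activity, antagonist
#' co-contraction and low-frequency involuntary activity. The intervention
#' improves `u` by a random decrement.
#'
#' Moderate-to-severe impairment at recruitment constrains the pre-session
#' latent range (total FMA between about 15 and 45), and MAS grades never
#' exceed 3.
#'
#' @param n_participants Cohort size (default 29).
#' @param trials_per_session Trials per assessment session (default 3).
#' @param trial_duration_s Trial length in seconds (default 30).
#' @param fs Sampling rate in Hz (default 1000).
#' @param seed Master RNG seed for the whole cohort.
#' @param u_pre_mean,u_pre_sd,u_pre_range Pre-intervention latent impairment:
#'   normal with this mean/SD, clipped to the recruitment range.
#' @param improvement_mean,improvement_sd Latent improvement `delta >= 0`
#'   (normal, clipped at 0); `u_post = max(0, u_pre - delta)`.
#' @param score_noise SD of the per-scale score-assignment jitter on the
#'   latent scale (default 0.03).
#' @param semg_band Main voluntary sEMG energy band in Hz (default 20-350).
#' @param spastic_band Involuntary low-frequency activity band in Hz
#'   (default 5-150).
#' @param base_amplitude_mv Voluntary-burst amplitude scale in mV at maximal
#'   impairment coupling (default 0.5).
#' @param spastic_gain Amplitude of the involuntary component at MAS 3,
#'   relative to `base_amplitude_mv` (default 0.6).
#' @param sensor_noise_mv White sensor-noise SD in mV (default 0.01).
#' @param gain_sd SD of the log-normal per-participant-session electrode gain
#'   (default 0.08).
#' @param burst_period_s Reach-withdraw movement cycle length in seconds
#'   (default 4).
#' @param max_pauses Maximum number of operator-marked pauses per trial
#'   (default 2).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 29, trials_per_session = 3,
                        trial_duration_s = 30, fs = 1000, seed = 42L,
                        u_pre_mean = 0.58, u_pre_sd = 0.09,
                        u_pre_range = c(0.30, 0.80),
                        improvement_mean = 0.175, improvement_sd = 0.06,
                        score_noise = 0.03,
                        semg_band = c(20, 350), spastic_band = c(5, 150),
                        base_amplitude_mv = 0.5, spastic_gain = 0.6,
                        sensor_noise_mv = 0.01, gain_sd = 0.08,
                        burst_period_s = 4, max_pauses = 2) {
  stopifnot(n_participants >= 1, trials_per_session >= 1, fs > 0,
            trial_duration_s * fs >= 400,
            semg_band[1] > 0, semg_band[2] < fs / 2,
            spastic_band[1] > 0, spastic_band[2] < fs / 2)
  structure(as.list(environment()), class = "cohort_spec")
}

# latent-to-signal couplings; all monotone increasing in impairment u
tonic_level <- function(u) pmin(pmax(1.3 * u - 0.15, 0.05), 0.95)
cocontraction_level <- function(u) pmin(pmax(0.2 + 0.6 * u, 0), 0.9)
amplitude_factor <- function(u) 0.3 + 0.7 * u

# MAS thresholds on the jittered latent; grades capped at 3 (recruitment)
mas_from_latent <- function(v) {
  cut_pts <- c(0.18, 0.34, 0.48, 0.64)
  grades <- c("0", "1", "1+", "2", "3")
  grades[findInterval(v, cut_pts) + 1]
}

#' Assign clinical scores from a latent impairment
#'
#' FMA subscores decrease linearly in `u` (42 and 24 points at `u = 0`) with
#' rounding and per-scale jitter; MAS grades threshold the jittered latent
#' onto `{0, 1, 1+, 2, 3}` per joint. With `jitter = FALSE` the mapping is
#' deterministic: `u = 0` gives full FMA and MAS 0, `u = 1` gives the minimal
#' FMA and MAS 3.
#'
#' @param u Latent impairment in `[0, 1]` (vectorized).
#' @param session `"pre"` or `"post"` (recorded in the output).
#' @param spec A [cohort_spec()] (controls the jitter SD).
#' @param jitter Add score-assignment noise? (default `TRUE`; uses the
#'   caller's RNG stream).
#' @return Tibble with `session`, `FMA_SE`, `FMA_WH`, `MAS_elbow`,
#'   `MAS_wrist`, `MAS_finger` (MAS as grade strings) and the latent `u`.
#' @export
assign_scores <- function(u, session = "pre", spec = cohort_spec(),
                          jitter = TRUE) {
  u <- pmin(pmax(u, 0), 1)
  n <- length(u)
  jit <- function() if (jitter) stats::rnorm(n, 0, spec$score_noise) else 0
  fma_se <- round(pmin(pmax(42 * (1 - u + jit()), 0), 42))
  fma_wh <- round(pmin(pmax(24 * (1 - u + jit()), 0), 24))
  tibble::tibble(
    session = session,
    FMA_SE = as.integer(fma_se), FMA_WH = as.integer(fma_wh),
    MAS_elbow = mas_from_latent(u + jit()),
    MAS_wrist = mas_from_latent(u + jit()),
    MAS_finger = mas_from_latent(u + jit()),
    u = u
  )
}

band_noise <- function(n, band, fs) {
  b <- signal::butter(4, band / (fs / 2), type = "pass")
  x <- zero_phase_filter(b$b, b$a, stats::rnorm(n))
  drop(x) / stats::sd(x)
}

# Hann burst trains for the two movement phases of each cycle
burst_trains <- function(n, fs, period_s) {
  t <- (seq_len(n) - 1) / fs
  phase <- (t %% period_s) / period_s          # 0..1 within cycle
  bA <- ifelse(phase < 0.5, 0.5 - 0.5 * cos(2 * pi * phase / 0.5), 0)
  bB <- ifelse(phase >= 0.5, 0.5 - 0.5 * cos(2 * pi * (phase - 0.5) / 0.5), 0)
  list(A = bA, B = bB)
}

#' Synthesize one task trial from scores-linked parameters
#'
#' Realizes the signal model: per channel `m`,
#' `x_m(t) = A_m(u) e_m(t) g_m(t) + s_m g_low(t) + sigma0 w(t)`, where
#' `g_m` is Gaussian noise band-limited to the voluntary band, `g_low` to the
#' low-frequency involuntary band (amplitude tied to the joint's MAS grade:
#' elbow for BIC/TRI, wrist+finger for ED/FD), `e_m` a task burst envelope
#' with tonic floor and antagonist overlap rising with impairment, and `w`
#' white sensor noise. Zero to `max_pauses` rest pauses are inserted and
#' recorded as pause intervals.
#'
#' @param participant_id,session,trial_index Identity of the trial.
#' @param u Latent impairment of this participant-session.
#' @param scores One row of [assign_scores()] output for this
#'   participant-session.
#' @param spec A [cohort_spec()].
#' @param gain Electrode gain multiplier (default 1).
#' @return A [semg_trial()] with channels ED, FD, BIC, TRI.
#' @export
synth_trial <- function(participant_id, session, trial_index, u, scores,
                        spec = cohort_spec(), gain = 1) {
  n <- as.integer(round(spec$trial_duration_s * spec$fs))
  if (n < 400)
    abort_semg("trial too short for a single analysis epoch.", "parameter")
  fs <- spec$fs
  tr <- burst_trains(n, fs, spec$burst_period_s)
  tau <- tonic_level(u)
  cc <- cocontraction_level(u)
  # pauses: rest intervals where the voluntary drive collapses
  n_pause <- sample.int(spec$max_pauses + 1L, 1) - 1L
  pauses <- list()
  if (n_pause > 0 && spec$trial_duration_s > 8) {
    anchors <- sort(stats::runif(n_pause, 1, spec$trial_duration_s - 3))
    last_end <- -Inf
    for (a in anchors) {
      len <- stats::runif(1, 0.5, 2)
      if (a > last_end) {
        pauses[[length(pauses) + 1]] <- c(a, a + len)
        last_end <- a + len
      }
    }
  }
  t0 <- (seq_len(n) - 1) / fs
  active <- rep(1, n)
  for (p in pauses) active[t0 >= p[1] & t0 < p[2]] <- 0
  mas_el <- encode_mas(scores$MAS_elbow)
  mas_df <- (encode_mas(scores$MAS_wrist) + encode_mas(scores$MAS_finger)) / 2
  agonist <- c(ED = "A", FD = "B", BIC = "B", TRI = "A")
  sig <- matrix(0, n, 4, dimnames = list(NULL, SEMG_CHANNELS))
  for (ch in SEMG_CHANNELS) {
    own <- if (agonist[[ch]] == "A") tr$A else tr$B
    other <- if (agonist[[ch]] == "A") tr$B else tr$A
    env <- (tau + (1 - tau) * (own + cc * other)) * active
    env[env < 0.02] <- 0.02
    A_m <- spec$base_amplitude_mv * gain * amplitude_factor(u)
    mas_m <- if (ch %in% c("BIC", "TRI")) mas_el else mas_df
    s_m <- spec$base_amplitude_mv * gain * spec$spastic_gain * (mas_m / 3)
    sig[, ch] <- A_m * env * band_noise(n, spec$semg_band, fs) +
      s_m * band_noise(n, spec$spastic_band, fs) +
      spec$sensor_noise_mv * stats::rnorm(n)
  }
  semg_trial(sig, channels = SEMG_CHANNELS, sampling_rate = fs,
             participant_id = participant_id, session = session,
             trial_index = trial_index, pauses = pauses,
             task_label = "vertical reach-grasp")
}

#' Generate a complete synthetic stroke cohort
#'
#' Draws the latent impairments, assigns pre/post clinical scores, and
#' synthesizes every trial. All randomness derives from `spec$seed`, so the
#' cohort (and any files written) is reproducible bit for bit.
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional output directory; when given, every trial is written
#'   as a `<id>_<session>_t<k>.csv` / `.json` pair plus `scores.csv` and a
#'   `manifest.json` holding the latent truth.
#' @return A list with `trials` (list of [semg_trial()]), `scores` (tibble,
#'   one row per participant-session) and `manifest` (tibble with the latent
#'   `u` and electrode gain per participant-session).
#' @export
generate_cohort <- function(spec = cohort_spec(), dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  out <- with_local_seed(spec$seed, {
    ids <- sprintf("P%02d", seq_len(spec$n_participants))
    u_pre <- pmin(pmax(stats::rnorm(spec$n_participants, spec$u_pre_mean,
                                    spec$u_pre_sd),
                       spec$u_pre_range[1]), spec$u_pre_range[2])
    delta <- pmax(stats::rnorm(spec$n_participants, spec$improvement_mean,
                               spec$improvement_sd), 0)
    u_post <- pmax(u_pre - delta, 0)
    trials <- list()
    scores <- list()
    manifest <- list()
    for (i in seq_along(ids)) {
      for (ses in c("pre", "post")) {
        u <- if (ses == "pre") u_pre[i] else u_post[i]
        sc <- assign_scores(u, session = ses, spec = spec)
        sc <- tibble::add_column(sc, participant_id = ids[i], .before = 1)
        gain <- exp(stats::rnorm(1, 0, spec$gain_sd))
        scores[[length(scores) + 1]] <- sc
        manifest[[length(manifest) + 1]] <-
          tibble::tibble(participant_id = ids[i], session = ses, u = u,
                         gain = gain)
        for (k in seq_len(spec$trials_per_session)) {
          trials[[length(trials) + 1]] <-
            synth_trial(ids[i], ses, k, u, sc, spec, gain)
        }
      }
    }
    list(trials = trials, scores = dplyr::bind_rows(scores),
         manifest = dplyr::bind_rows(manifest))
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (trial in out$trials) {
      stem <- sprintf("%s_%s_t%d", trial$participant_id, trial$session,
                      trial$trial_index)
      write_trial(trial, file.path(dir, paste0(stem, ".csv")),
                  file.path(dir, paste0(stem, ".json")))
    }
    utils::write.csv(out$scores[setdiff(names(out$scores), "u")],
                     file.path(dir, "scores.csv"), row.names = FALSE,
                     quote = FALSE)
    jsonlite::write_json(out$manifest, file.path(dir, "manifest.json"),
                         dataframe = "rows", digits = I(17), pretty = TRUE)
  }
  out
}
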