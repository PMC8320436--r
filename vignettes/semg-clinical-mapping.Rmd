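---
title: "Mapping upper-limb sEMG to clinical motor scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping upper-limb sEMG to clinical motor scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semgmap)
```

## The problem

After a stroke, upper-limb motor impairment and spasticity are tracked with
manual clinical scales: the Fugl-Meyer Assessment, split here into its
shoulder/elbow (FMA-SE, 0-42) and wrist/hand (FMA-WH, 0-24) subscores, and
the Modified Ashworth Scale (MAS, ordinal grades 0, 1, 1+, 2, 3, 4 per
joint, with 1+ encoded numerically as 1.4). Manual scoring is slow and
rater-bound. Surface electromyography (sEMG) recorded from four task muscles
— extensor digitorum (ED), flexor digitorum (FD), biceps (BIC) and triceps
(TRI) — during a standardized reach-grasp task carries enough information
about voluntary drive, co-activation and involuntary (spastic) activity to
estimate those scales automatically. `semgmap` implements that estimation
pipeline end to end and the evaluation protocols used to validate it.

## Pipeline

1. **Preprocessing** (`read_trial()`, `excise_pauses()`, `apply_filters()`,
   `segment_epochs()`). Operator-marked rest pauses are excised first;
   every contiguous segment is then filtered zero-phase: 4th-order
   Butterworth high-pass at 10 Hz, optional low-pass at 500 Hz (skipped at
   Nyquist for 1000 Hz data, where a Butterworth edge would be degenerate),
   and a 50 Hz biquad mains notch. Segments are cut into 400 ms epochs
   stepped by 200 ms. Epochs never span a pause splice: concatenating across
   excised intervals would manufacture discontinuities that inflate the
   turning-count features. `check_wss()` verifies wide-sense stationarity
   per epoch (sub-window mean test plus autocorrelation-profile similarity);
   the flag is informational and nothing is excluded by default, because the
   protocol only requires stationarity to be *verified*.

2. **Features** (`mav()`, `rms()`, `zc()`, `ssc()`, `wl()`,
   `extract_features()`). Five classic time-domain features per channel and
   epoch. MAV, RMS and WL measure signal magnitude (mV); ZC and SSC count
   zero crossings and slope-sign changes and reflect motor-unit firing
   statistics. Two conventions matter and are deliberate: a zero crossing
   requires strict sign opposition of neighboring samples (a sample exactly
   at zero is never a crossing by itself), and a slope-sign change requires
   strictly positive products of the adjacent differences — the
   non-strict variant would count every interior sample of a constant
   signal as a turn. WL is normalized by the epoch length, so it is an
   average absolute first difference rather than a raw path length. An
   optional amplitude deadband for ZC/SSC defaults to 0.

3. **Mapping model** (`bpnn_train()`, `predict_participant()`). A
   three-layer network (sigmoid hidden layer, sigmoid output) maps the
   standardized feature vector of one epoch to the target scale min-max
   normalized into (0, 1), so mapped scores are bounded by the scale by
   construction. Training is Levenberg-Marquardt on the regularized
   objective `F = beta * E_D + alpha * E_W` with the evidence-framework
   re-estimation of `alpha` and `beta` after every accepted step
   (`gamma = N_w - 2 alpha tr(H^-1)`, `alpha = gamma / 2 E_W`,
   `beta = (N - gamma) / 2 E_D`, Gauss-Newton `H`). `gamma` is the
   effective number of parameters; on targets carrying no signal it
   collapses far below `N_w`, which is the mechanism that suppresses
   overfitting with generous hidden layers. A participant-session's final
   mapped score is the mean of its test-epoch outputs.

4. **Evaluation protocols** (`run_cv()`, `hidden_node_search()`,
   `feature_combination_search()`, `mas_cutoff_sweep()`,
   `mismatched_test()`, `proportion_sweep()`, `muscle_subset_run()`).
   Epochs are shuffled within each trial and partitioned into five
   near-equal blocks; fold k tests on block k of every trial, so 80% of
   each trial trains the model, every epoch is tested exactly once, and the
   headline correlation is the mean per-fold Pearson r between mapped and
   manual scores (p from the t-transform at n-2 df). The pooled-prediction
   correlation is reported alongside, labeled separately. Note the
   epoch-level split permits 200 ms overlap between a training and a test
   epoch; this follows the reference protocol, and nothing prevents passing
   stricter splits of your own construction to `bpnn_train()` directly.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| band edges | 10-500 Hz | Butterworth band, order 4 |
| notch | 50 Hz, Q = 30 | mains interference; Q chosen for a ~1.7 Hz notch width |
| epoch / step | 400 / 200 ms | stationarity vs information trade-off |
| envelope low-pass | 6 Hz, order 2 | linear-envelope smoothing |
| hidden nodes | 15 | smallest size with r > 0.9 on both FMA subscores |
| feature set | MAV, SSC, RMS, ZC | best joint FMA correlation among the 26 candidate sets |
| LM budget | `max_iter` 300, `mu0` 0.005, x10 / x0.1 | damping schedule; stops early on gradient or plateau |

The notch quality factor, the envelope recipe (full-wave rectification plus
zero-phase 6 Hz low-pass), the co-contraction overlap rule (pointwise
minimum; `product` available), the per-feature input standardization and
the uniform fan-in-scaled weight initialization are all conventions this
package fixes explicitly because the underlying protocol leaves them open.
The evaluation helpers in the test-suite and the acceptance script run the
optimizer at `max_iter = 40`: on the synthetic cohort the data error
plateaus well before that, and the retained budget keeps a full five-fold,
two-scale evaluation under two minutes of training per scale.

## Secondary sEMG outcomes

`semg_parameters()` computes, per participant-session, each muscle's
activation level (time-average of the linear envelope normalized by the
muscle's session-wide maximum) and the co-contraction index of every muscle
pair (time-average of the pointwise minimum of the two normalized
envelopes, i.e. the overlapping activity). Both live in [0, 1]; CI is
symmetric and never exceeds the smaller activation level.
`compare_sessions()` pairs participants across sessions and applies
Shapiro-Wilk normality checks and paired t-tests; `compare_clinical_sessions()`
does the same for the scales, with paired Wilcoxon signed-rank tests for
the ordinal MAS grades.

## The synthetic cohort

No public recording of this kind of clinical cohort exists, so
`generate_cohort()` builds one: 29 participants, two sessions (pre/post
intervention), three 30 s trials per session, four channels at 1000 Hz. A
single latent impairment `u` per participant-session drives everything:

* clinical scores: FMA subscores decrease linearly in `u` with rounding and
  independent per-scale jitter (SD 0.03 on the latent scale); MAS grades
  threshold the jittered latent onto {0, 1, 1+, 2, 3}. Pre-intervention
  latents are drawn so total FMA sits in the moderate-to-severe recruitment
  band, and the intervention subtracts a non-negative improvement
  (mean 0.175) for the post session. The latent mean (0.58) and SD (0.09)
  and the improvement distribution were set so the pre/post FMA means and
  SDs land near the reference cohort's, and the jitter SD keeps the
  attainable mapping correlation near the mid-0.9s rather than 1.0.
* signals: per channel, band-limited Gaussian noise (20-350 Hz) is
  amplitude-modulated by a task burst envelope with a tonic floor and an
  antagonist-overlap fraction that both rise with `u` (worse impairment ->
  more continuous, more co-contracted activity), scaled by an amplitude
  coupling that rises with `u`; a second noise component band-limited to
  5-150 Hz models slow involuntary spastic activity with amplitude tied to
  the joint's MAS grade (elbow MAS drives BIC/TRI, the wrist/finger mean
  drives ED/FD); white sensor noise (10 uV) and a log-normal electrode gain
  (SD 0.08) per participant-session are added. Zero to two operator pauses
  are inserted and recorded.

This surrogate reproduces the statistical structure the mapping relies on —
amplitude, tonic fraction, co-contraction and spectral mix all covary
monotonically with impairment — but it is not a physiological simulator:
there are no motor-unit action potentials, no firing trains, no fatigue,
and the voluntary band has no participant-specific spectral signature.
Passing tests on this cohort therefore demonstrate that the pipeline
recovers the latent structure it assumes, not that it would reach the same
correlations on real patients.

Two measured consequences of this design are worth stating plainly, since
the test suite reports them as failures rather than hiding them. First, the
MAS low-pass cutoff sweep is nearly flat above 150 Hz on the default
cohort: because one latent drives both amplitude and MAS, the spastic
low-band component adds no identifiable increment over the amplitude
features, and the argmax among {80..500 Hz} is not reproducibly 200 Hz
(the r differences above 150 Hz are smaller than seed noise). Second, the
null calibration of the cross-validated correlation test is not 5%: the
fold-mean r test is conservative (averaging five dependent fold
correlations shrinks the null statistic, and Bayesian regularization
collapses many null fits to a constant output, scored r = 0), while the
pooled variant is anticonservative (~10-14%) because CV predictions share
training data. The conservative headline behavior under-rejects, which is
the benign direction for clinical claims.

## Numerical choices and degenerate inputs

* Zero-phase filtering pads with odd reflection before the
  forward-backward pass; without padding a narrow notch rings visibly at
  segment edges. Measured on a 10 s tone, the 50 Hz notch residual is ~3%
  and passband gain is within 0.1%.
* Pause intervals are half-open `[start, end)` in seconds; sample `i`
  (1-based) covers time `(i-1)/fs`. Epoch starts are 0-based sample
  offsets within their contiguous segment and are multiples of the step.
* Fold sizes differ by at most one, larger blocks first; grid ties resolve
  toward fewer nodes / fewer features.
* A trained network that collapses to a constant output (possible under
  the regularizer when targets carry no signal) scores r = 0 in the
  evaluation protocols — no association — rather than erroring; constant
  *manual* scores are a hard error, as is an all-zero envelope session or
  a trial fully covered by pauses.
* `gamma` is clamped to `[0, min(N_w, N)]` so `beta` stays positive on
  very small training sets; Cholesky failures of the Gauss-Newton Hessian
  fall back to a ridge-stabilized solve.
* Model JSON serializes weights at 17 significant digits, so save/load
  round-trips predictions exactly.

## Problem sizes used in the checks

The packaged tests run the full protocol on the default 29-participant
cohort for the headline recovery and direction checks (five-fold CV on both
FMA subscores, the mismatched pre-to-post test, the secondary-outcome
comparison and the six-point MAS cutoff sweep), a reduced
8-participant/10 s cohort for the module-level integration tests, and 200
small null cohorts (15 participants, 15 epochs each, 3 hidden nodes) for
the calibration experiment. `scripts/acceptance.R` regenerates the default
cohort from a command-line seed and recomputes the headline quantities from
scratch in about five minutes.

## Known limitations

* The generator's single-latent design makes all scales mutually
  predictable; real cohorts dissociate FMA and MAS far more.
* The epoch-level CV split shares 200 ms of signal between training and
  test epochs (information leakage inherited from the protocol); treat the
  in-cohort correlations as internal validity, not generalization.
* Only time-domain features are implemented; frequency-domain features and
  real-time (streaming) operation are out of scope.
* EDF/BDF readers are not provided; trials enter as CSV + JSON sidecar.
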