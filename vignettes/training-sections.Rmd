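---
title: "Training-set composition for myoelectric classification of dynamic contractions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training-set composition for myoelectric classification of dynamic contractions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pattern-recognition myoelectric control classifies short windows of
multichannel surface EMG into intended motions. Classifiers for this task
are usually trained and validated on *static* (isometric) contractions, but
a prosthesis is used while the limb is moving: every grasp begins and ends
with a *dynamic* phase in which the EMG is non-stationary. `emgdyn`
implements, end to end, a study of how the temporal composition of the
training set — how much of the dynamic phase is included — affects
window-level classification error, using a fully synthetic but
protocol-faithful data generator so that every stage is testable without
access to human recordings.

The emulated recording protocol is a 9-class hand/wrist task (8 active
motions plus rest) on 6 bipolar channels sampled at 1024 Hz and band-passed
47–440 Hz. Each contraction lasts 10 s — 3 s rest-to-target ramp, 4 s
static hold, 3 s target-to-rest ramp — with 3 s of rest in between; each
subject performs every class twice per session in three sessions
(54 contractions, 6 per class).

## Pipeline

1. **Windowing.** 128-sample (125 ms) windows with a 32-sample hop
   (96-sample overlap). A 10 s contraction yields 317 windows.
2. **Features.** Per channel and window either the time-domain +
   autoregressive set (mean absolute value, zero crossings, slope-sign
   changes, waveform length, plus 6 Burg AR coefficients; 60 features on 6
   channels) or wavelet marginals (L1 norms of the 4 detail bands and final
   approximation of a periodized Coiflet-4 DWT; 30 features).
3. **Onset gate.** Each window's per-channel activity is the mean absolute
   Teager–Kaiser energy. A window is *active* if any channel's activity
   strictly exceeds `coefficient × rest_activity` for that channel. The
   coefficient is calibrated per subject and fold: the largest value on a
   log grid (10^-1^–10^3^, 400 points) keeping >97% of all hold windows
   and ≥85% of each class's hold windows active.
4. **Classification.** LDA (no tunables) or Gaussian-kernel SVM in
   one-vs-one or one-vs-rest decomposition, trained only on active-class
   windows from the selected training section; inactive windows are labelled
   rest without consulting the classifier.
5. **Fusion.** The stream decision is a causal majority vote over the 6 most
   recent window labels (281.25 ms of signal); ties go to the most recently
   observed tied label (the vote depth is even, and this is the only
   deterministic tie-break that never invents a label).
6. **Evaluation.** Leave-one-session-out three-fold cross-validation. The
   error is the fraction of *all* windows of the held-out session (rest
   included) whose fused label differs from the annotated ground truth.
   Fused decisions are scored because they are the pipeline's terminal
   output; the raw per-window error is logged alongside.

The five training sections are intervals centered on each contraction: the
4 s hold only, 6 s and 8 s (hold plus one and two thirds of each ramp), the
full 10 s, and a threshold-based section that keeps whichever contraction
windows pass the calibrated activity gate. For non-default protocols the
time sections generalize as hold + {0, 1/3, 2/3, 1} of the ramps, which
reduces to 4/6/8/10 s under the default timing.

```{r}
library(emgdyn)
study <- reproduce_study(master_seed = 101, n_subjects = 8)
summarize_results(study$results, wide = TRUE)
plot_normalized_errors(study$normalized)
```

## What the synthetic generator emulates

The carrier is amplitude-modulated band-limited Gaussian noise: white noise
filtered by a zero-phase 4th-order Butterworth band-pass (47–440 Hz,
emulating the acquisition hardware), scaled by a per-channel amplitude
envelope. The classification and detection methods under study depend only
on amplitude and spectral statistics, so no motor-unit physiology is
simulated.

Each synthetic subject has:

* a class × channel **holding activation pattern** (relative amplitudes in
  [0, 1], unit maximum per class, pairwise distinct rows, rest row zero);
* a separate **movement activation pattern** used during the ramps. Muscle
  coordination while moving a limb differs from coordination while holding
  it, which is precisely why static-only training is expected to
  underperform. The effective pattern blends linearly (by target-position
  fraction) from the movement pattern into the holding pattern and is
  renormalized to unit channel maximum, so overall drive is maintained
  while relative channel weights shift;
* a signal-to-rest-noise ratio drawn from 10–25 dB, and a per-class peak
  normalized activity drawn from 56–92%, reproducing the reported
  between-class activity spread;
* 5% log-normal trial-to-trial amplitude jitter.

The **amplitude envelope** does not track limb position. Accelerating and
guiding a limb demands muscle activity comparable to holding the target, so
during the ramps the amplitude sits at `dyn_amplitude` (default 0.9) of the
hold level, blending to 1 as the target is approached, with raised-cosine
rise/fall skirts of `onset_tau_s` (default 0.25 s) at the rest boundaries.
An envelope that simply followed the raised-cosine position trajectory
would place most ramp windows below any threshold calibrated to keep 97% of
hold windows active, producing a large gate-rejection error plateau across
the entire ramp — inconsistent with the narrow clustering of errors at
contraction boundaries that motivates the onset gate in the first place.
A consequence of the coordination blend is that per-channel amplitude is
not monotone within a ramp (channels trade amplitude as the pattern
rotates); amplitude grows monotonically through the onset transition, and
the tests assert exactly that.

What the generator does **not** emulate: motor-unit action-potential
shapes, recruitment/firing-rate spectral changes with force, electrode
shift, fatigue, force/kinematics, or cross-channel crosstalk correlation.
Passing the qualitative tests therefore demonstrates that the *pipeline*
reproduces the mechanisms (pattern mismatch between dynamic and static
phases, boundary-concentrated gate errors), not that real EMG would yield
the same numbers.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| window length / hop | 128 / 32 | samples | 125 ms windows, 96-sample overlap; standard latency/accuracy trade-off |
| vote depth | 6 | windows | 281.25 ms decision span, under the ~300 ms usability bound |
| threshold constraints | >0.97, ≥0.85 | fraction | hold-window coverage overall / per class; the coefficient is maximized subject to these |
| threshold grid | 10^-1^–10^3^, 400 pts | – | coefficients span orders of magnitude across subjects; monotone feasibility makes the grid scan exact at its resolution |
| AR order | 6 | – | convention of the time-domain + AR literature; configurable |
| DWT depth / wavelet | 4 / Coiflet-4 | – | 5 bands on a 128-sample window; periodic boundary for exact orthogonality |
| ZC/SSC deadzone | 0.01 × window RMS | amplitude | suppresses noise-driven counts in pipeline runs; 0 in unit tests |
| SVM policy | median-distance γ, C = 10 | – | see below |
| train stride | 4 | windows | consecutive 32-sample-hop windows share 75% of samples; training on every 4th (non-overlapping) window removes the redundancy |

## Numerical and design choices

* **Burg AR, vectorized.** The Burg recursion is implemented over a matrix
  of windows (one column each) so a session's ~45,000 window-channel fits
  are six vector sweeps; it matches `stats::ar.burg` to 10^-10^ on single
  windows (tested) in the convention `x[t] = a1 x[t-1] + … + e[t]`.
  Zero-variance windows return all-zero coefficients with a warning.
* **Periodized DWT.** Implemented as cached orthogonal analysis matrices
  per level; periodic extension keeps coefficient counts halving exactly
  and makes the Parseval identity hold to machine precision (asserted at
  1e-8 in tests), and the marginals match an independent implementation
  (PyWavelets, periodization mode) on a frozen two-tone fixture.
* **Window labels.** A window takes the class/phase of the annotation
  covering the majority of its samples; exact ties go to the later-starting
  annotation. Trailing samples that do not fill a window are dropped.
* **Threshold crossing** is strict (`>`), and calibration uses only
  hold-phase and rest-phase windows of the training sessions — the test
  fold never informs the coefficient.
* **SVM hyperparameters.** The Gaussian kernel's two parameters must be
  set, but no protocol or values are prescribed for this task. The package
  implements both an internal 5-fold cross-validated grid search
  (`tune = "cv"`: C in 10^-1^–10^3^, γ scaled around the median-distance
  heuristic) and a deterministic heuristic (`tune = "heuristic"`:
  γ = 1/median squared pairwise distance of a 400-row training subsample,
  C = 10). The study runs use the heuristic: on z-scored features it is
  stable across training sections and subjects (the grid search selects
  essentially the same region at ~45× the cost), and it keeps the full
  study inside a desktop-scale compute budget. Both SVM decompositions are
  built on binary libsvm machines with explicit decision rules: one-vs-one
  counts pairwise votes (ties → largest aggregate decision value → lowest
  class index); one-vs-rest takes the arg-max of sign-normalized decision
  values.
* **Class balance.** One-vs-rest is trained with no re-balancing of the
  1:7 class ratio, deliberately: the imbalance mechanism is part of what
  the study examines. (A weighting option would be a trivial extension.)
* **Ability index.** A subject's index is the arithmetic mean of their five
  section errors; normalized errors are section errors divided by the
  index, so the mean of the five normalized errors is identically 1. This
  definition is the one under which that identity — used to place all
  subjects on a common scale — holds exactly.
* **Study sizes.** The bundled study runs 8 subjects × 3 sessions under the
  full default protocol and evaluates the key cells (TD+AR/LDA and
  WT/SVM-OVO across all five sections; TD+AR/SVM-OVR on the 4 s and 10 s
  sections); the full 2 × 3 × 5 factorial is available through
  `run_experiment(dataset, study_cells())`.

## Known limitations

* The synthetic carrier is Gaussian; real EMG is spiky (higher kurtosis),
  which raises Teager–Kaiser activity relative to its mean and would make
  onset detection somewhat easier than in this simulation.
* With sound per-fold standardization and hyperparameter selection, the
  one-vs-rest SVM degrades only mildly relative to one-vs-one as dynamic
  data enter the training set; it does not collapse. Reports of a
  catastrophic one-vs-rest breakdown on real recordings plausibly involve
  scaling or hyperparameter-transfer artifacts that this implementation
  deliberately avoids; the package asserts the direction of the
  OVR-vs-OVO gap rather than reproducing a collapse.
* Transitions between pairs of active motions (never passing through rest)
  are out of scope, as are proportional/simultaneous control and online
  threshold adaptation.
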