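---
title: "A multi-area accumulator model of covert visual search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multi-area accumulator model of covert visual search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covertsearch)
library(dplyr)
```

## The task and the model

In the covert search task a macaque fixates a central point surrounded by
2, 4 or 6 placeholders. At cue onset (t = 0) the placeholders are stripped
to reveal one target — a letter E facing left or right — among distractors.
Maintaining fixation, the animal must find the target covertly, identify
its orientation, and release the left or right bar with the corresponding
paw. Reaction times, accuracy, and single-unit recordings from the lateral
intraparietal area (LIP) show three signature effects: higher LIP firing
with the target than with a distractor in the receptive field, suppression
of firing and slower/less accurate behavior as set size grows, and a
response-hemifield congruence effect (faster, more accurate responses when
the required release is on the same side as the target) that is strong in
one subject (M11) and nearly absent in the other (M12).

`covertsearch` implements a network of coupled leaky competing
accumulators spanning four areas:

- **LIP** — six units, one per stimulus location (`L1..L3`, `R1..R3`),
  with recurrent self-excitation and mutual inhibition that decays with
  ring distance (full strength at distance 1, multiplied by `eta_lip_decay1`
  at distance 2 and additionally by `eta_lip_decay2` at the antipode).
  Each unit receives an Ornstein-Uhlenbeck (OU) filtered stimulus input:
  a perceptual drive `s_lip` to the stimulated locations after a
  perceptual delay `p_delay`, a target drive `s_tar` to the target's
  location after a further search delay `t_delay`, and an unconditional
  background `s_back`.
- **IT** — a mutually inhibiting pair selective for the two target
  orientations, driven (also through OU-filtered inputs) by `s_ori` on
  the matching unit from `p_delay + t_delay`.
- **AIP** — a pair of gated accumulators, one per response side. The left
  unit collects the left-facing IT unit (weight `w_itaip`) and the three
  left LIP units (`w_lipaip`) through a threshold-linear gate
  `G[I, g] = max(I - g, 0)`; it excites the left LIP units back
  (`w_aiplip`) and inhibits the right ones (`beta_aiplip`).
- **Motor** — a thresholded pair integrating AIP (`w_aipm`). When either
  unit reaches the threshold `theta` the corresponding response is made
  and the reaction time is the crossing time plus a nondecision latency
  `t_0`. Motor activity feeds global inhibition back onto LIP/IT
  (`beta_mitlip`) and AIP (`beta_maip`), a reset that pulls firing down
  around the time of the response. Motor rates are capped at 150 Hz.

LIP and IT activities pass through the sigmoidal rate function `phi()`,
which rises from 1 Hz to 101 Hz (activities are in kHz); AIP and motor
units are linear leaky integrators with gates. Altogether the state is 20
stochastic differential equations: 6 LIP + 6 LIP input OU processes +
2 IT + 2 IT OU processes + 2 AIP + 2 motor.

The 31 parameters per subject are listed by `param_info()`; the fitted
values for the two subjects ship as `params_m11()` / `params_m12()` (also
as YAML under `inst/extdata/`). In the joint fit 18 parameters are shared
between the subjects and 13 vary, giving the 44 free values handled by
`pack_params()` / `unpack_params()`.

## Numerical scheme and conventions

Several choices are under-determined by the published description of the
model; the package fixes them as follows (each is a documented engine
option where alternatives are plausible):

- **Time origin and initial state.** Integration starts at cue onset
  (t = 0) with all 20 states at zero. The perceptual input switches on at
  `p_delay` and the target/orientation inputs at `p_delay + t_delay`,
  with a right-continuous step (H(0) = 1). The placeholder period before
  cue onset is not simulated.
- **LIP leak.** The LIP rate equations are integrated as
  `tau_lip dX = (phi[...] - X) dt`, matching the IT form. Without the
  leak term, `phi >= 0.001` would force monotone growth and the
  characteristic post-decision decay of LIP firing could not occur.
  `engine = list(lip_leak = FALSE)` selects the leak-free variant.
- **Noise discretization.** An equation written
  `tau dX = f dt + c xi(t)` is read literally, giving the increment
  `(f/tau) dt + (c/tau) dW`; an OU input then has stationary mean equal
  to its drive and variance `c^2 / (2 tau)`. The alternative `c/sqrt(tau)`
  scaling is available as `engine = list(noise_scale = "sqrt_tau")` for
  sensitivity analysis; under it the fitted noise magnitudes are far too
  large to sustain task performance, which supports the literal reading.
- **Integration.** A second-order stochastic Runge-Kutta scheme for
  additive noise (Heun/RK2 with the same Wiener increment in both
  stages), step `dt = 0.5` ms. Halving `dt` moves zero-noise crossing
  times by well under a millisecond.
- **Clamps.** Motor activities are capped at 0.150 kHz; AIP and motor
  activities, which are gated accumulators and may be driven negative by
  noise, are clamped at zero after each step (`clamp_nonneg`).
- **Timeouts.** Trials without a threshold crossing by `t_max`
  (default 1500 ms) are recorded as timeouts and excluded from accuracy
  and RT summaries but reported in counts.
- **Tie-break.** If both motor units cross within the same step the unit
  with the larger activity responds.

Each trial draws its noise from a counter-based generator seeded by
hashing (master seed, condition stream, trial index), so a batch is
bit-reproducible and any single trial can be re-simulated in isolation.

## What the fitted model reproduces — and what it does not

With the shipped M11 parameters, a 6000-trial-per-condition batch at set
size 4 reproduces the printed model behavior closely (pooled accuracy
near 94%, mean RT near 492 ms, and the strong congruence effect), and the
qualitative signatures hold for both subjects: peak LIP rates fall as set
size grows, target-in-RF firing exceeds distractor-in-RF firing through
the selection window, and mean RT *decreases* with set size — the model's
own counterintuitive prediction, opposite to the data, caused by more
active LIP units converging on the response units.

For M12 the simulated accuracies match the printed values at every set
size and congruence, but simulated mean RTs run some 45-65 ms slower
across the board. M12's threshold crossings are noise-driven (with the
noise switched off the fitted M12 dynamics never reach threshold), so its
RT distribution is strongly right-skewed and its mean is sensitive to
discretization details that the published description leaves open. None
of the documented engine variants (leak-free LIP, unclamped accumulators,
square-root noise scaling, finer steps, shorter timeouts) removes the
offset without destroying the M11 match or the accuracies, so the default
conventions are retained and the discrepancy is reported as-is.

## The objective and the optimizer

The fit minimizes a weighted sum of a neural and two behavioral terms
(`objective()`): a squared relative error between simulated and reference
LIP rates over [0, 800] ms (relative to the *simulated* rate, floored at
1 Hz, averaged over the two congruence conditions and the stimulated
units), plus quantile chi-square errors for correct and error RT
distributions. The chi-square bins are set at the 0.1/0.3/0.5/0.7/0.9
quantiles of the reference sample (type-7 interpolation); simulated
counts are rescaled by the reference trial count (using joint
correct+error proportions, so accuracy mismatches are penalized) and
floored at one expected count per bin. A correct/error class with fewer
than 12 reference trials collapses to a single count-only bin. The
default weights are 0.25 on the rate term and 1 on each chi-square.

`fit_search_model()` runs an optional simulated-annealing stage followed
by restarted Nelder-Mead refinement on a logit-transformed scale that
enforces box bounds. Annealing proposals are local Gaussian steps
(SD 0.25) on that scale. Every evaluation simulates with the *same* seed
(common random numbers), which turns the stochastic simulation objective
into a fixed deterministic function during optimization; the best
evaluation over all stages is returned. Two practical findings shaped the
defaults: the objective has long curved valleys in which a single
Nelder-Mead simplex collapses and stalls, so each restart re-expands a
fresh simplex from the best point so far; and from a starting point
within tens of percent of the optimum, annealing mostly *hurts* (its
accepted uphill moves can hand the refinement stage the wrong basin), so
desk-scale experiments with informed starts should set `sann_iter = 0`.
Full 44-parameter joint refits are far beyond desk scale; the supported
workflow fits small free subsets with the rest clamped, as in the
parameter-recovery experiment below.

## The synthetic dataset generator

`generate_dataset()` emulates the structure of the recorded dataset:
cells with rotating receptive-field assignments, sessions of
fixed-set-size blocks, uniformly random target location and orientation,
behavioral outcomes from the simulated network, and spike trains drawn as
inhomogeneous Poisson processes whose intensity is the model LIP
trajectory of the cell's unit. That is a deliberate idealisation: real
LIP spike trains are not Poisson conditioned on a trial-mean rate, there
is no pre-cue baseline activity (the network starts at zero at cue
onset), and no cross-trial rate drift, adaptation or waveform/LFP
structure is modeled. Passing tests on synthetic data therefore validate
the *pipeline* — kernel rate estimation (`fr_from_spikes()`, Gaussian
kernel, SD 15 ms), cell exclusion (`filter_cells()`: peak smoothed rate
above 80 Hz, or missing set sizes), bundle assembly and fitting — not the
realism of the spike model. Firing-rate references average over trials
(trial-weighted, not cell-weighted), matching how the model traces are
averaged.

Default scale (6 cells, 40 trials per block, 3 blocks per cell) keeps a
generated dataset near a thousand trials — small enough for tests while
exercising every set size and receptive-field geometry; the recorded
sessions are an order of magnitude larger.

## A worked parameter-recovery run

The reference bundle is simulated from the true parameters with the same
seed and trial count (1000 per congruence condition) that the objective
itself uses — the self-fit construction, under which the behavioral
chi-squares vanish exactly at truth and the objective bottoms out at the
small within-label firing-rate floor. This isolates what the experiment
is meant to test: whether the optimizer can find the optimum. (With an
independently seeded reference, the chi-square sampling-noise floor at
these trial counts is large enough to open a compensating ridge between
`beta_aiplip` and `s_lip`, and estimates of those two parameters become
unreliable at the 20-40% level — a genuine small-sample identifiability
limit worth knowing about.)

```{r recovery, eval = FALSE}
truth <- params_m11()
ref <- simulate_batch(truth, fitting_conditions(4), 1000,
  seed = 7, keep_traces = TRUE
)
bundle <- objective_data(ref)
start <- update_params(truth,
  w_itaip = truth$w_itaip * 1.3, w_lipaip = truth$w_lipaip * 0.75,
  beta_aiplip = truth$beta_aiplip * 1.3, s_lip = truth$s_lip * 0.75
)
fit <- fit_search_model(bundle, start,
  free = c("w_itaip", "w_lipaip", "beta_aiplip", "s_lip"),
  config = objective_config(n_sim = 1000), seed = 7,
  sann_iter = 0, nm_iter = 90, nm_restarts = 2
)
tidy(fit)
```

The four freed parameters are the connection weights that differentiate
the two subjects plus the perceptual input strength; two Nelder-Mead
restarts (about 180 objective evaluations) recover all four to well
within a percent of their true values.

## Known limitations

- The M12 mean-RT offset described above.
- No pre-cue dynamics: data firing rates rise before cue onset; model
  traces start at zero, so the earliest ~50 ms of a comparison window
  penalizes the model's zero baseline.
- Timeout handling, sparse-bin collapse and the quantile interpolation
  rule are reasonable conventions, not published prescriptions.
- The generator's Poisson spiking understates real spike-train
  variability structure; exclusion thresholds calibrated on it should be
  re-examined on real recordings.
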