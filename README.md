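# covertsearch

A simulator and fitting toolkit for a multi-area stochastic accumulator
model of covert visual search. In the underlying task, a macaque fixates
a display of 2, 4 or 6 stimuli, covertly locates a left- or right-facing
E-shaped target among distractors, and reports the target's orientation
by releasing the left or right bar. The model couples four areas built
from leaky competing accumulators:

- six **LIP** units (one per stimulus location) with recurrent
  excitation and mutual inhibition decaying with ring distance, driven
  by Ornstein–Uhlenbeck-filtered perceptual, target and background
  inputs;
- two **IT** units selective for target orientation, a mutually
  inhibiting pair;
- two gated **AIP** (limb pre-motor) accumulators, one per response
  side, collecting IT and same-hemifield LIP activity through a
  threshold-linear gate `G[I, g] = max(I − g, 0)` and feeding
  cross-inhibition back to LIP;
- two thresholded **motor** units whose first threshold crossing
  triggers the response, with reaction time
  `RT = crossing time + T₀` and global inhibitory feedback that resets
  LIP/IT firing after the decision.

LIP/IT rates pass through the sigmoid
`φ[I] = 0.001 + 0.352(I−0.384) / (1 − e^{−352(I−0.384)} + 3.52(I−0.384))`
(kHz). The full state is 20 stochastic differential equations,
integrated by a compiled second-order stochastic Runge–Kutta scheme at
dt = 0.5 ms. Fitted parameter sets for the two experimental subjects
(M11, M12) ship with the package; 18 of the 31 parameters per subject
are shared in the joint fit and 13 vary, for 44 free values.

The package also implements the analysis layer: Gaussian-kernel firing
rate estimation from spike times (σ = 15 ms), cell-exclusion filters
(peak rate > 80 Hz; missing set sizes), RT-quantile χ² fitting of
correct and error RT distributions, the composite neural/behavioral
objective (weights 0.25 / 1 / 1), simulated annealing + Nelder–Mead
optimization with common random numbers, and a synthetic spike/behavior
dataset generator for parameter-recovery studies.

## Worked example

```r
library(covertsearch)

# simulate 2000 trials per congruence condition at set size 4 for M11
b <- simulate_batch(params_m11(), fitting_conditions(4),
  n_per_condition = 2000, seed = 1
)
glance(b)
#> # A tibble: 2 × 7
#>   set_size congruent     n n_timeout accuracy mean_rt_ms sem_rt_ms
#>      <int> <lgl>     <int>     <int>    <dbl>      <dbl>     <dbl>
#> 1        4 FALSE      2000         0    0.901       527.      3.79
#> 2        4 TRUE       2000         0    0.967       461.      2.44
batch_summary(b)
#> # A tibble: 1 × 5
#>       n n_timeout accuracy mean_rt_ms sem_rt_ms
#>   <int>     <int>    <dbl>      <dbl>     <dbl>
#> 1  4000         0    0.934       494.      2.31
```

Congruent trials (target and required response on the same side) are
faster and more accurate than incongruent ones for M11 — the
response-hemifield congruence effect — and the pooled values sit at the
model's published operating point for this subject (≈94% correct,
≈492 ms). Decision times decompose the mean RT:

```r
cmd_report(NULL, "params_m11", subject = "M11")
# set size 4: ~195 ms (congruent) / ~288 ms (incongruent) of deliberation
# after removing the 250 ms of sensory, search and motor latencies
```

`simulate_batch(..., keep_traces = TRUE)` records mean unit
trajectories; `model_fr_traces()` labels them target-in-RF /
same-hemifield distractor / opposite distractor for comparison with
kernel-smoothed recordings, and `plot_fr_traces()` / `autoplot()` /
`plot_accuracy_rt()` draw the standard figures.

A command-line front end wrapping these functions is installed at
`inst/cli/covertsearch` (subcommands `simulate`, `report`, `synth`,
`objective`, `fit`).

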