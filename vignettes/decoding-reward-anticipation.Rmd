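---
title: "Decoding reward anticipation from single-trial MID EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding reward anticipation from single-trial MID EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(middecode)
```

`middecode` analyses cue-locked EEG from the monetary incentive delay
(MID) task at the single-trial level. This vignette is the package's own
account of the method: the model and its assumptions, the parameters that
matter, what the simulator does and does not emulate, the numerical and
design choices made where the design was genuinely open, and the
limitations a user should keep in mind.

## The task and the two contrasts

Each MID trial shows a cue (250 ms) announcing a potential gain, a
potential loss, or no consequence; after a 2000–2500 ms jittered
anticipation period a target appears briefly, and only a response within
the target's presentation interval counts as a hit. An adaptive staircase
holds the hit rate near 66% so subjective difficulty is comparable across
participants. The anticipation-phase EEG is analysed along two binary
contrasts:

* **valence** — gain-cue vs loss-cue trials (the sign of the anticipated
  outcome);
* **salience** — incentive (gain + loss) vs neutral trials (motivational
  relevance), computed on reaction-time-matched trial sets so that motor
  preparation speed cannot masquerade as a neural salience signal.

## The sliding-window regularized Fisher discriminant

At each training window (width $\delta = 60$ ms, centres $\tau$ from
$-200$ to $2000$ ms in 10-ms steps) the epochs are averaged over the
samples inside the window, giving one channel vector $\bar x_i \in
\mathbb{R}^D$ per trial. A Fisher discriminant with trace-preserving
covariance shrinkage is fit:

$$
w_\tau = S_c^{-1}(m_2 - m_1), \qquad
S_c = \tfrac12(\tilde S_1 + \tilde S_2), \qquad
\tilde S_i = (1-\lambda) S_i + \lambda \nu_i I, \quad
\nu_i = \operatorname{tr}(S_i)/D .
$$

$\lambda = 0$ applies no regularization; $\lambda = 1$ assumes spherical
class covariances. Because $\nu_i$ is the average eigenvalue,
$\operatorname{tr}(\tilde S_i) = \operatorname{tr}(S_i)$ for every
$\lambda$ — shrinkage redistributes variance across directions without
changing its total. The per-trial *discriminating component*
$y_{i\tau} = w_\tau^\top \bar x_i$ integrates evidence across the scalp;
its leave-one-out ROC area (**Az**) measures discrimination, with 0.5 as
chance. $\lambda$ is chosen per window by grid search (step 0.01,
101 candidates) on the leave-one-out Az, ties broken toward stronger
regularization.

Three reading choices deserve note, each configurable:

* $\tau$ is treated as the window **centre** (the window-average runs
  symmetrically over $\tau \pm \delta/2$); an `align = "onset"` option is
  available.
* The window average uses every sample whose centre falls in the closed
  interval — 15 or 16 samples at 256 Hz depending on grid alignment.
* A singular pooled covariance (possible at $\lambda = 0$ with more
  channels than trials) is solved with a pseudo-inverse and a warning
  rather than an error; windows where a class has fewer than two trials
  yield null records rather than aborting a curve. By package convention
  a class left with fewer than two trials contributes a zero covariance
  matrix and zero $\nu$.

The leave-one-out refits are computed exactly, not approximately: leaving
one trial out perturbs its class mean and scatter by rank-one terms, so
all leave-outs within a class share one eigenbasis and each
$(\text{trial}, \lambda)$ solve reduces to a diagonal system plus a
Sherman–Morrison correction. The test suite verifies exact agreement with
an independent brute-force implementation that refits every fold from
scratch, including the more-channels-than-trials case.

## Significance, forward models, intervals

Significance of an Az curve comes from a label-permutation null that
reruns the **full** pipeline — including the $\lambda$ grid search —
inside every draw. This matters: selecting $\lambda$ on the evaluated
trials makes even a null per-window Az sit slightly above 0.5, and the
only honest null reproduces that optimism. The default `pooling =
"pooled"` aggregates draws across evaluated windows into one threshold
(the single dotted significance line usually drawn across time);
`per_window` thresholds are available. The threshold is the
$\lfloor \alpha \, n_{\text{draws}} \rfloor$-th largest null value — for
1000 draws at $\alpha = 0.05$, the 50th largest. Supra-threshold runs
of consecutive windows are reported as intervals, extended half a grid
step beyond their first and last centre. No multiplicity control beyond
the permutation line is applied within a participant's curve; the group
comparison adds cluster-level control.

Decoder weights are not interpretable as brain patterns, so scalp maps
use the forward model $a_\tau = X y_\tau / (y_\tau^\top y_\tau)$, the
channel pattern whose coupling with the component best reconstructs the
data. When a map is requested for several window centres (e.g. a
component's significant interval), the windows are pooled,
$a = \sum_\tau X_\tau y_\tau / \sum_\tau y_\tau^\top y_\tau$, which
targets the same pattern with less estimation noise and down-weights
low-amplitude shoulder windows automatically.

## Behaviour: matching, STV, and the group test

For the salience contrast, incentive trials are selected to match the
neutral RT distribution. The exact sampler is a design choice; the
implementation fits a Gaussian to the neutral RTs, discards incentive
trials implausible under it (|z| > 2.5), and then 1–1 nearest-neighbour
matches incentive to neutral RTs within a caliper (0.25 neutral SDs,
tightened stepwise if diagnostics fail). A Bernoulli sampler that accepts
incentive trials with probability proportional to the neutral density was
considered and rejected: the accepted sample is then distributed as the
*product* of the two densities, whose mean sits between the groups, so it
cannot reach a standardized mean difference below 0.1 under a realistic
80-ms incentive speeding. Pair matching guarantees equal counts by
construction, and the function fails loudly (with diagnostics) rather
than returning unbalanced sets.

Single-trial variability (STV) is the per-trial component amplitude
averaged over the analysis window — by default the a-priori valence
window 400–550 ms, which is also the fallback when no window reaches
significance (the disrupted-valence case). Each participant's RTs are
regressed on {1, STV, trial order, trial outcome (+1 hit / −1 miss)} by
ordinary least squares over responded trials, and the per-participant STV
coefficients enter a one-tailed, one-sample t test ($df = n-1$). Two
points about this design:

* The "mixed-effect model" is implemented as this two-stage
  summary-statistics procedure (per-participant fits, then a test on the
  coefficient distribution), which is what the equations and the group
  test actually describe — not a joint hierarchical likelihood.
* The tested direction is a configuration parameter recorded in the
  output. The hypothesis motivating the default is *negative*: larger
  trial-wise valence differentiation predicts faster responses.
* The per-participant coefficient is expected to be weak (|t| of 1–3):
  the STV is an estimate, so errors-in-variables attenuate the slope, and
  its scale inherits the arbitrary normalization of $w$. Only its sign is
  comparable across participants, which is exactly what the group test
  uses.

## ERP analyses and the group comparison

Classical window means are computed per condition over the conventional
electrode groups and windows — P2 (160–210 ms) and N2 (210–310 ms) over
FC1/FC2/FCz/Fz; cue-P3a (250–400 ms) and cue-P3b (400–550 ms) over
P1/P2/POz/Pz; CNV (1800–2000 ms, the 200 ms before the earliest target)
over C1/C2/Cz/FCz — plus condition difference waves. The
repeated-measures and mixed ANOVAs with Tukey-adjusted contrasts are thin
wrappers over `aov()` and emmeans; they are standard statistics, not
re-derived.

Group Az curves are compared with a nonparametric cluster-mass
permutation test: per-timepoint pooled-variance t statistics, clusters
formed at the one-tailed $t$ critical value for $\alpha = 0.05$, cluster
mass = the sum of t values, null = maximum cluster mass under group-label
permutation. This replaces a random-field-theory (SPM-style) threshold:
the RFT machinery is toolbox-specific, while the permutation test targets
the same cluster-level inference without smoothness assumptions. The two
tails are implemented by group swapping and are exactly symmetric.

## The simulator: what it emulates, and what it does not

`simulate_task()` plays a Gaussian simple-RT agent (per-condition mean
and SD, a lapse probability) against the per-condition staircase: after
every trial the running success rate of that condition is compared with
the 66% target and the response interval is stepped down/up by 20 ms,
clipped to 100–1250 ms. A 30-trial practice block precedes the main 144
trials and carries its staircase state over, as a participant's practice
would; without it the first trials' transient biases the block hit rate
upward. The staircase step (20 ms) and initial interval (350 ms) are free
parameters not fixed by the task design; they are exposed in
`task_config()`. Across heterogeneous agents the simulated grand-mean hit
rate settles near 66–67%, with an across-participant SD of about 2
percentage points.

`simulate_eeg()` builds each epoch as

$$
E_i = a^V_i \, k_V(t) \, \phi_V + a^S_i \, k_S(t) \, \phi_S + \varepsilon_i ,
$$

with $\phi_V$ a unit-norm parietal topography (spatial Gaussian centred
on Pz), $k_V$ a raised-cosine bump supported on 350–600 ms (peak 475 ms,
inside the 400–550 ms analysis window), $a^V_i = \pm g + \text{stv}_i$ by
cue sign (0 for neutral); $\phi_S$ fronto-central (FCz), $k_S$ a linear
ramp over 1300–2000 ms, $a^S_i > 0$ only on incentive trials. The noise
is spatially correlated Gaussian (squared-exponential over the montage,
length scale 0.9, nugget 0.25) with a temporal spectrum mixing white and
1/f power (weight 0.15). Reaction times are optionally re-generated as
$\text{rt} = \beta_0(\text{condition}) + \beta_1 \text{stv}_i +
\varepsilon$ with $\beta_1 = -12$ ms per unit by default, and outcomes
re-derived against the staircase intervals.

Default amplitudes ($g = 10\,\mu V$, STV SD 3, noise SD $8\,\mu V$) were
chosen once as a working point where an intact-valence participant
reaches a peak Az around 0.95–0.99 with 48 + 48 trials — cleaner than
typical real data, deliberately, so that recovery failures in tests
indicate pipeline defects rather than simulation noise. Three structural
choices matter more than the exact numbers:

* the component topographies are more focal (width 0.45–0.5) than the
  noise correlation length (0.9): spatial whitening can then separate
  signal from background, as it does for real focal ERP sources in
  spatially broad background activity;
* gain and loss RT means are equal (280 ms; neutral 360 ms). Planting
  even a few ms of gain-loss RT asymmetry silently breaks the null
  calibration of the STV→RT test, because the decoder's in-sample
  component always separates gain from loss a little, and a systematic
  RT difference then leaks a consistent coefficient sign across
  participants — mirroring the empirical observation that gain and loss
  RTs do not differ while neutral is slower;
* the `LA`/`HA` group presets differ only in stated parameters: `HA` has
  a zero valence amplitude, an elevated salience amplitude, and no RT
  link.

The simulator is deliberately not a head-model forward simulation: no
leadfield, no ocular or muscular artifacts, no feedback-phase activity,
and stationarity across the session. Consequently, passing recovery tests
shows the *pipeline* is correct and calibrated under its assumptions; it
does not show that real recordings satisfy those assumptions.
Synthesis runs at 256 Hz by default (configurable) to keep desk-scale
runtimes; recordings at higher rates are simply decimated grids here.

## Preprocessing

The deterministic chain — 0.1–95 Hz band pass (cascaded high/low pass),
50 Hz notch, common-average reference, cue-locked epoching (−500 to
2000 ms), final 30 Hz low pass — uses zero-phase forward–backward
Butterworth filters (orders 2/4/2/4; the forward–backward pass doubles
the effective order). Baseline correction subtracts the per-channel mean
over −200 to 0 ms, a conventional pre-cue window applied identically to
all trials (the discriminant contrasts trial groups, so a shared baseline
shift is immaterial); it is configurable because the original analysis
does not state whether the machine-learning epochs were baseline
corrected. Statistical artifact rejection is out of scope; a simple
amplitude-threshold epoch rejector (default off) stands in for synthetic
data. Average referencing is idempotent (a second application warns and
returns the input), and filtering and re-referencing commute to numerical
tolerance, which the suite checks.

## Problem sizes used by the validation suite

The acceptance tests exercise cohort-level properties at reduced size so
the default suite runs on one CPU in minutes: 16- or 32-channel montage
subsets, 128 Hz synthesis, 25-ms window grids, shrinkage grids of 5–21
values, 10–20 seeds or replicates per property, and 199–1000 permutation
draws depending on the check. These are the package's own choices of
validation scale; every number is set in the test code, and the
full-resolution configuration (64 channels, 256 Hz, 10-ms grid, 101
shrinkage values, 1000 draws) remains the user-facing default.

## Known limitations

* The permutation and cluster machinery assumes exchangeable trials
  (participants) under the null; slow non-stationarities in real sessions
  violate this in ways the simulator does not model.
* The STV coefficient's scale is participant-specific (it inherits the
  decoder normalization); group inference is therefore restricted to
  sign/direction, and comparing coefficient magnitudes across groups is
  not meaningful without additional normalization.
* The per-window shrinkage search is performed on the same trials it is
  evaluated on; its optimism is mirrored in the permutation null, but Az
  point estimates at selected $\lambda$ remain slightly optimistic.
* RT matching discards trials; with strong incentive speeding the matched
  sets can shrink toward the minimum acceptable size, reducing the
  salience contrast's power — visible in the matching diagnostics.
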