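# middecode

Single-trial EEG decoding of reward anticipation in the (EEG) monetary
incentive delay (MID) task.

During MID anticipation a cue announces whether a fast response will win
money (gain), avoid losing it (loss), or have no consequence (neutral).
Two dimensions of that anticipation can be decoded from cue-locked EEG:
**valence** (gain vs loss) and **salience** (incentive vs neutral).
`middecode` implements the full single-trial analysis chain used to study
these dimensions — including in at-risk-alcohol-use cohorts where valence
discrimination is hypothesised to be disrupted — together with a
task-plus-EEG simulator, so every stage can be validated end-to-end
without access to real recordings.

The package is aimed at EEG researchers who want a tested, reusable R
implementation of this decoding pipeline, and at methodologists who want a
controlled sandbox (planted components, known ground truth) for studying
its behaviour.

## The method

For each training window of width δ = 60 ms centred at time τ (grid −200
to 2000 ms, 10-ms steps), trials are window-averaged into channel vectors
x̄_i ∈ R^D and a regularized Fisher discriminant is fit:

    w_τ = S_c⁻¹ (m₂ − m₁),   S_c = (S̃₁ + S̃₂) / 2,
    S̃ᵢ = (1 − λ) Sᵢ + λ νᵢ I,   νᵢ = trace(Sᵢ) / D,

with the shrinkage λ ∈ [0, 1] chosen per window by grid search (step 0.01)
on leave-one-out performance. The discriminating component y_iτ = w_τᵀ x̄_i
is scored by the leave-one-out ROC area (**Az**); significance comes from a
label-permutation null that reruns the entire pipeline — λ search included
— in every draw. Because the model is linear, each component has an
interpretable scalp topography via its forward model a_τ = X y / (yᵀ y).

Around this core the package provides:

* an adaptive-staircase MID task simulator (66% target hit rate) with a
  Gaussian-RT agent model, and an EEG generator that plants a parietal
  valence component (±g by cue sign plus trial-level variability, STV)
  and a late fronto-central salience ramp in structured noise;
* RT-distribution matching of incentive to neutral trials for the
  salience contrast (removes motor-preparation confounds);
* STV extraction over a component window and a per-participant regression
  `rt ~ 1 + stv + trial_order + trial_outcome`, with a one-tailed group
  test on the coefficients;
* classical ERP window amplitudes (P2, N2, cue-P3a, cue-P3b, CNV),
  difference waves, and repeated-measures/mixed ANOVA wrappers;
* a cluster-mass permutation test comparing group Az curves over time.

## A worked example

```r
library(middecode)

# one simulated low-risk-like participant: task, then cue-locked EEG
trials <- simulate_task(seed = 1)
sim    <- simulate_eeg(trials, group_preset("LA"), seed = 2)

# gain-vs-loss sliding discriminant on the incentive trials
idx    <- which(sim$trials$condition != "neutral")
labels <- factor(sim$trials$condition[idx], levels = c("loss", "gain"))
dec    <- sliding_analysis(sim$epochs, labels,
                           sliding_window_spec(center_grid_ms = seq(-200, 2000, 25)),
                           subset = idx)
glance(dec)
#> # A tibble: 1 × 6
#>   n_windows n_evaluated    n1    n2 peak_az peak_ms
#>       <int>       <int> <int> <int>   <dbl>   <dbl>
#> 1        89          87    48    48   0.993     475

# permutation significance line and supra-threshold intervals
null <- permutation_threshold(sim$epochs, labels,
                              sliding_window_spec(center_grid_ms = seq(-200, 2000, 100)),
                              n_perm = 1000, seed = 3, subset = idx)
significant_intervals(dec, null)
#> # A tibble: 4 × 4
#>   start_ms end_ms peak_az peak_ms
#>      <dbl>  <dbl>   <dbl>   <dbl>
#> 1     62.5   87.5   0.693      75
#> 2    238.   262.    0.674     250
#> 3    312.   588.    0.993     475
#> 4    912.   962.    0.675     950

# the component's scalp pattern over its window
fm <- decode_forward_map(sim$epochs, dec, seq(400, 550, 25), subset = idx)
cor(fm, sim$truth$topo_valence)
#> [1] 0.968
```

The dominant interval (312–588 ms, peak Az 0.993 at 475 ms) brackets the
planted 400–550 ms valence component, and the forward model correlates
0.97 with the planted parietal topography; the three one-window blips are
the expected cost of drawing a single α = 0.05 line across ~90 windows
with no further multiplicity control (the group comparison module adds
cluster-level control where it matters). The trial-by-trial link to
behaviour is a group-level question — per participant it is weak, exactly
as in real data:

```r
spec <- cohort_spec(n_per_group = 12, groups = "LA",
                    config_args = list(channels = mid_montage()$label[seq(1, 64, 2)],
                                       srate_hz = 128), seed = 42)
res <- analyze_cohort(spec, contrast = "valence",
                      spec = sliding_window_spec(center_grid_ms = seq(400, 550, 25)),
                      grid = seq(0, 1, 0.05))
group_beta_test(res$beta_stv, "negative")
#> # A tibble: 1 × 6
#>       n mean_beta     t    df         p direction
#>   <int>     <dbl> <dbl> <dbl>     <dbl> <chr>
#> 1    12     -1.17 -5.49    11 0.0000950 negative
```

`autoplot()` methods draw the Az curve with its significance line, the
cluster comparison and the null histogram; `plot_topography()` maps any
channel vector (e.g. a forward model) on the scalp.

Cohort-level workflows (`cohort_spec()`, `generate_cohort()`,
`analyze_cohort()`, `compare_az_curves()`) simulate and analyse whole
two-group studies; see the methods vignette in `vignettes/`.

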