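# patchforage

Simulation and analysis of temporal decision-making in a two-port
patch-foraging task: a generative task model with Marginal-Value-Theorem
(MVT) optimal exit computation, seeded synthetic-data generators with
known ground truth, and the full analysis chain used to characterize
reward-reset foraging behavior, striatal firing-rate state transitions,
and dopamine transient amplitudes.

## The problem

In the task, a mouse alternates between a **context port** — four evenly
spaced water rewards over 5 s ("high" reward-rate blocks) or 10 s
("low"), alternating every three minutes — and a **time-investment
port**, a patch whose reward opportunities arrive on a 100 ms grid with
probability decaying exponentially from entry,

    p(t) = p0 · exp(−t / τ),     Σ p(t) = 8 expected rewards.

The scientific questions are *when* the animal abandons the patch, how
that compares with the reward-rate-maximizing (MVT) policy, how
populations of dorsomedial-striatum neurons time the reward-to-exit
interval through discrete firing-rate state transitions that accumulate
to a threshold, and how dopamine transients after each reward scale with
reward timing and context. The package is aimed at researchers who want
a tested, reusable implementation of these analyses that can be
validated end to end on synthetic data with known generating parameters.

Seven analysis surfaces:

| Stage | Functions |
| --- | --- |
| Task model & MVT optimum | `task_config()`, `patch_reward_probability()`, `expected_cumulative_rewards()`, `overall_reward_rate()`, `mvt_optimal_exit()` |
| Synthetic behavior | `exit_policy()`, `simulate_session()`, `simulate_patch_rewards()` |
| Synthetic spikes / photometry | `synthetic_neuron()`, `neuron_population()`, `simulate_spike_trains()`, `photometry_gen_params()`, `simulate_photometry()` |
| Behavior analysis | `build_trial_table()`, `leaving_hazard()`, `fit_stay_leave_svm()`, `project_exit_times()` |
| Step detection | `instantaneous_rate()`, `fit_session_sigmoid()`, `fit_interval_sigmoid()`, `classify_unit()`, `detect_steps()` |
| Accumulation to threshold | `build_accumulation()`, `fit_threshold_model()` |
| Photometry | `preprocess_trace()`, `quantify_transients()`, `fit_amplitude_model()` |

Event logs, spike trains, and photometry traces read and write plain
tab-delimited text (`write_session_events()` and friends), matching the
timestamped-text format such rigs produce. `run_synthetic_benchmark()`
chains every stage over seeded sessions and reports parameter recovery.

## Worked example

```r
library(patchforage)

cfg <- task_config()          # calibrated defaults: tau = 8 s, sums to 8
mvt_optimal_exit(cfg, "high")
mvt_optimal_exit(cfg, "low")
#> MVT optimum (high context): exit 2.200 s after entry, overall rate 0.7594 rewards/s
#> MVT optimum (low context): exit 5.600 s after entry, overall rate 0.4955 rewards/s
```

Leaner environments warrant longer stays: the optimal exit moves from
2.2 s to 5.6 s when the context port slows down.

```r
ev  <- simulate_session(cfg, exit_policy(), seed = 42)   # 18-min session
tab <- build_trial_table(ev)
#> 61 completed patch visits; mean occupancy 8.69 s (high) vs 12.73 s (low)

project_exit_times(tab)
#>  context intercept      slope  n
#>     high  3.959523 -0.1399601 37
#>      low  5.647254 -0.1660253 22
```

The projected-exit regression recovers the generating reward-reset
policy (intercepts 4 / 5.5 s, slope −0.15): each reward resets the
intended wait, shortened by patch occupancy and lengthened in the low
context. A linear stay/leave classifier ranks the behavioral factors —
the time since the most recent reward dominates:

```r
fit_stay_leave_svm(tab, bin = 0.05)
#>   time from reward:  -6.3984
#>   time from entry:   -2.0209
#>   context (high=1):  -1.9354
```

Neural and dopamine stages run the same way:

```r
sts <- simulate_spike_trains(ev, neuron_population(16), seed = 43)
det <- detect_steps(sts, ev)
#> Step detection: 16 units, 423 intervals; 13 step-like units

acc <- build_accumulation(det, ev)
fit_threshold_model(acc, tab, project_exit_times(tab))
#> Accumulate-to-threshold model: 13 step-like units, threshold 11.49 units
#>       slope_vs_exit  r = -0.842  (p = 1.9e-17)
#>   intercept_vs_exit  r =  0.085  (p = 0.52)
#>   predicted_vs_exit  r =  0.832  (p = 9.7e-17)
```

The accumulation of transitioned units ramps faster when the exit comes
sooner (negative slope–exit correlation), its intercept carries no
timing information, and the threshold-crossing times predict the actual
exits — the accumulate-to-threshold signature.

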