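---
title: "Models and methods behind patchforage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind patchforage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchforage)
```

`patchforage` implements an analysis pipeline for a two-port
patch-foraging task in freely moving mice, together with seeded
generators that produce behavioral event logs, spike trains, and
fiber-photometry traces with known ground truth. Every analysis stage can
therefore be validated by parameter recovery. This vignette explains the
underlying models, the defaults and why they were chosen, and the
numerical decisions that shape results.

## The task model and the MVT-optimal exit

The *time-investment port* (the patch) offers discrete Bernoulli reward
opportunities on a 100 ms grid whose per-bin probability decays
exponentially from patch entry,

$$p(t) = p_0 \, e^{-t/\tau},$$

with $p_0$ solved so the infinite sum of bin probabilities equals eight
expected rewards — the calibration constraint of the task. The *context
port* pays four evenly spaced rewards over 5 s ("high" reward-rate
blocks) or 10 s ("low"), alternating every three minutes over an
18-minute session, with 300 ms of travel between ports.

The task description fixes the sum-to-eight constraint and the 100 ms
minimum reward spacing but not $\tau$ itself; `task_config()` defaults to
$\tau = 8$ s, a free simulation parameter that yields realistic reward
runs of a few per visit with optimal exits of a few seconds, and exposes
it as an argument. With the default calibration $p_0 \approx 0.0994$ per
bin.

A stay-until-$T$ policy earns, per foraging cycle,

$$R(T) = \frac{E(T) + 4}{T + D_c + 2 \cdot 0.3},$$

where $E(T)$ is the expected cumulative patch reward by $T$ and $D_c$ the
context duration. `mvt_optimal_exit()` maximizes $R$ by deterministic
coarse-to-fine grid search (tolerance 1 ms). Because $E$ increments only
at bin boundaries, the maximizer lies on the opportunity grid; the
Marginal Value Theorem stationarity condition — the instantaneous patch
rate equals the achieved overall rate at the optimum — is verified and
reported as `stationarity_gap`. Premature context-port exits are not
modeled (trained animals rarely leave early, and the simulated agent
never does). Two degenerate regimes are flagged rather than solved: a
patch that never depletes below the overall rate (unbounded optimum), and
a patch so lean that even the first opportunity bin is not worth its time
(optimum at the boundary, exit at entry; with the default calibration
this happens for $\tau \gtrsim 11$ s). Sweep-style analyses therefore
sample $\tau \in [3, 11]$ s.

At the defaults the optima are 2.2 s (high context) and 5.6 s (low):
leaner environments warrant longer patch stays.

## The behavioral generator: a reward-reset agent

Observed exit behavior in this task is dominated by the time since the
most recent reward, modulated by patch occupancy and context. The
generator encodes this directly: after each reward at occupancy time $t$,
the intended wait is reset to

$$w = a_c + b_c\, t + \varepsilon, \qquad \varepsilon \sim
\mathcal N(0, \sigma^2),$$

truncated at 0.2 s, with $b_c \le 0$ (longer occupancy shortens the
wait) and $a_\text{low} \ge a_\text{high}$ (cheap time lengthens it). The
wait before the first reward is a separate `baseline_wait`, since nothing
forces an animal to time its pre-first-reward wait the same way. The
linear form makes generator and analyzer self-consistent: the
projected-exit regression fits exactly this model, so recovery is a
well-posed check rather than an approximation.

Defaults — intercepts 4 s (high) and 5.5 s (low), slope −0.15, baseline
4.5 s, noise SD 0.25 s — produce occupancies of a few seconds, low
context longer than high, with trial-to-trial jitter comparable to
rodent timing variability at these durations. They are fixed study
conditions, not tuning knobs.

One subtlety: a reward is "final" only if no further reward arrives
within its wait, which mildly favors short-noise draws among final
rewards. The induced bias on the recovered policy scales with
$\sigma^2$ times the local reward hazard and is below 2% at the default
noise; the policy-recovery analyses average over 50 seeds and recover
slope and intercepts within 5%.

## Two-state neurons and spike trains

Each synthetic unit is a two-state Poisson neuron that resets to its
pre state at every patch anchor (entry or reward) and transitions to its
post state at a characteristic *fraction of the agent's current intended
wait* — the ground-truth encoding of "the population spans the intended
interval". A transition is realized with probability `participation`
(default 0.9; intervals without a realized step motivate the detector's
50% classification rule), jittered (default SD 50 ms), and clipped to the
interval: a reward that arrives before the transition re-arms the unit.
Default populations are 75% off/on units (5 to 20 Hz) and 25% on/off
units (20 to 5 Hz) whose delay fractions take the early end of the
(0.05, 0.95) spread, mirroring the early clustering of on/off units.

## Step detection

The detector follows a bounded-sigmoid procedure:

1. **Rates.** The instantaneous rate is one over the interspike interval
   covering each 10 ms bin center; bins beyond the first/last spike use
   the gap to the window edge. Within the detection pipeline the
   inverse-ISI estimates are clipped at half the bin sampling limit
   (50 Hz at 10 ms bins). The unclipped estimator is mean-unbiased under
   the length-biased sampling of bins but so heavy-tailed (per-bin SD of
   order the rate itself) that least squares mislocalizes steps: the
   typical post-state bin reads *below* the midpoint of the fitted
   levels, biasing split placement late. Clipping restores calibration
   and cut the median step-time error by roughly 20% in synthetic
   benchmarks. The clip is configurable (`max_rate`).
2. **Session sigmoid.** All post-anchor rate series of a unit are pooled
   on time-from-anchor (truncation-free, unequal lengths pooled as-is)
   and fit with a four-parameter logistic
   $y = A + (B-A)/(1+e^{-k(t-c)})$ by least squares. Reported parameters
   follow the (y-offset, height, slope, center) convention with
   height $= B-A$ and slope $= k(B-A)/4$, the rate of change at the
   center in units of Δ(spikes/s)/s, so bounds can be stated in those
   units regardless of parameterization.
3. **Interval fits.** Each interval is refit with $A$ and $B$ bounded to
   ±20% of the session |height| around the session values (the "match
   the session states" constraint; the exact numeric tie is not
   prescribed anywhere, so it is a configurable `level_tol`), the slope
   at center required to exceed 11 Δ(spikes/s)/s, and the center bounded
   to the interval duration ±10%. A fit succeeds when the center lands
   at least 100 ms inside both edges; otherwise the center saturates at
   a bound — the interval is fit as entirely low or entirely high.
   Intervals shorter than 0.3 s cannot contain a valid center and are
   failed without fitting.
4. **Ramps.** The slope bound exists to keep shallow sigmoids from
   fitting ramping activity. A bounded fit alone does not achieve that (a
   forced steep step placed mid-ramp is a local optimum with an interior
   center), so the optimizer runs from two deterministic starts — a steep
   start with the center seeded at the interval's best two-level split
   (an exhaustive SSE scan over bin positions; plain midpoint seeding
   left the single start in local minima), and a shallow start at the
   slope bound. If the shallow, bound-saturated curve fits at least as
   well, the activity is ramp-like and the fit is recorded as a
   `slope_bound` failure. Everything is deterministic and invariant to
   interval order.
5. **Classification.** Step times are summarized over successful fits in
   a single pass; intervals longer than mean + SD are *eligible*, and a
   unit is step-like when at least 50% of eligible intervals (minimum 5,
   with at least 10 intervals overall) carry a detected step. The 50%
   rule alone admits constant-rate units too often — with a spurious
   session contrast, noise places interior centers freely — so two
   detector guards apply: session |height| ≥ 3 Hz and session-sigmoid
   $R^2 \ge 0.02$. The $R^2$ guard was calibrated on synthetic data,
   where two-state units pool to $R^2 \ge 0.036$ and constant-rate units
   to $\le 0.011$; at these settings constant-rate false positives are
   below 5%. Polarity is the sign of the session height.

Median absolute step-time error on 5→20 Hz units with 2–6 s intervals and
no jitter is ~0.08 s. About half of that is irreducible with this
estimator: a rate change is only observable at the first post-transition
spike, which lags the true transition by an exponential with mean
1/rate_post.

## Accumulation to threshold

For each interval, the step-like units' detected step times form a
cumulative count; an ordinary least-squares line is fit to the support
points (0, 0), each transition's post-jump value, and the final count at
the interval end. Dense 10 ms sampling of the step function is available
behind `sampling = "grid"` but overweights long flat tails; the default
uses the transition-time support. Sessions need at least six step-like
units, the population inclusion rule; smaller sessions are skipped with a
logged reason.

The session threshold is the mean count at true exits over
reward-to-exit intervals; each interval's predicted exit is where its
fitted line crosses the threshold (no prediction when the slope is not
positive — reported, never extrapolated backwards). Slope and intercept
are correlated against true exit times, and, for reward-to-reward
intervals, against the behaviorally projected exit times.

Because transitions scale with the intended wait, the accumulation slope
is approximately (units)/(wait): steeper when exits come sooner. The
slope–exit correlation is therefore negative by construction — as in the
recorded data, where nearly every session shows a negative correlation —
and this holds in ≥95% of seeded synthetic sessions through the full
detector. "Noiseless" prediction checks (jitter 0, participation 1) feed
the generator's ground-truth transition times to the accumulation stage,
since Poisson spiking noise and detector edge effects are noise sources
in their own right; truth-fed predictions match true exits essentially
exactly, while detector-fed predictions correlate at r ≈ 0.94.

## Behavior analyses

**Hazard curves.** The leaving hazard is the probability of exiting in a
bin given survival to its start. Reward-aligned curves treat every
reward (and the entry — "time since most recent reward" before any
reward is defined as time since entry) as the start of an epoch,
censored at the next reward: the epoch counts as at-risk up to the
censoring reward but contributes no exit. The stratification edges for
reward-time groupings are exposed as a parameter
(`reward_time_breaks`), as no canonical edges exist.

**Stay/leave classifier.** Patch occupancy is cut into 10 ms bins
("stay") and the 5 s after each exit into "leave" bins; features are time
since entry, time since most recent reward, and context. Features are
z-scored; a linear-kernel SVM (cost 1) with inverse-frequency class
weights separates the classes, and the signed coefficients of the
normalized features rank the factors. For tractability each class is
thinned to at most `max_bins_per_class` bins by deterministic
even-spaced subsampling (default 2000); coefficients are stable under
the thinning. For reward-reset agents the time-since-reward coefficient
dominates, reproducing the behavioral signature.

**Projected exits.** Per context, exit-time-from-final-reward is
regressed on the final reward's time from entry (trials without rewards
are excluded — there is no reward to time from), and the fitted line is
applied to every reward to project the exit that would have followed it.

## Photometry

The generator writes a 40 Hz two-channel trace: a shared baseline with
slow sinusoidal drift, a motion artifact injected identically into both
channels, independent Gaussian noise, and — in the signal channel only —
one double-exponential transient per patch reward (rise 0.1 s, decay
0.5 s, onset shifted so the peak lands 300 ms after the reward,
consistent with the sub-second kinetics of genetically encoded dopamine
sensors). The ground-truth amplitude in dF/F0 units is
$a_0 + g_N \log(\text{NRI}) + g_C\,[\text{low}]$, multiplied by a
suppression factor when the inter-reward interval is under 1 s — the
three empirical signatures of the dopamine signal: larger transients for
later rewards, larger in the lean context, suppressed for rapid
doublets.

Preprocessing follows the fixed order: Butterworth high-pass (2nd order,
0.01 Hz, forward–backward — well below transient timescales), 200 ms
moving average, OLS scaling of the isosbestic channel onto the signal
channel and subtraction, then dF/F0 with a centered 10 s moving-mean F0.
Channels are demeaned before filtering: the forward–backward filter's
edge transient on a DC offset decays over ~1/cutoff seconds and differs
between channels with different baselines, which would corrupt the
scaling regression. Moving windows truncate at trace edges and the
affected samples are flagged. F0 is taken from the *raw* 470 nm trace by
default: the detrended trace is zero-centered, so its moving mean does
not measure baseline fluorescence; the motion-corrected alternative is
available behind `f0_source = "corrected"` with a floored F0.

Per reward, the peak is the maximum dF/F0 within 0.5 s after the reward
and the baseline the minimum after the reward but before the peak;
amplitude is their difference. This quantification is structurally
conservative: the moving average flattens the peak (~4%), the
min-before-peak baseline sits slightly above zero (~2%), and F0 absorbs
some transient mass (~1%), so recovered amplitudes run ~8% below the
generating values on isolated transients — a property of the
measurement, visible only because the generator's truth is known.
Amplitude-recovery checks therefore use rewards at least 1 s from their
predecessor; sub-second doublets overlap and belong to the suppression
analysis, not calibration.

The amplitude model is a linear mixed-effects fit, amplitude ~
standardized log(NRI) + context + standardized log(IRI), with a random
intercept per session (nested in animal when animal identifiers exist).
The first reward of a visit has no predecessor; its IRI is defined as
its NRI. Singular fits (e.g. perfectly homogeneous sessions) fall back
to ordinary least squares with a flag.

## Problem sizes and runtime

The validation suites run at desk scale, chosen to keep the full test
suite in minutes while leaving Monte-Carlo error well inside the asserted
margins: 10,000 visits for calibration; 20 configs for the MVT sweep; 500
intervals and 200 control units for the detector; 50 seeds × ~240 trials
for policy recovery; 50 sessions of 12 units (360 s each) for the
accumulation sweep; 50 sessions for the classifier; and ~10 seeded runs
of ~1,200 transients for the photometry model. `run_synthetic_benchmark()`
performs the same end-to-end recovery at a configurable scale.

## Known limitations

* The generator's statistical structure matches what the analyses
  assume; real data bring non-Poisson spiking, electrode drift,
  multi-timescale behavior, lick dynamics, and sensor nonlinearity, none
  of which are emulated. Passing recovery here validates the pipeline's
  logic, not its robustness to those features.
* The inverse-ISI step detector carries an intrinsic late bias of order
  1/rate_post and degrades for steps within ~0.1 s of interval edges;
  units with extreme delay fractions are systematically missed.
* The hazard estimator is undefined in bins with no at-risk epochs
  (`NA`), and reward-aligned curves assume the censoring-at-reward rule
  stated above; the source analyses do not state theirs.
* MVT optima are exact only for the discrete-bin reward model; the
  continuous-hazard limit differs at the bin scale.
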