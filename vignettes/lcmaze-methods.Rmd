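---
title: "Models and methods behind lcmaze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lcmaze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcmaze)
```

# What the package computes

Locus coeruleus (LC) neurons fire tonically at 1–3 Hz and emit brief
phasic bursts around salient events. `lcmaze` analyzes LC single-unit
activity recorded while a rat runs a self-paced T-maze discrimination
task: each trial starts when the rat crosses a photodetector (PD) on the
central arm, which lights a visual cue (VC) on one side; crossing the
reward-arm PD triggers reward delivery; crossing the return-arm PD
extinguishes the cue. The reward contingency alternates, unsignalled,
between a visual rule (follow the lit screen) and a spatial "turn" rule
(always one arm), switching automatically once the animal is correct on
at least 18 of the last 20 trials.

Four families of statistics are implemented:

1. **Windowed response ratios.** For each session/unit, the baseline rate
   is the mean firing rate in $[-1.5, -1)$ s before VC onset. The VC-onset
   and VC-off statistics divide the larger of the two 0.5 s pre-event bin
   rates ($[-1,-0.5)$ and $[-0.5,0)$, before the VC-onset and return-arm
   PD respectively) by that baseline; the reward-PD statistic uses the
   single bin $[-0.5, 0)$ before the reward PD, and the reward-site
   statistic the window $[1, 2)$ s after it. All four share the VC-anchored
   baseline; a ratio of 1 means no change. Population inference is a
   one-sample two-sided t test of session ratios against 1.

2. **Rule-shift comparison.** Per-trial spike counts in $[0, 0.5)$ s
   after VC onset, split at the first rule change, compared with a
   two-sided Wilcoxon rank-sum test.

3. **Firing–acceleration coupling.** Head-LED tracking at ~30 Hz yields
   instantaneous speed (distance per frame interval), Gaussian-smoothed
   and differenced to acceleration. Firing rate and mean acceleration are
   paired in 200 ms bins over $\pm 1$ s around each PD crossing; bins with
   firing below 0.1 Hz (zero-spike bins) are excluded; rate and
   acceleration are z-scored per unit-session; ordinary least squares is
   run on the positive-acceleration bins. A matched analysis runs outside
   all event windows (100 ms bins, down-sampled to the event-window n).

4. **Timing.** A lag scan displaces the acceleration series in 20 ms
   steps over $\pm 1$ s and reports the shift maximizing the Pearson
   correlation with the binned firing rate (positive = firing precedes
   acceleration). Independently, onsets of firing-rate increases (95th
   percentile threshold on a 50 ms-binned, kernel-smoothed rate) and of
   acceleration increases (97.5th percentile threshold) are detected as
   upward threshold crossings, and acceleration-onset lags are collected
   in a $\pm 500$ ms onset-triggered cross-correlogram whose mean lag
   summarizes the lead of firing over movement.

# The synthetic session generator

No public recordings accompany this task, so the package ships a
generator whose sessions carry exactly the statistical structure the
analyses assume. It is first-class, tested code, not a fixture.

**Task automaton.** Cue sides follow the task's pseudorandom constraints:
no side lit more than 2 consecutive trials, no strict alternation longer
than 4 trials, and at most 5 of either side in any 8 consecutive trials.
Generation uses backtracking search with randomized branch order, which
terminates for any length (rejection sampling does not guarantee this).
The rule switches when a moving window of the last 20 trials (within the
current rule epoch) contains at least 18 correct responses.

**Behavior agent.** The agent attends to one rule, follows it with
probability `p_follow_rule` (default 0.9), otherwise guesses with a side
bias, and updates its attended rule only `attended_rule_lag` trials
(default 10) after an unsignalled switch. The agent, like the kinematic
bump shape and the rule-schedule policy, is an acknowledged invention:
the task defines contingencies, not a behavioral model.

**Kinematics.** The maze is a 1-D canonical path (start area, 100 cm
central arm, 50 cm reward arm, return path) mapped to 2-D for tracking
output; all analyses depend only on scalar speed and acceleration. The
simulated rat cruises at 35 cm/s with an AR(1)-wandering set-point
(relative SD 0.08, time constant 0.5 s), launches out of dwells at up to
80 cm/s², relaxes toward its set-point with a 1 s time constant, brakes
smoothly into the reward well and start area, and dwells there (2.5 s and
1.5 s). Before each PD crossing it emits an acceleration bump of 40 cm/s²
lasting 0.5 s, with a fast quarter-sine rise over the first quarter of
the bump and a slow cosine decay — locomotor accelerations begin
abruptly, and a gradual symmetric bump would make "onset" ill-defined for
any threshold detector. The 1 s controller constant matters for the same
reason: an instantaneous controller would slam an equal-and-opposite
braking lobe one frame after every bump, an artifact with no
physiological counterpart that distorts every correlation-based timing
estimate. PD crossing times are interpolated within the frame, so event
times and tracking agree to within one video frame (33 ms). Kinematic
magnitudes for this task are not published anywhere; these defaults are
free parameters chosen once at plausible rat-locomotion values.

**Spikes.** Each unit is an inhomogeneous Poisson process sampled exactly
by thinning, with intensity

$$\lambda(t) = b \; g_{ev}(t) \; s_{rwd}(t) + \gamma \,
  \max\{0, a(t + \delta)\}$$

where $b$ = 2 Hz is the tonic rate; $g_{ev}$ multiplies the baseline by
1.5 over the 0.5 s before VC onset and by 1.4 before the return PD
(event-locked phasic gains at the magnitude of the observed response
ratios); $s_{rwd} = 0.44$ suppresses firing over $[1, 2)$ s after the
reward PD (reward-site quiescence); $\gamma$ = 0.3 Hz/(cm/s²) couples
firing to positive acceleration only; and $\delta$ = 35 ms makes firing
*lead* acceleration, giving ground truth for the timing estimators. The
coupling strength places phasic excursions at 10–20 Hz instantaneous —
the LC phasic-burst range — which is also the regime in which
percentile-threshold onset detection is driven by signal rather than by
Poisson rate noise; at couplings several-fold weaker the 95th-percentile
threshold exceeds the deterministic signal peaks and detected "onsets"
degrade into noise crossings. The acceleration entering $\lambda$ is
indexed by the frame whose center sits at $t + \delta$; frame-edge
indexing would silently subtract half a frame from the ground-truth lead.

**What the generator does not emulate.** Real LC spike trains are not
Poisson (refractoriness, burst structure, post-burst autoinhibition);
real tracking has positional noise and dropouts (supported by the gap
masking, but off by default); real behavior has satiety drifts, pauses
and backtracks. Passing recovery tests on this generator therefore shows
the *estimators* are correct and calibrated on data satisfying their
assumptions — it does not certify performance on recordings.

# Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `baseline_rate_hz` | 2 | Hz | LC tonic rate |
| `event_gain` | 1.5 (VC), 1.4 (return) | – | phasic gain, 0.5 s pre-event |
| `reward_suppression` | 0.44 | – | rate factor, [1,2) s post reward PD |
| `accel_coupling` | 0.3 | Hz/(cm/s²) | positive-acceleration coupling |
| `firing_lead_s` | 0.035 | s | firing precedes acceleration |
| smoothing kernel SD | 0.1 | s | speed and instantaneous rate |
| rate grid | 0.05 | s | instantaneous-rate bins |
| event bins | 0.2 over ±1 | s | paired-bin analyses |
| outside bins | 0.1 | s | outside-event analysis |
| onset percentiles | 95 / 97.5 | – | firing / acceleration thresholds |
| onset exclusion | ≤ 4 | Hz | session threshold floor |
| lag-scan step / span | 0.02 / ±1 | s | shift grid |

The smoothing kernel deserves a note: the task description fixes the
kernel only as "size twice its SD", but the instantaneous-rate
construction is pinned by the statement that a single spike can reach
4 Hz — with 50 ms count bins a lone spike's smoothed peak is
$1/(\sqrt{2\pi}\,\sigma)$ Hz, which equals 4.0 Hz exactly at
$\sigma = 0.1$ s. The same kernel is applied to speed.

# Numerical and inferential choices

* **Half-open windows.** Every window and bin is $[a, b)$; a spike
  exactly at an event time belongs to the bin starting at 0. This makes
  bin assignment unambiguous (edge handling is otherwise unspecified).
* **Backward differences.** Speed and acceleration are assigned to the
  later timestamp (causal, matches online computation); samples across
  tracking gaps larger than two frames are masked, never interpolated.
* **Ratio of means, not mean of ratios.** Response ratios divide
  trial-mean rates; per-trial ratios are unstable at LC rates.
* **Bin exclusion.** "Below 0.1 Hz" removes zero-spike bins for the
  regressions (with raw 200 ms bin rates nothing can lie strictly
  between 0 and 0.5 Hz). The regressions use raw per-bin rates — their
  errors are then independent across bins and the OLS p-value is
  calibrated; bin means of the *smoothed* rate series are kept alongside
  and drive the lag scan, which needs a continuous-valued series.
* **Lag-scan selection.** The positive-acceleration restriction is
  applied to the regressions, where it is a fixed sample; inside the lag
  scan the selected sample would change with every shift, which adds
  argmax noise, so the scan correlates the full paired series (a
  `positive_only` switch restores the restriction). Ties in the maximal
  correlation break toward the smallest absolute shift.
* **Permutation rank-sum.** Spike counts in 0.5 s windows are heavily
  tied; the rule-shift Wilcoxon p-value is computed by Monte-Carlo
  permutation of the rank-sum statistic (999 draws), which stays exact
  under ties where the normal approximation is conservative.
* **Onset hysteresis.** After an onset, no new onset is counted until
  the series falls back below the threshold, preventing bin-jitter
  double counting.
* **Degenerate inputs.** Zero baselines make ratios undefined (error,
  not NaN); all-zero count vectors flag the rank-sum test degenerate;
  a unit with zero baseline rate is "unclassifiable" by the opto test
  rather than entrained or not; sessions whose firing-onset threshold is
  at or below 4 Hz are flagged excluded, not errored.
* **Blocks.** Welch t tests compare per-trial pre-event rates between
  every block pair, Holm–Bonferroni-adjusted over all pairs within the
  session. Multi-unit sessions are analyzed per unit throughout.

# Estimator properties worth knowing

Two systematic properties of the timing estimators, visible on synthetic
ground truth, inform interpretation on any data:

* The onset cross-correlogram's mean lag is a *mixture*: pairs from
  genuine firing→acceleration events sit near $\delta$ plus the
  difference between the two detectors' threshold-crossing delays, while
  chance pairs contribute a symmetric background that pulls the mean
  toward zero. Restricting firing onsets to $\pm 1$ s around task events
  removes background pairs but exposes the crossing-delay asymmetry: the
  97.5th-percentile acceleration threshold is crossed later in a rising
  waveform than the 95th-percentile rate threshold, so the
  events-restricted mean lag overshoots the true lead. The whole-session
  estimate under the default generator recovers a 35 ms lead to within
  ~10–15 ms.
* The lag scan is unbiased at the 20 ms step resolution under the default
  generator once the two conventions above (center-of-frame indexing,
  shift-independent sampling) are in place; with 200-trial sessions it
  recovers a 100 ms lead within one step in ≳ 90% of runs.

# Problem sizes used in the shipped checks

The test suite exercises the full recovery loop at desk scale, chosen so
the whole suite stays fast while estimates remain well-resolved:
response-ratio recovery uses 200-trial sessions with 20 seeds per gain;
null calibrations use several hundred simulated sessions of 40–60
trials; lag-scan recovery uses 200-trial and onset recovery 150-trial
sessions over 20 seeds. The acceptance script regenerates the cue and
behavior quantities from scratch (10 × 1,000-trial sequences; 20
simulated behavioral runs).

# Known limitations

* Poisson spiking has no refractory period; at high couplings two
  thinned candidates can fall within a real neuron's refractory window.
* The agent's strategy space is binary (visual rule vs. turn rule); real
  animals mix strategies within blocks.
* The 2-D tracking is emitted on the maze skeleton; corner frames
  shorten chord distances by a sub-frame amount.
* The onset detectors' absolute calibration depends on waveform shape
  and signal occupancy (see above); their lags are comparable across
  conditions analyzed identically, not absolute physiological latencies.
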