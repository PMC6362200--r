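# lcmaze

Analysis and simulation of locus coeruleus (LC) single-unit activity in a
self-paced T-maze discrimination task with unsignalled rule shifts.

LC neurons fire tonically at 1–3 Hz and burst phasically around salient
events. In the T-maze task, each trial begins when the rat crosses a
central-arm photodetector (PD), lighting a visual cue (VC) on one side;
the reward-arm PD triggers reward delivery and the return-arm PD switches
the cue off. The rewarded contingency alternates between a visual rule
(choose the lit side) and a spatial rule (always one arm), switching
automatically when the animal reaches 18 correct of the last 20 trials.
`lcmaze` implements, for people analyzing such recordings (and for anyone
wanting a calibrated synthetic testbed):

* **Windowed response ratios** — peak pre-event firing over a common
  baseline (mean rate in $[-1.5, -1)$ s before VC onset): VC onset and VC
  off use the larger of the two 0.5 s pre-event bins, the reward PD the
  single $[-0.5, 0)$ s bin, and the reward site the $[1, 2)$ s
  post-reward-PD window; one-sample t tests compare session ratios to 1.
* **Rule-shift comparison** — Wilcoxon rank-sum (permutation p-value) on
  post-VC-onset spike counts before vs. after the first rule change, and
  Welch t tests with Holm–Bonferroni adjustment between trial blocks.
* **Firing–acceleration coupling** — LED-tracking speed/acceleration,
  200 ms paired bins around each PD crossing (plus a matched analysis
  outside all event windows), z-scored OLS on positive accelerations,
  a 20 ms-step lag scan, and percentile-threshold onset detection with a
  ±500 ms onset-triggered cross-correlogram, whose positive mean lag
  means firing leads movement:

  $$\hat\Delta = \arg\max_s \; r\big(\text{rate}(t),\, a(t+s)\big)$$

* **A synthetic session generator** — constrained pseudorandom cue
  sequences, a criterion-driven rule-switching behavior agent, maze-path
  kinematics with pre-PD acceleration bumps, and inhomogeneous-Poisson
  spikes with intensity
  $\lambda(t) = b\,g_{ev}(t)\,s_{rwd}(t) + \gamma \max(0, a(t+\delta))$,
  so that event gains, reward-site suppression and the firing lead
  $\delta$ are known ground truth for every estimator.

See the methods vignette (`vignettes/lcmaze-methods.Rmd`) for the models,
parameter defaults and numerical conventions.

## Worked example

```r
library(lcmaze)

# a 60-trial synthetic session with the default task structure
s <- simulate_session(sim_config(n_trials = 60, seed = 1))
s
#> LC T-maze session
#>   1 unit(s), 60 trial(s), 3 block(s), 236 event(s)
#>   tracking: 30280 frames over 999.2 s
#>   rat: synthetic
#>   synthetic, seed 1

response_ratio(s, "VC_ONSET")
#> VC_ONSET response ratio: 2.193 (peak 9.87 Hz / baseline 4.50 Hz, 60 trials)
#>  windows: max of [-1,-0.5), [-0.5,0) pre VC_ON; baseline [-1.5,-1) pre VC_ON
response_ratio(s, "REWARD_SITE")
#> REWARD_SITE response ratio: 0.170 (peak 0.77 Hz / baseline 4.50 Hz, 60 trials)
#>  windows: [1,2) post RWD_PD; baseline [-1.5,-1) pre VC_ON

# firing leads acceleration: the generator's delta is 35 ms
kin <- session_kinematics(s)
lag_scan(s, "VC_ON_PD", kin = kin)
#> Lag scan (VC_ON_PD): best shift +20 ms (r = 0.607)
#>   positive shift = firing precedes acceleration

fo <- detect_firing_onsets(s$spikes[[1]]$times, range(s$tracking$time_s))
ao <- detect_accel_onsets(kin)
onset_lag_crosscorr(fo, ao)
#> Onset cross-correlogram (session): mean lag +36.8 ms over 128 pairs
#>   positive lag = acceleration onset after firing onset
```

The VC-onset ratio exceeds 1 (phasic activation before trial
initiation), and both timing estimators report a positive lead of firing
over acceleration — the scan at its 20 ms step resolution, the
onset-correlogram mean close to the generator's true 35 ms. Note that
under the full default model the baseline window itself sits mid-run, so
acceleration coupling raises the 4.5 Hz "baseline" above the 2 Hz tonic
rate and pushes the reward-site ratio below the generator's suppression
factor 0.44; with coupling disabled the ratios recover the generator
parameters directly (that recovery is what the acceptance tests check).

The same flow works from the command line over on-disk session bundles
(plain CSV/JSON):

```sh
Rscript inst/cli/lcmaze.R simulate --config cfg.json --out session1/
Rscript inst/cli/lcmaze.R analyze  --config session1/ --out results1/ --seed 1
Rscript inst/cli/lcmaze.R report   --config results1/
```

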