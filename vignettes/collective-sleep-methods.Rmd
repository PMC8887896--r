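---
title: "Scoring sleep and collective night-time dynamics from biologger data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring sleep and collective night-time dynamics from biologger data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accsleep)
```

## The problem

Wild, group-living animals such as baboons sleep in refuges (trees, cliff
ledges) where direct observation of sleep is impractical. Collar-mounted
triaxial accelerometers make sleep observable indirectly: sustained low
overall body movement is a reliable, if imperfect, correlate of sleep.
`accsleep` implements an actigraphy-style scoring pipeline for
burst-sampled collar accelerometry together with the group-level analyses
that become possible when most members of a social group are tracked
simultaneously: synchronization of nocturnal wakefulness, fidelity to
particular sleep trees, and wake contagion between tree-mates.

## Activity measure and sleep scoring

The movement intensity measure is VeDBA (vectorial dynamic body
acceleration). For each burst, the static (gravitational) component of
each axis is estimated by a centered running mean over 0.7 s (window
truncated at burst edges), the dynamic component is the raw signal minus
that estimate, and VeDBA is the Euclidean norm of the three dynamic
components. The per-minute series used everywhere downstream is
`log(mean VeDBA + 1e-6)`, the natural log of the burst-mean with a small
offset guarding against perfectly still bursts. The log base is
documented because the classification threshold multiplies a percentile
by a constant, an operation that is not invariant to the base.

Scoring operates on noon-to-noon days (local 12:00 to next 12:00, 1440
one-minute epochs), so each day contains exactly one nocturnal sleep
period. Per day and individual:

1. **Threshold.** The 10th percentile (linear-interpolation definition,
   `stats::quantile` type 7) of the day's non-missing log VeDBA, times
   1.125. Days with fewer than 1320 non-missing epochs are unscorable.
   The multiplier raises the threshold only when log VeDBA is positive;
   applied to a negative percentile it lowers it. The formula is applied
   literally either way (a regression test pins this behaviour), and the
   synthetic generator emits acceleration in raw sensor-count units - as
   field collars record - for which log VeDBA is positive.
2. **Sleep-period detection.** A rolling 9-min median of log VeDBA is
   computed (window shrinking symmetrically at edges, missing values
   excluded, output missing where input is missing). Runs of at least
   30 min of below-threshold median are candidate sleep blocks; blocks
   separated by at most 45 min merge, and the longest merged period is
   the sleep period (SPT window), ties resolved to the earliest. Its
   boundaries are sleep onset and waking.
3. **Epoch classification.** Independently of the sleep period, runs of
   at least 3 consecutive epochs of raw below-threshold log VeDBA are
   labelled sleep; other observed epochs are wake. Sleep-labelled
   minutes between 07:30 and 17:30 are napping.
4. **Night metrics.** Total sleep time (sleep epochs inside the SPT),
   efficiency (TST over SPT duration), and fragmentation: wake bouts of
   at least 2 min, counted as distinct only when separated by at least
   3 sleep epochs, per hour of sleep. Onset and waking are also
   expressed relative to astronomical twilight (sun 18 degrees below the
   horizon), computed from the standard NOAA solar-position equations.
5. **Quality control.** Days missing at least 120 bursts lose all
   metrics including napping; days with at least 20 consecutive missing
   bursts additionally lose the SPT-derived metrics but keep napping,
   which does not depend on the sleep period.

### Missing epochs

Missing epochs are represented explicitly and never interpolated. For
*epoch classification* they break below-threshold runs: an interrupted
run is not assumed continuous, which is the conservative choice for
labels. For *sleep-period detection* the default bridges a missing epoch
whose nearest observed neighbours on both sides are below threshold.
Without bridging, one dropped burst in the first or last half hour of
the night truncates the detected sleep period by up to 30 min, making
total sleep time discontinuous in a single burst - the same reason
canonical actigraphy toolchains impute short gaps, and the reason the
20-consecutive-burst QC rule exists for the long ones.
`scoring_params(missing_bridge_blocks = FALSE)` restores strict
breaking.

## Sleep sites, travel, and fidelity

The nightly sleep location is the componentwise median of the first 10
GPS fixes before 06:15 (fewer than 10 fixes excludes the night). A
location inside a traced crown polygon is assigned to that tree;
otherwise to the nearest crown within 10 m, beyond which the night is
excluded. All geometry runs in a local equirectangular projection in
meters about the site centre; at site extents of a few kilometers the
projection error is far below the 5 m and 10 m thresholds. Daily travel
distance retains a fix only when at least 5 m from the last retained fix
(suppressing jitter accumulation) and applies the coverage rule (first
fix by 07:30, last after 17:00). Note that on dense (about 1 Hz) tracks
with meter-level jitter the discretized distance still overestimates a
path's nominal length by several percent, because each retained step's
noise is counted; tests therefore validate the discretization on tracks
whose fix spacing is comparable to the 5 m resolution.

Fidelity to sleep trees is tested with Shannon entropy, in nats, of each
individual's tree-use distribution (the base cancels from the
comparison). The null preserves the social structure of each night:
within every night the observed multiset of occupied tree slots is
reshuffled uniformly among the individuals present, so per-night
occupancy is conserved exactly. Empirical entropies of eligible
individuals (at least 4 nights, first 14 nights of data) are compared to
the pooled permuted entropies with a one-tailed two-sample
Kolmogorov-Smirnov test, the alternative being that empirical entropies
are stochastically smaller (fidelity means lower entropy). Pooling all
permutation rounds into one comparison sample is the default; per-round
group means are available. The asymptotic one-sided KS p-value is
slightly conservative at group sizes around 26, which the calibration
checks quantify (empirical size about 0.02-0.03 at nominal 0.05). The
fidelity index is the observed number of nights in a tree minus its
permutation mean; indices sum to zero within each individual by
construction.

## Collective synchronization

The collective analyses subset to 21:00-05:00 (480 epochs), times that
lie strictly inside every individual's sleep period. Two statistics
summarise the group: the proportion of epochs (across nights) with at
least one non-missing individual awake, and the mean proportion of the
group in its modal state per epoch ("synchronization"; the modal-share
reading of the ambiguous phrase is the default, a pairwise-agreement
variant being a trivial change of statistic). Epochs with no observed
individual are excluded.

Two null models give reference distributions:

* **Time shift.** Every individual-night state vector is circularly
  shifted by an independent uniform offset in 1..479; missing epochs
  travel with the vector. Each individual-night's wake total and
  autocorrelation are conserved exactly; only cross-individual alignment
  is destroyed. The offset 0 is excluded.
* **Night permutation.** Each individual's nights are relabelled by an
  independent permutation, clock time kept. This controls for a shared
  stereotyped schedule, which the time shift cannot.

The permutation p-value is the proportion of null values at least as
extreme as the empirical value in the direction of interest (wakefulness
spread *below* null, synchronization *above* null), with resolution
floor 1/n_iter; a zero count prints as `< 1/n_iter`. Wake contagion
produces exactly this signature: fewer epochs with someone awake, and
more of the group in the same state, than time-shifted data.

Dyadic synchronization is, per pair and night, the share of co-observed
epochs in the same state, flagged by whether the pair shared a tree.

## Arousal-response table

The wake-contagion analysis is epoch-level: for each focal individual
asleep during the three preceding epochs (within 21:00-05:00, first 14
nights), the outcome is waking at t and the key predictor is whether any
tracked same-tree group-mate was awake at t-1 (awake state, not onset;
rows with no observable group-mate are dropped). Previous-night total
sleep time and fragmentation enter as individual-mean-centered
covariates with their interactions. The package fits an ordinary
logistic regression with cluster-robust (by focal) standard errors as a
stand-in exposing the sign and significance surface; hierarchical
Bayesian estimation is deliberately out of scope, and the exported table
is ready for any mixed-model backend.

## The synthetic generator

Every stage is validated against a generator with known ground truth
(`sim_config()`, `generate_group_truth()`, `render_accel_bursts()`,
`render_gps_fixes()`, `inject_missingness()`, `simulate_dataset()`).
Design choices that matter:

* **Three latent states.** Sleep, resting wakefulness, and active
  wakefulness, even though scoring is binary. Resting wakefulness is
  emitted at sleep-like acceleration, so the generator reproduces the
  known actigraphy bias: motionless wake is misread as sleep, and
  accuracy falls as the resting-wake share rises.
* **Sleep window.** Onset ~ N(19:00, 15 min) and waking ~ N(06:05,
  15 min), truncated at 2 sd. The sleep period is then about 11.1 h and
  21:00-05:00 falls strictly inside it on every night - the same
  property that motivated the empirical choice of that window.
* **Arousal process.** Spontaneous wake bouts form a renewal process:
  1.3 arousals per hour, geometric durations (mean 3 min, capped at
  15), and at least 40 min of sleep between arousals, with no arousals
  within 40 min of onset or waking. The refractory interval encodes
  consolidated sleep between discrete arousals and, importantly,
  exceeds the scorer's 30-min block length plus its 9-min median
  window: detection of onset and waking is then structurally exact on
  noise-free data. A pure Poisson process (set the gap to 0) produces
  occasional bout clusters whose alternation of short sleep runs and
  breaks exceeds the 45-min merge and splits the night - with rates
  matched to field estimates this happens on several percent of nights,
  so the renewal form is the default. The price is a sparser bout
  process than the field estimate (about 0.9 scored bouts per hour of
  sleep and 93% efficiency versus roughly 1.8 and 85% in wild groups).
* **Wake contagion.** When a same-tree group-mate transitions to
  wakefulness at t-1, each tree-mate asleep for at least the last 5 min
  wakes at t with `coupling_prob` (default 0.05, consistent with the
  modest odds ratios reported for wild groups; cascades propagate but
  the refractory damps them). Responsive arousals are brief (mean
  2 min, capped at 4 min, below the rolling-median majority), so
  contagion perturbs epoch labels and synchronization without
  fragmenting sleep-period detection. Unbounded contagion durations
  with large same-tree groups make the wake process supercritical
  (each arousal triggering more than one), which contradicts the
  consolidated sleep being emulated.
* **Emissions.** Log burst-mean VeDBA per state: sleep 2.2 (sd 0.06),
  resting wake 2.25 (sd 0.06), active 5.5 (sd 0.5), in log-count units.
  The burst renderer scales a fixed triaxial waveform so that the
  pipeline's own VeDBA computation recovers the drawn value exactly,
  making emission parameters directly testable. With these defaults the
  Q10 x 1.125 threshold sits about 3.8 sd above the sleep mean: epoch
  errors are dominated by the intended resting-wake bias rather than by
  emission noise.
* **Missingness.** Bursts drop independently at 0.005 by default
  (clustered outages are injected explicitly via
  `inject_missingness()`'s run specification, mirroring how real collar
  failures arrive in chunks and exercising the QC rules).

What the generator does *not* emulate: biomechanics of locomotion,
terrain, predator events, diurnal activity structure beyond a constant
active state, and temporally correlated emission noise. Passing the
recovery checks therefore shows the pipeline is a faithful
implementation of the scoring rules, not that those rules attain any
particular accuracy on real animals - that question belongs to
field-validation studies.

## Problem sizes used in the checks

The test-suite and `scripts/acceptance.R` run at deliberately scaled
problem sizes: recovery on 26 individuals x 10 nights; fidelity-test
calibration on 400 (tests) or 200 (script) groups of 26 individuals x
14 nights x 10 trees with random tree choice; synchronization
calibration on groups of 12 x 10 x 4; power on 100 (tests) or 60
(script) coupled groups (coupling 0.3) of 12 x 10 x 3, with 100
resampling iterations inside each simulated dataset and 1000 wherever a
single dataset is analysed. Calibration and power runs consume latent
state matrices directly; the rendering-scoring path is validated
separately by the recovery checks.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_individuals = 6, n_nights = 6, n_trees = 3,
                  tree_preference_concentration = 10, seed = 1)
ds <- simulate_dataset(cfg, "sim_demo")
pc <- pipeline_config(accel = ds$accel, gps = ds$gps, trees = ds$trees,
                      out_dir = "sim_demo/out", n_iter = 200,
                      n_perm = 200, seed = 1)
res <- run_pipeline(pc)
res$sync$time_shift$mean_prop_synchronized
res$fidelity
```

## Known limitations

* The scorer cannot distinguish motionless wakefulness from sleep; all
  downstream totals inherit that bias by design.
* The sleep-period algorithm is sensitive to the spacing of wake bouts:
  alternations of sub-30-min quiet runs and breaks longer than 45 min in
  total split the night, and the longest-period rule may then pick a
  fragment. The QC rules catch the missing-data route to this failure
  but not the behavioural one.
* The one-sided two-sample KS p-value is asymptotic and mildly
  conservative at realistic group sizes.
* Twilight times are accurate to about a minute; polar latitudes where
  astronomical twilight vanishes raise an error.
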