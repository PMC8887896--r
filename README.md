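# accsleep

Accelerometry-based sleep scoring and collective sleep analysis for
group-living animals.

Collar-mounted biologgers let field researchers follow the sleep of wild
animals — and, when most of a social group is tracked at once, the
*collective* structure of sleep: do group-mates stagger their wakefulness
(sentinel-style vigilance) or wake together? Do individuals return to the
same sleep trees night after night, and does a neighbour's movement wake
them? `accsleep` implements the full analysis chain for burst-sampled
triaxial accelerometry and GPS from such a group, plus a synthetic
biologger-data generator with known ground truth so every stage can be
validated end to end without field data.

## What it computes

**Sleep scoring (per individual, per noon-to-noon day).** Movement
intensity is VeDBA — the norm of the dynamic (gravity-removed)
acceleration, the static component estimated by a 0.7 s running mean —
summarised as the natural log of the burst-mean per minute epoch. The
classification threshold is

    threshold = Q10(log VeDBA) × 1.125

with Q10 the linear-interpolation 10th percentile of that day's series.
Runs of ≥ 30 min in which the 9-min rolling median stays below threshold
are sleep blocks; blocks ≤ 45 min apart merge, and the longest merged
period is the sleep period (onset → waking). Independently, runs of ≥ 3
below-threshold minutes are sleep epochs, giving total sleep time,
efficiency, fragmentation (wake bouts ≥ 2 min, separated by ≥ 3 sleep
epochs, per hour of sleep), napping (07:30–17:30), onset/waking relative
to astronomical twilight, and QC flags for days missing ≥ 120 (or ≥ 20
consecutive) bursts.

**Sleep sites.** Nightly sleep location = median of the first 10 GPS
fixes before 06:15; assignment to tree-crown polygons (nearest crown
within 10 m); 5 m-discretized daily travel distance; NOAA solar-position
twilight times.

**Tree fidelity.** Shannon entropy H = −Σ p log p of each individual's
tree use against a within-night permutation null (per-night tree
occupancy conserved exactly), compared with a one-tailed two-sample
Kolmogorov–Smirnov test; per-tree fidelity indices (observed − expected
nights).

**Collective synchronization.** In the 21:00–05:00 window: the
proportion of epochs with ≥ 1 individual awake and the mean proportion
of the group in the modal state, each against a circular time-shift null
(conserves every individual-night's wake total and autocorrelation) and
a night-permutation null (controls for shared schedules), with
permutation p-values; dyadic same-state scores with same-tree flags.

**Arousal response.** The epoch-level design table for wake contagion —
focal asleep the three preceding epochs, outcome waking at *t*,
predictor any same-tree group-mate awake at *t − 1*, previous-night
relative covariates — and an ordinary-logistic stand-in fit with
cluster-robust errors (the table is ready for any mixed-model backend).

## Worked example

```r
library(accsleep)

cfg <- sim_config(n_individuals = 6, n_nights = 6, n_trees = 3,
                  tree_preference_concentration = 10, seed = 1)
ds <- simulate_dataset(cfg, "sim_demo")          # accel CSV, GPS CSV, GeoJSON, truth
pc <- pipeline_config(accel = ds$accel, gps = ds$gps, trees = ds$trees,
                      out_dir = "sim_demo/out", n_iter = 200,
                      n_perm = 200, seed = 1)
res <- run_pipeline(pc)                          # ingest → score → sites →
                                                 # fidelity → sync → arousal
nm <- res$scored$nights
sprintf("mean TST %.1f h, efficiency %.1f%%, fragmentation %.2f bouts/h",
        mean(nm$tst_min)/60, 100*mean(nm$efficiency), mean(nm$fragmentation))
#> "mean TST 10.4 h, efficiency 93.8%, fragmentation 0.83 bouts/h"

res$sync$time_shift$prop_any_awake
#> <null_report> prop_any_awake (time_shift): empirical 0.3097,
#>   null 0.3255 [0.3132, 0.3378], p = 0.01 (le)
res$fidelity
#> <fidelity_report> 6 eligible individuals, 200 permutations
#>   one-tailed KS D = 0.7767, p = 0.0007447
fit <- res$arousal$fit
fit[fit$term == "groupmate_awake_prev", ]
#>                   term estimate std_error   z p_value
#> 2 groupmate_awake_prev    0.342     0.155 2.2  0.0278
```

Read: the group spends *fewer* epochs with at least one member awake
than time-shifted data (wakefulness is synchronized, not staggered,
p = 0.01); individuals reuse particular trees far more than the
within-night reshuffling null allows (KS p ≈ 7 × 10⁻⁴); and a focal's
odds of waking rise when a tree-mate was awake in the previous minute
(logit +0.34). Every run also writes per-stage CSV/JSON outputs and a
manifest under `out_dir`.

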