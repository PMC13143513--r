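# avoidr

Does a prey species temporarily avoid a site after a predator has passed
through? `avoidr` answers this question for camera-trap surveys. It is aimed
at ecologists analysing motion-triggered detection tables from multi-camera
monitoring programmes who want a calibrated, reproducible test for *reactive
avoidance* — depressed prey detection counts in the hours to days after a
predator detection — together with the power analysis needed to interpret a
negative result.

## The method

The unit of analysis is a **detection** (one motion-triggered capture event
of one species at one camera) and a **roll** (the continuous operating
interval of a camera between two services). For a prey species *B* and a
predator species *P* at one site:

1. **Filtering.** Rolls with a lifespan < 30 days are dropped. Predator
   detections are passed through a 30-min time-to-independence filter that
   collapses each chain of detections with consecutive gaps < 30 min to its
   *central* element (keeping the centre, not the first, preserves symmetry
   of the before/after windows), and predator detections within 72 h of a
   roll's start or end are excluded so every retained event has a complete
   observation window. Prey detections are not filtered.
2. **Statistic.** For each retained predator detection at time *t₀*, prey
   detections at the same camera are counted in six 24-h blocks
   [−72,−48), [−48,−24), [−24,0), (0,24], (24,48], (48,72] hours relative
   to *t₀*; the statistic is the sum of these counts over all predator
   events, per block.
3. **Null model.** Under non-avoidance, the *date* of each predator
   detection is exchangeable within its roll. Each event is relocated to a
   uniformly drawn eligible date (the margin-trimmed roll interval) while
   its clock time is preserved exactly, keeping the species' diel activity
   pattern intact; the statistic is recomputed; this is repeated 1000 times.
4. **Inference.** For each after-block the empirical one-sided p-value is
   the proportion of iterations with a count ≤ the observed count (few prey
   after a predator = avoidance); for before-blocks it is the proportion
   ≥ the observed count (many prey before a predator = e.g. a predator
   following its prey). Ties count on both sides; p-values are reported raw
   at α = 0.05.
5. **Power.** Because a negative result may just reflect sparse data, the
   prey detections can be repeatedly subsampled to a target size and the
   test re-run, summarising how often significance survives.

A synthetic survey generator (inhomogeneous Poisson detection processes
with hourly diel profiles, thinning-injected avoidance, optional
predator-following and burst triggering) provides ground-truthed data for
validating the whole pipeline.

## Worked example

```r
library(avoidr)

# a synthetic survey with strong injected avoidance:
# prey intensity x0.2 for 24 h after each predator passage
scn <- scenario(n_cameras = 30, roll_days = 90, prey_rate = 3,
                predator_rate = 0.5, avoidance_effect = 0.8, seed = 7)
sv  <- simulate_interacting(scn)
fit <- run_site_test(sv, "baboon", "lion",
                     test_params(n_iterations = 500, seed = 3))
fit
#> <avoidance_test> site S1 | prey baboon | predator lion
#>   1220 predator event(s) over 30 roll(s), 500 iterations, seed 3
#>     window   side observed       p
#>  [-72,-48) before     2602   0.492
#>  [-48,-24) before     2654   0.232
#>    [-24,0) before     2560   0.696
#>     (0,24]  after      742 0.000 *
#>    (24,48]  after     2712   0.968
#>    (48,72]  after     2547   0.300
```

The injected effect is recovered exactly where it was planted: the observed
count in the (0,24] block (742) sits far below every one of the 500 null
counts (p = 0.000, starred at α = 0.05), while the remaining five blocks are
consistent with the null. `tidy(fit)` returns the full-precision per-block
table, `glance(fit)` a one-row summary, `autoplot(fit)` the null-density
panels with the observed count marked, and `report_table(list(fit, ...))`
formats many tests as a site × prey × predator significance table.

`downsampling_study(sv, "baboon", "lion", n = 200, n_subsets = 20, ...)`
re-runs the test on 20 random subsets of 200 prey detections and reports,
per block, the mean ± SD of p and the fraction of subsets still significant.

A YAML-driven pipeline (`read_config()` + `run_pipeline()`, stages
`simulate`, `preprocess`, `test`, `power`, `report`) and a thin CLI wrapper
(`inst/cli/camtrap-avoidance.R`) cover scripted use; every stage writes CSV
artifacts plus a JSON manifest and is byte-deterministic given the seed.

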