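---
title: "Date-randomization tests for reactive avoidance in camera-trap data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Date-randomization tests for reactive avoidance in camera-trap data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avoidr)
```

## The question and the model

Reactive avoidance is the temporary avoidance of an area by a prey species
after a predator has passed through it. With camera traps it shows up — if
it exists — as a deficit of prey detections at a camera in the hours or
days following a predator detection at the same camera. The difficulty is
that raw before/after comparisons confound avoidance with everything else
that structures detection rates: diel activity cycles of both species,
heterogeneity among cameras, and the finite span of each camera **roll**
(the continuous operating interval between two services, typically about
three months).

`avoidr` addresses this with a within-roll date-randomization test. For one
prey species and one predator species at one site, the observed statistic
is the total number of prey detections in consecutive 24-h blocks around
each retained predator detection, summed over events:
[−72,−48), [−48,−24), [−24,0) hours before and (0,24], (24,48], (48,72]
hours after (a prey detection exactly at the reference instant belongs to
no block; before-blocks are closed on the left, after-blocks on the right,
symmetric about the excluded instant). The null hypothesis — non-avoidance
— implies the *date* of a predator detection is exchangeable within its
roll. Each randomization iteration therefore relocates every predator event
to a date drawn uniformly from the eligible dates of its roll while
preserving the event's clock time exactly, so the predator's diel activity
pattern is untouched and cannot masquerade as (or mask) avoidance. The
empirical one-sided p-value of an after-block is the proportion of
iterations with a count less than or equal to the observed count; for
before-blocks the direction is reversed (an excess of prey *before*
predator detections is the signature of a predator following its prey).
Ties count on both sides, which makes the p-value conservative
(super-uniform) and guarantees the two one-sided p-values of a block sum to
at least one.

No correction for multiple testing is applied: the six blocks of a test are
reported raw and flagged at α = 0.05, and each site × prey × predator
combination is its own test. Beyond 72 h, attributing prey absence to a
particular predator passage becomes ambiguous, which is why the window
stops there.

## Filtering rules and their rationale

Three filters precede the test, with these defaults (`test_params()`):

* **Minimum roll lifespan, 30 days.** Dates in a short roll can only be
  shuffled within a narrow window, so the null distribution degenerates;
  rolls with a lifespan strictly below 30 days are dropped along with every
  detection on them (the filter is roll-level, matching the roll-level
  randomization). The boundary is inclusive: exactly 30.0 days is kept.
* **Time-to-independence, 30 min, predators only.** Camera triggers arrive
  in bursts; chains of same-species detections with consecutive gaps
  strictly under 30 min collapse to one event. The *central* element
  (position ⌈k/2⌉ of a size-k chain, the earlier middle one for even k) is
  retained rather than the customary first element, because the test looks
  both backward and forward in time and the representative should not be
  biased toward either side. Chaining is transitive — three detections 29
  min apart form one cluster spanning 58 min — because a cluster is defined
  by consecutive gaps, not by a window anchored at the first event. Prey
  detections are deliberately not collapsed: the statistic counts prey
  presence, and collapsing it would discard signal rather than remove
  pseudo-replicated *reference points*.
* **Edge exclusion, 72 h, predators only.** Predator events within 72 h of
  a roll's start or end lack a complete ±72-h observation window and are
  excluded; the retained interval is closed, `[start + 72 h, end − 72 h]`.

Randomized dates are confined to the same margin-trimmed interval. This is
a deliberate design choice: observed and relocated events then have
identical exposure, so no artifactual count deflation appears near roll
edges. Relocations are drawn independently per event, uniformly and with
replacement across eligible dates (two events of a roll may land on the
same date) — the simplest exchangeable null; since every observed event
survives edge exclusion, its own date is always a member of its eligible
set, which is what makes observed and null statistics exchangeable under
the null.

Prey counts are camera-local (only prey detections from the predator
event's own camera contribute), and a prey detection falling in the windows
of two predator events is counted for both — the statistic is a plain sum
over events.

A companion diagnostic, `co_detection_rate()`, reports the percentage of
(camera, calendar-day) pairs with a predator detection on which a *second*
predator species was also detected; when this is low, testing each predator
separately carries little risk of cross-attribution.

## The synthetic survey generator

`scenario()` + `simulate_interacting()` generate ground-truthed surveys so
every stage is testable without field data. Detection processes are
inhomogeneous Poisson with piecewise-constant hourly intensity proportional
to a 24-weight diel profile and scaled to integrate to the daily rate;
sampling is by thinning of a homogeneous process at the peak intensity, so
acceptance probabilities are bounded by one by construction. Avoidance is
injected by thinning the baseline prey process: within the union of
`avoidance_duration`-hour windows after predator events at the same camera,
each prey point survives with probability `1 − avoidance_effect` (windows
do not compound, so the effect size stays interpretable as the per-window
rate reduction). Attraction — a predator following its prey, the mechanism
that would produce elevated prey counts *before* predator detections —
multiplies the predator intensity by `1 + attraction_effect` after baseline
prey events. Burst triggering adds 1–3 extra detections within ±15 min of
a parent event purely to exercise the independence filter.

Each component (predator process, baseline prey process, avoidance
thinning, bursts) draws from its own substream derived deterministically
from the scenario seed, so the whole survey is bit-reproducible and the
null scenario (`avoidance_effect = 0, attraction_effect = 0`) is exactly
the composition of two independent `simulate_species()` runs.

The default scenario — 20 cameras, one 90-day roll each, a diurnal prey at
1 detection/day, a mostly nocturnal predator at 0.3/day — represents a
medium-density site in a savanna-style monitoring programme. What the
generator does *not* emulate: spatial structure (cameras are independent;
there is no movement model, so cross-camera avoidance cannot arise),
detection-probability differences among cameras or over time, seasonality,
and multi-predator interactions beyond the single attraction kernel.
Passing calibration and power checks on these surveys therefore shows the
*test machinery* is sound under the stated stochastic structure, not that
any particular field system satisfies it.

## Numerical choices

* All timestamps are naive local clock time stored as UTC `POSIXct`, so
  second-of-day arithmetic is exact and no daylight-saving discontinuities
  exist; analysis is local-clock based because diel timing is the quantity
  being preserved.
* Block counting runs on numeric seconds via `findInterval` over the sorted
  camera-local prey vector; per predator event the counts are precomputed
  for every eligible date, after which each randomization iteration is a
  table lookup. This makes 1000 iterations on hundreds of events a
  sub-second operation and — as a side effect — makes the exhaustive
  single-event null available for validation at no extra cost.
* One master seed drives everything; substreams for simulation components,
  subsets and iterations are derived with a fixed integer mixer, so results
  are reproducible end to end and independent of evaluation order across
  components.
* Degenerate inputs are explicit: a margin of at least half the roll length
  yields an empty retained set with a warning; a roll with an empty
  eligible-date set for some clock time is excluded from the test with a
  warning; a prey × predator pair with no roll containing both species
  returns a `no_data` result, not a p-value; an all-zero diel profile and
  `n > available` downsampling are errors.

## The downsampling power study

`downsampling_study()` subsamples the prey detections (never the predator
events) to a target size `n`, uniformly without replacement, re-runs the
complete test on each of `n_subsets` subsets with an independent derived
substream for both the subsetting and the randomization, and summarizes
per-block `mean_p`, `sd_p` (undefined and reported `NA` for a single
subset) and the fraction of subsets significant at α. Mean p in the first
after-block is non-increasing in the subset size under a fixed avoidance
scenario, and with no injected effect the significant fraction stays near
α at every `n` — both properties are exercised in the test suite.

## Validation at the study conditions

The acceptance suite (and `scripts/acceptance.R`, which recomputes the same
quantities from scratch) checks, at these problem sizes:

* **Type-I calibration** — 200 replicate null surveys (20 cameras × 90 d,
  prey 1/day, predator 0.3/day, distinct diel profiles), 500 iterations per
  test: per-block rejection at α = 0.05 must lie in [0.01, 0.09].
* **Power and specificity** — 100 replicates with `avoidance_effect = 0.8`
  over 24 h (prey 3/day, predator 0.5/day, 30 cameras): rejection ≥ 0.8 in
  the (0,24] block, calibrated rejection in (48,72].
* **Oracle agreement** — one roll, one predator event, 10 eligible dates:
  per-block p from a 10,000-iteration Monte-Carlo null within 0.02 of
  exhaustive enumeration over all date assignments.
* **Downsampling significance loss** — `avoidance_effect = 0.6` with ~2000
  prey detections and ~50 predator events (20 cameras × 90 d, prey
  1.1/day, predator 0.03/day — predator sparsity of the order seen in real
  savanna surveys; chosen a priori from a normal-approximation power
  calculation giving ≈ 0.98 power at full size and ≈ 0.3 at n = 200): the
  (0,24] block significant in ≥ 80% of 20 replicate surveys, and the
  significant fraction over 20 subsets of n = 200 at most half the full
  fraction.
* **Conservation** — 1000 relocations preserve per-roll event counts and
  time-of-day multisets exactly, and per block
  `#{null ≤ obs} + #{null ≥ obs} = N + #{null = obs}`.

These sizes are the package's chosen validation conditions; they keep the
complete suite to a few minutes on a single core.

## Known limitations

* The test is camera-local and temporal only; spatial displacement to
  neighbouring sites is invisible to it.
* The null assumes date-exchangeability within a roll; strong seasonal or
  weather-driven trends in predator activity within a roll would violate it.
* Raw p-values across many site × species combinations invite multiplicity
  caution; the package flags, it does not correct.
* Power at realistic detection rates is modest — that is precisely what the
  downsampling study quantifies — so a non-significant result is evidence
  of absence only jointly with an adequate-power demonstration.
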