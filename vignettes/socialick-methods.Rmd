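---
title: "Methods: session engine, lick microstructure, and social proximity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: session engine, lick microstructure, and social proximity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socialick)
```

`socialick` models a social operant chamber in which one or two rats,
each carrying an implanted RFID tag, drink from an active and an inactive
spout. This vignette is the package's account of the underlying models,
the parameters that matter, what the synthetic-data generator does and
does not emulate, and the numerical and design choices that were genuinely
open.

## The session model

A session is three timestamped event streams over a common clock
(integer-friendly milliseconds from session start): RFID detections, licks
and rewards, plus a configuration and an animal registry. Streams are kept
sorted; events at the same millisecond keep stream order, and RFID
detections are logged before licks, so a simultaneous read can still
attribute the lick. Detection frames from the optional camera use seconds
(frame index × 2 s capture period) — the two time bases never mix.

### Tag dialects

The two antennas report the same physical chip differently: 8 hexadecimal
digits on the active side, 10 on the inactive side. How the two encodings
relate is reader-firmware detail, so the registry stores both forms
explicitly per animal and `canonicalize_tag()` only ever looks them up —
nothing is inferred from string arithmetic. Duplicate tags are a
configuration error caught at registry construction.

### Debouncing

The reader cannot resolve a second, different tag within its ~0.25 s dead
time, so `debounce_rfid()` drops a different-tag read arriving within
`rfid_refractory_ms` (default 250, strict inequality keeps a read at
exactly 250 ms + 1) of the previously *kept* read on the same antenna.
Same-tag repeats are kept: they mean one head is simply staying in the
loop, and the attribution rule depends on them.

### Lick attribution

Each lick on a spout is assigned to the animal of the latest detection on
that spout's antenna at or before the lick, provided the gap is at most
`assignment_window_ms`. The 3 s default window is inclusive at exactly
3000 ms ("a maximal delay of 3 s" reads as *up to and including*). A lick
with no qualifying detection becomes `RatUnknown`. Unattributed licks are
recorded — they are a quality-control signal — but never advance any
schedule: a device must not reward an animal it cannot identify. The
implementation is a two-pointer scan (`findInterval`); the test suite
holds it against a brute-force all-pairs oracle on hundreds of random
streams.

### Schedules

Counters are strictly per animal; there is no cross-animal reset, so an
animal's reward total is exactly `floor(assigned active licks / ratio)`
under FR. Variable-ratio requirements are drawn uniformly from
`{ratio - k, ..., ratio + k}` (default k = 2, the smallest sensible
symmetric support; the distribution is not otherwise constrained by the
hardware description). Each animal consumes an independent, seeded
sub-stream of draws (seed = session seed + a hash of the animal id), so
one animal's requirement sequence does not depend on what its cagemate
did. Rewards carry the timestamp of the triggering lick — pump latency is
not modeled because no latency figure is available. Cue flashes (0.5 s)
may overlap when rewards arrive faster than the flash length; both are
logged rather than merged.

### Calibration arithmetic

Calibration commands `per_reward_ul x rewards_per_iteration` per iteration
(60 µl × 5 = 300 µl) over three iterations (900 µl) and compares with the
measured totals; the correction factor `commanded / measured` rescales the
motor's steps-per-µl. The fixed point is exact: measuring exactly the
commanded volume gives factor 1, and a pump whose true µl/step is off by
x% returns to within 0.1% of commanded volume after one correction (this
is a property test, not a tolerance of the arithmetic, which is exact).

## Lick microstructure

A cluster sustains as long as no gap exceeds the 1 s pause threshold; a
gap *strictly* greater than 1000 ms splits. The boundary is deliberate: "a
pause of 1 s" is read as the largest tolerated gap, so `c(0, 1000)` is one
cluster and `c(0, 1001)` is two.

The mean ILI is computed over within-cluster gaps only. Pooling all
successive gaps would mix the lick rhythm (~150 ms in rats) with pause
structure (seconds to minutes) and make the statistic uninterpretable;
since the convention is not universal, `mean_ili(mode = "pooled")` is
provided for comparison but is not the default.

Lick counts are log-scaled as `log10(x + 1)`: inactive-spout counts are
legitimately zero, and the offset keeps the transform total. Intake is
reported volumetrically as ml/kg (= µl reward volume × rewards / g body
weight). A dose in mg/kg requires a solution concentration that is not
derivable from the reward volume alone, so it is exposed as the optional
`solute_mg_per_ml` argument rather than baked in.

## Social proximity

Coordinates follow the image convention (origin top-left, y downward).
Frames are filtered at a 0.5 confidence floor — the same 50% criterion
used when a detector is validated against annotation — then reduced to at
most one box per spout class (highest confidence) and at most two heads
per frame.

Normalization translates every frame so its active spout lands on the
cross-frame mean spout position; the same translation moves every object
in the frame, so within-frame geometry is exactly preserved. Frames in
which the spout went undetected get their session's mean translation —
imputing the typical camera shift, not a position. After translation the
spout coordinate is pinned to the mean exactly (floating-point `a + (m -
a)` can be one ulp off, and the post-condition is exact equality of all
normalized spout positions).

Quadrants are fixed by convention: Q1 is the low-x/low-y corner holding
the active spout, Q2 adjacent along x, Q3 diagonal (inactive spout), Q4
the remainder; boundary points go to the lower index, so the exact
midpoint is Q1. A frame's quadrant is the quadrant of the head-pair
midpoint (the alternative — requiring both heads in one quadrant — discards
straddling frames and was rejected). Distances are divided by the chamber
diagonal, which bounds any within-chamber distance to [0, 1]; the constant
is configurable because "normalized units" conventions vary.

Frames without exactly two detected heads are excluded from pair
statistics rather than imputed: detector dropouts carry no position
information, and head identity is never tracked (top-down images cannot
tell the rats apart), so all pair statistics are identity-symmetric.
`pearson_r()` is the plain product-moment formula implemented directly and
cross-checked against `stats::cor` in the tests; density maps are exact
binned counts (plots may smooth; the core stays exact).

## The synthetic-data generator

`simulate_session()` emulates bout-structured licking: Poisson bout onsets
per rat (default 1.8/min), a shifted-geometric number of licks per bout
(mean 16), gamma within-bout ILIs (mean 150 ms, sd 50 ms — a 6–7 Hz lick
rhythm) floored at the 16 ms sensor interval, bouts targeting the active
spout with probability 0.9, and a per-bout RFID miss probability of 0.019,
the unattributed-lick rate observed in real deployments of this kind of
chamber. With a 1 h session these defaults produce roughly 90–110 active
bouts and 1,400–1,800 active licks per rat — the scale seen in palatable-
solution sessions. Lick times are quantized to the 16 ms sensor grid by
the generator, not by the engine: the sensor quantizes, the logic does
not.

Two structural guarantees make ground truth exactly recoverable:

* consecutive bouts of one rat are separated by strictly more than the 1 s
  cluster pause (with margin for grid quantization), so generated bouts
  *are* the clusters the segmenter should find;
* bouts on one antenna are separated by more than the assignment window.
  Only one head fits the spout opening at a time, so overlap is physically
  impossible anyway; the stronger gap guarantees that a bout whose RFID
  read was missed cannot inherit the previous bout's read and be silently
  attributed to the wrong animal. While a bout runs on, the generator
  emits repeated same-tag reads every 2 s (the head stays in the loop, and
  same-tag repeats survive debouncing by design), so every lick of a
  detected bout falls inside the window. Under these two rules, detected
  bouts attribute 100% correctly and missed bouts are 100% `RatUnknown`.

`simulate_trajectories()` uses a two-state behavioral model per rat:
*drinking* (the head moves a fraction `spout_attraction` = 0.25 of the
remaining distance to the spout per 2 s frame, with halved jitter) and
*roaming* (an unbiased random walk, step sd 4 chamber units, clamped at
the walls), switching by a Markov chain (enter 0.10, exit 0.12 per frame —
visits of ~16 s and a ~45% time share at the spout). The `coupling`
parameter sets where the pair's social proximity is anchored: at each
episode boundary of rat 1's chain, rat 2 joins a starting spout visit with
probability `coupling`, or huddles with its roaming partner — tracking its
position wherever it goes — with probability `0.7 (1 - coupling)`.

This design is deliberate. A naive follower whose drift target blends the
spout and the partner's position makes the pair distance *noise* at high
coupling — uncorrelated with spout distance — so the correlation between
head-pair distance and mean head-to-spout distance *falls* as following
tightens, the opposite of what coordinated drinking looks like. And some
correlation is unavoidable: with both rats attracted to one spout, a rat
drinking alone puts the pair exactly on the line (pair distance) = 2 ×
(mean spout distance). What distinguishes weak from strong coordination in
the data is *where* the pair is close: huddling away from the spout
produces small pair distances at large spout distances and washes the
relation out, while spout-anchored coordination produces tight co-location
at the spout and dispersion elsewhere. Under this model the correlation
rises with `coupling` (about 0.45 → 0.55 → 0.70 across 0.1/0.5/0.9,
averaged over seeds at 1,800 frames), mirroring the session-over-session
strengthening reported for cohabiting rats, and at `coupling = 0` the
relation is weak, as expected for an uncoordinated pair.

What the generator does **not** emulate — and what passing recovery tests
therefore do not show about real data: drift or satiation within a
session, learning across sessions, pharmacological dose effects,
detector-specific box noise (confidences are drawn uniformly, dropouts are
independent), simultaneous-presence RFID collisions, and licking artifacts
(double-contacts, grooming touches). Tests on synthetic data validate the
*logic*; they cannot validate sensor physics.

## Numerical and interface choices

* All engine arithmetic is on raw millisecond timestamps; no floating
  rescaling is applied before comparison, so window boundaries are exact.
* Logs serialize as four comma-delimited UTF-8 tables plus a YAML config
  sidecar; numbers are written in fixed notation with up to 15 significant
  digits, so write → read is the identity on valid logs and writing is
  byte-stable (the determinism checks compare file digests).
* Every stochastic component (VR draws, all simulator draws) flows from an
  explicit integer seed, and seeded code restores the caller's RNG state.
* Degenerate inputs: empty streams are valid everywhere (empty session →
  header-only files, empty cluster list → `NA` ILI); zero-variance series
  make `pearson_r` return `NA` with a warning rather than dividing by
  zero; geometry with zero extent, non-positive weights or measured
  volumes, and unsorted lick input are errors.
* Problem sizes in the test and acceptance runs (500 random streams for
  the oracle comparisons, one to six 1 h simulated sessions for recovery
  statistics, 1,800-frame trajectory sweeps over five seeds) were chosen
  to make the binomial and standard-error tolerances sharp at desk scale.

## Known limitations

The engine is a deterministic event-ordered reduction; it does not model
the real device's concurrency, sensor debouncing firmware, or pump
latency. The unknown-rate recovery treats RFID misses as independent
per-bout events, while real misses cluster (tag orientation, chip
variation). Quadrant statistics depend on the documented corner
convention; detection tables with a different image orientation must be
mapped before analysis. The CLI is a thin wrapper over the exported
functions and adds no logic of its own.
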