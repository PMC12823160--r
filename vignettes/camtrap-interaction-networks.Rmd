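---
title: "From camera-trap video to interaction networks: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From camera-trap video to interaction networks: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camtrapnet)
```

## The problem

Surveys of frugivory (and other plant–animal interactions) increasingly run
camera traps in video mode, aimed at individual fruiting plants. Three
facts shape the data:

1. **Triggers are cheap and noisy.** Wind-moved vegetation fires the motion
   sensor constantly, so most videos are empty; an object detector is used
   to discard blanks before anyone watches them.
2. **Videos are short.** A 10 s clip almost never spans a full frugivore
   visit, so one visit produces a cascade of consecutive clips, and the
   visible evidence of feeding is often partial: active fruit-searching
   behavior must count as an interaction or encounter frequencies are badly
   underestimated.
3. **The detector misses animals.** Below-threshold videos vanish before
   review. These false negatives (FN) are invisible unless a validated
   subsample is re-watched by humans, and they are not evenly distributed
   across plant species or individuals.

`camtrapnet` implements the full path from detector output to weighted
bipartite networks, and the audit machinery for point 3.

## Data model

Three related CSV tables carry all pipeline state: deployments (one camera
on one focal plant for a period), media (one row per video), observations
(one row per reviewed video content). Conventions:

* Timestamps are ISO-8601 **local camera time**; no timezone arithmetic is
  performed (all cameras in a project share one clock convention). An
  unparseable timestamp flags the row (`timestamp_issue`), it never drops it.
* Referential violations (orphan media/observations, duplicate keys) are
  collected into an integrity report; the caller decides. Early silent
  deletion is the classic way camera-trap databases rot.
* The behavior vocabulary is fixed: `feeding` (ingestion seen),
  `probably_feeding` (handling seen), `searching_food` (active foraging
  posture/movement), then `perching`, `walking`, `passing`, `other`,
  `unknown`. The first three count as interactions by default; free-text
  behaviors should be mapped to `other` upstream.
* Species identity for difficult videos comes from independent expert
  reviews: `resolve_species_consensus()` accepts a label when at least
  `min_agree = 3` reviewers coincide, otherwise returns `"unidentified"`,
  which the interaction filter excludes downstream.

## Detection: frames to videos

Detectors run on frames, not videos. Frames live in a tree mirroring the
video tree, named `<videoStem>_<frameIndex>.<ext>` (configurable pattern).
The video-level score for each category is the **maximum confidence over
the video's frames** — one visible-animal frame suffices to rescue a video.

Thresholding convention: a video is *selected* when max confidence is
**strictly greater** than τ; ties at exactly τ fall to blank. The default
τ = 0.8 is a deliberately conservative community-level value; the
calibration tools below exist precisely because no single τ suits all
plant species. Two further rules avoid silent bias:

* Videos absent from the detector output are "not processed", never blank.
* Person/vehicle detections are carried through the index but never enter
  interaction pipelines.

`extract_frames()` is an optional adapter around an external `ffmpeg`
binary (option `camtrapnet.ffmpeg`); everything else in the package
consumes detector JSON and never touches video files.

## Events, effort, networks

**Collapsing.** Consecutive videos of the same animal species at the same
deployment within `window_s = 300` s merge into one independent event. The
default is a *gap (chain) rule* — a new event starts when the start-to-start
gap to the previous record exceeds the window; gaps exactly equal to the
window merge. A *fixed-interval* mode (bins anchored at each group's first
record) is also provided because field pipelines sometimes bin rather than
chain; the mode is recorded on the result. The chain rule conserves total
video count, is idempotent on its own output, and is monotone (fewer events
as the window grows) — all of which are asserted as properties in the test
suite. Records with missing timestamps are excluded and reported.

**Effort.** Field crews trigger a recording when opening and closing every
deployment revision, so revision effort is (last − first media timestamp) in
decimal trap-days. Revisions with fewer than two parseable timestamps have
*undefined* effort: reported, excluded from sums, never imputed as zero.

**Networks and PIE.** Event counts fill the plant × animal matrix at
species level (community analyses) or plant-individual level. PIE defaults
to **row normalization** — the phytocentric reading: the probability that
plant *i*'s next interaction partner is animal *j*. Global normalization is
available; so is a multiplicative per-animal diet weight (the hook for
down-weighting foraging-only records by the fruit fraction of the diet —
the weights themselves are the user's data). Zero rows stay zero rather
than becoming NaN.

## Validation and threshold calibration

`stratified_sample()` allocates `round(fraction * n)` per stratum with a
largest-remainder correction so the total matches `round(fraction * N)`,
samples without replacement, and is reproducible under a seed (the RNG
state of the session is restored afterwards).

All twelve standard binary metrics are computed from TP/TN/FP/FN. Any
metric with a zero denominator is **explicitly undefined (`NA`)**, never
silently 0 — the convention recommended for MCC on degenerate matrices.
Accuracy is reported but deliberately de-emphasized: with ~80% empty
videos, a detector that discards everything scores high accuracy; MCC uses
all four cells and is robust to that imbalance.

`threshold_curves()` reports success, FP and FN rates as **fractions of all
evaluated videos** (the same convention as reporting confusion cells as
proportions of the review sample), over a τ grid of 0–1 in steps of 0.01.
FN rate is non-decreasing and FP rate non-increasing in τ by construction.
`select_optimal_threshold()` minimizes `fp_rate + fn_cost * fn_rate`
(default `fn_cost = 1`, i.e. unweighted FPR+FNR up to class-size scaling);
ties break toward the **lowest** τ, favoring recall, since in this protocol
a missed interaction is costlier than an extra video to review. The
cost-ratio parameter exists because the balance between review effort and
FN-aversion is a study-level decision.

**Lost information.** Given the events with and without FN, the report
counts per plant stratum: events lost, percentage lost (rendered at one
decimal, as in published tables, via `format_lost_info()`), animal species
with at least one lost event, and pairwise interactions present only in the
full data. A CV event for a pair absent from the full data is a consistency
error, not a warning. **FN imputation** is a direct flagged union of the
reviewed FN records with the CV records — no `1/fraction` extrapolation.
Scaling would fabricate events that were never watched; the cost is that
imputed totals understate the full-survey FN burden by roughly the review
fraction, which users should keep in mind when comparing counts.

## Network comparison and the two-mode QAP

Valued Hamming distance (Σ|a−b| over aligned cells) is the default
comparison because on weighted event-count networks the binary version
saturates (typically only a handful of links flip presence); binary mode is
retained for sensitivity checks. Graph correlation is the product-moment
correlation over vectorized cells, undefined (with a warning) when either
matrix is constant.

The QAP test permutes the second network's **plant labels and animal labels
independently** each iteration — the natural two-mode analogue of one-mode
node-label permutation. One-mode QAP implementations exist, but their
behavior on rectangular bipartite matrices is not well defined, so the
permutation scheme is implemented here and documented prominently: results
are comparable across studies only under the same scheme. p-values use the
add-one estimator `(#{null as-or-more-extreme} + 1)/(n_perm + 1)`, ties
inclusive, so p = 0 is impossible. Defaults: `alternative = "less"` for
Hamming (similar networks are *closer* than the null), `"greater"` for
gcor. The test suite checks the Monte-Carlo p against full enumeration of
all 36 label permutations on 3×3 networks.

## The synthetic generator

`generate_scenario()` produces a complete study with known truth:

* visits as homogeneous Poisson processes per (deployment, animal) with
  species-specific rates, exponential visit durations (default mean 45 s);
* each visit emits consecutive videos every `video_length_s +
  trigger_gap_s` (10 + 1 s), at least one per visit; behavior is drawn per
  visit so all its videos share it;
* wind false triggers as an independent Poisson process (default 40/day —
  empty videos dominate, as they do in the field);
* sentinel recordings bracketing every revision, so effort is exact;
* frame confidences: an occupied video's frame shows the animal with
  probability *d* (per-species detectability, defaults 0.6–0.9), drawing
  from Beta(8, 2); otherwise, and on empty videos, from Beta(2, 8). The
  default 3 frames per video reflects sparse frame extraction (sampling a
  few frames per clip keeps storage and GPU time manageable).

Per-frame modeling with max-aggregation is chosen deliberately so the
aggregation step is exercised nontrivially, and it admits closed forms used
as oracles: `expected_fn_rate()` = (d·F₁(τ) + (1−d)·F₀(τ))^k averaged over
the visit-rate-weighted species pool, and `expected_fp_rate()` = 1 − F₀(τ)^k.
Under the defaults the video-level FN rate at τ = 0.8 spans roughly 12–30%
across species — the regime where the lost-information machinery matters.

What the generator does **not** emulate: diel and seasonal activity,
temporally correlated occlusion (a bird behind a branch is hidden in *all*
frames, not independently per frame — real FN are burstier than the model),
multi-animal videos, species misidentification, camera clock drift, and
detector confidence miscalibration. Passing tests therefore demonstrate
that the pipeline arithmetic is right under a plausible stochastic regime,
not that any particular detector performs well on any particular system —
that is exactly why the calibration-on-your-own-subsample workflow exists.

## Numerical and design choices

* **Seeds.** Every stochastic function takes a `seed` and restores the
  caller's RNG state; identical seeds give identical output, including
  byte-identical CSV/JSON from the CLI.
* **Degenerate inputs.** Empty record sets collapse to empty event tables;
  1×1 networks are rejected by QAP (the permutation group is trivial);
  zero-variance matrices make gcor undefined rather than NaN.
* **Text round-trips.** Tables are UTF-8 CSV with quoted character fields;
  `read(write(T)) = T` field-for-field at second-resolution timestamps.
* **Problem sizes.** The test suite and the acceptance script run at desk
  scale: synthetic studies of ~3–5 thousand videos, calibration at
  5000 + 5000 videos, QAP at 1000 permutations, enumeration oracles at 3×3.
  These sizes were chosen so each check has clear statistical resolution
  (e.g. 3·binomial-SE bands) while remaining instant to run.

## Known limitations

* Collapsing is keyed by (deployment, animal species); simultaneous visits
  by two individuals of the same species merge into one event, and
  overlapping camera fields of view double-count — the field protocol, not
  the software, must prevent the latter.
* The optimal-threshold objective treats FP and FN rates over the pooled
  evaluated videos; with strongly unequal class sizes the `fn_cost`
  parameter, not the default, encodes the real trade-off.
* Reproducing any published full-survey comparison numerically requires the
  survey's own deposited data and its (often unstated) collapsing and
  permutation conventions; the package documents its own conventions so
  they can be matched or varied explicitly.
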