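---
title: "soseq: methods and validation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{soseq: methods and validation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical conventions used throughout
`soseq` and the generative model behind its synthetic validation
experiments. It is a methods reference; the README shows the worked
analysis example.

## Data model and conventions

A *recording* is a 25 Hz session of one (solitary) or two (dyadic) mice in
a 453 mm square arena. Per animal it carries

* frame-wise syllable labels in `0..n_syllables-1` (32 by default), with
  `-1` for unassigned frames;
* a centroid track in mm (the median of 10 tracked keypoints when raw
  keypoints are supplied);
* for dyadic recordings, contact-bout annotations typed `active`
  (initiated by the focal animal) or `passive`.

All frame intervals are half-open and 0-based: `[start, end)`. A *bout* is
a maximal run of one syllable; unassigned frames break bouts. A *syntax*
is a sliding window of 3 consecutive bouts of one animal. At 25 Hz, 400 ms
is 10 frames and the 5 s pre-contact window is 125 frames.

Contact annotations are pooled before alignment analyses: bouts of the same
type separated by less than 6 s (150 frames) merge into one event
(`pool_annotations()`), and an aligned analysis only uses bouts whose 5 s
pre-onset window is free of any contact (`clean` baseline).

## Statistical conventions

* Per-syllable and per-edge context comparisons use two-sided Mann-Whitney
  U tests on per-animal values (normal approximation with tie and
  continuity correction, matching `wilcox.test(exact = FALSE)`).
* Multiplicity: Benjamini-Hochberg across the 32 syllables for usage
  (the significant set is the *dyadic-modulated*, DM, set) and across
  divergence time-course bins; Bonferroni for centrality, per-edge, and
  per-family tests, whose families are small and where false positives are
  costlier than misses.
* Transition networks: bout-to-bout transition counts per animal,
  row-normalized. Node importance is the *left* eigenvector of the
  transition matrix (the stationary direction, `c P = c`), computed by
  power iteration restricted to the largest strongly connected component;
  an optional damping factor handles reducible matrices. The per-edge
  family is restricted to edges with pooled count ≥ 10, which bounds the
  Bonferroni family instead of testing all `n(n-1)` edges.
* Composition divergence: within each 5-frame offset bin around contact
  onset, the empirical syllable distribution is compared with the pooled
  dyadic distribution by Kullback-Leibler divergence (nats, pseudocount on
  the reference only).

### Bootstrap null for the divergence time-course

Frame labels are strongly autocorrelated (median bout ≈ 10 frames), so an
i.i.d. frame bootstrap understates the null variance roughly by the bin
width. The null therefore resamples *segments*: the pool holds each
aligned bout's labels within each baseline (pre-onset) bin; a null draw
for a bin supported by `m` bouts concatenates `m` random segments and
recomputes the divergence. Nulls are shared across bins of equal support.
`n_boot = 1000` keeps the discrete p-value floor `1/(n_boot+1)` well below
`alpha / n_bins`, which the Benjamini-Hochberg step needs to be able to
reject at all. The negative control repeats the analysis on sequences
whose bout order is permuted (`shuffle_control()`), which preserves
composition and bout durations but destroys alignment.

### Syntax families and kinematic classes

A syntax *family* is the set of bout triples within Hamming distance 1 of
a reference triple; with 32 syllables a family has `1 + 3×31 = 94`
members. Family occupancy is related to social kinematics through rolling
30-frame windows of the inter-mouse distance (IMD): each window
contributes a point (change in IMD, family occupancy).

Each syntax occurrence is also placed in the plane spanned by
`x` = IMD at its start and `y` = change in IMD over the occurrence.
With the 100 mm contact radius `c`, the four parametric classes partition
the admissible half-plane `x + y ≥ 0`:

* `approach`: `x > c` and `x + y < c`
* `leave`: `x < c` and `x + y > c`
* `contact`: `x ≤ c` and `x + y ≤ c`
* `far_stationary`: `x ≥ c` and `x + y ≥ c`

## The synthetic generator

`simulate_experiment()` produces a full experiment from a seeded
configuration; all default parameters below are the study conditions, and
every stochastic element draws from named substreams derived from the root
seed.

| parameter | default | role |
|---|---|---|
| `n_syllables` | 32 | vocabulary size |
| `n_animals_per_context` | 20 | solitary animals; dyadic animals are paired |
| `duration_s` / `frame_rate` | 1200 / 25 | 20-minute recordings |
| `duration_median_frames` | 10 | geometric bout-duration median (400 ms) |
| `planted_dm` | 7, 10, 12, 13, 18, 23, 28, 30 | usage-modulated syllables |
| `dm_effect`, `centrality_boost` | 1.6, 1.5 | column modulation factors |
| `contact_bias_ids` / `contact_syntax` | 7, 10, 12, 13 / (7, 10, 12) | contact-enriched composition and triple |
| `family_syntaxes` | approach (9, 0, 5); leave (11, 2, 8) | reference triples for planted episodes |
| `n_approach` / `n_leave` | 6 / 6 | planted kinematic episodes per dyadic pair |
| `arena_mm` / `contact_mm` | 453 / 100 | geometry |

**Sequences.** Labels follow a bout-level Markov chain: per-context base
transition matrix (Dirichlet rows, zero diagonal) with per-animal Dirichlet
perturbations, and geometric bout durations.

**Mass-preserving planting.** In the dyadic base matrix the first half of
the planted ids is boosted by `dm_effect × centrality_boost` and the second
half suppressed by its inverse; within every row the planted column block
is rescaled to its original total mass. Non-planted transition
probabilities are therefore *exactly* context-invariant, so the planted
syllables are the only directly modulated ones.

**Network spillover.** Exact invariance of non-planted columns still does
not make the *stationary* distribution of non-planted syllables invariant:
renormalizing within the planted block redistributes mass that previously
flowed through it. The expected onset-proportion shift per syllable is
analytic — the ratio of the two base matrices' stationary distributions —
and the ground truth records it (`expected_onset_shift`) together with
`spillover_ids`, the non-planted ids whose absolute expected shift exceeds
5%. Spillover detections are genuine modulation, not detector false
positives, and the validation battery scores them accordingly.

**Temporally localized plantings.** Approach/leave episodes overwrite the
steering animal's labels with family syntaxes, and active contacts inject
the contact triple and re-draw overlapping bouts from a biased
composition. These overwrites would otherwise change whole-recording bout
counts and contaminate the usage ground truth; a compensation pass
(`rebalance_bout_counts()`) relabels matching bouts *outside* the planted
windows so each animal's whole-recording bout composition returns to the
pure matrix process. The planted contact effects are thereby temporal
*redistributions*, leaving the DM set as the only whole-recording usage
modulation.

**Tracks and contacts.** Mice follow bounded correlated random walks with
corner attraction; planted approach (leave) episodes steer one mouse
toward (away from) its partner, and DM bouts slow the animal down.
Contacts are proximity runs (IMD < 100 mm for ≥ 5 frames), randomly typed
active/passive, logged with achieved frame intervals and distances in the
episode ground truth.

## Validation batteries

`recover_planted(seed)` simulates one planted experiment and scores:
DM sensitivity and false positives (`flagged ∖ (planted ∪ spillover)`),
the fraction of planted ids flagged by the centrality test, significant
post-onset divergence bins on real and bout-shuffled sequences, the
fraction of completed planted episodes classified as their own kinematic
class, and approach-family occupancy in windows with IMD change below
−200 mm versus elsewhere. `null_metrics(seed)` runs the same detectors on
the matched null configuration (`null_synthetic_config()`: unit effects,
no contact planting) and records their false-positive rates, which must
stay at the nominal level. `scripts/acceptance.R` runs both batteries
from a single `--seed` and writes the aggregate metrics as JSON; the test
suite runs the same batteries on fixed seeds.

## Limitations

* Spillover is inherent to stationary-distribution modulation: planting
  usage effects through transition columns cannot leave all other
  stationary probabilities untouched. The ground truth quantifies rather
  than hides this.
* The bout-duration law is geometric and context-independent; duration
  modulation is not simulated.
* The per-edge test family depends on the pooled-count floor; edges below
  it are never tested.
* Kinematics are centroid-level; posture is outside the scope of the
  generator and the analyses.
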