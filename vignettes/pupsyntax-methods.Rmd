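---
title: "Methods: detection, taxonomy, timing, and syntax of rat pup ultrasonic vocalizations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detection, taxonomy, timing, and syntax of rat pup ultrasonic vocalizations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupsyntax)
```

## The scientific problem

Rat pups separated from their dam emit ultrasonic vocalizations (USVs) in
the 40–130 kHz band.  These isolation calls are a standard readout in
neurodevelopmental models: their number, acoustics (peak frequency,
bandwidth, duration), timing (inter-call intervals, sequences, bouts),
and ordering (which call type follows which) all change with age, sex,
treatment, and brief reunion with the dam (maternal potentiation).
pupsyntax implements that analysis chain end to end, together with a
synthetic cohort generator so that every stage can be validated without
animal data.

This vignette documents the models and the design decisions: what each
stage assumes, which parameters matter, where the numerics are
deliberate choices, and what the tests do and do not establish.

## Call detection by spectral entropy

Calls are detected on a short-time Fourier transform: Hann window,
frame length equal to the FFT length (512 samples, no zero padding),
75% overlap, so at a 250 kHz sampling rate the hop is 128 samples
(0.512 ms) and the frame count is `floor((N - 512)/128) + 1`.  For each
frame the power spectrum restricted to the analysis band is normalised
to a probability vector `p` and scored by normalized Shannon entropy

$$ H = -\frac{\sum_k p_k \log p_k}{\log K} \in [0, 1], $$

with `K` band bins.  Broadband noise spreads power across the band
(`H` near 1); a tonal call concentrates it (`H` near 0).  A frame is a
call candidate when `H` falls below a threshold **and** its band power
exceeds a noise floor (median band power + 10 dB by default — the
entropy of near-silent frames is ill-behaved, so low entropy alone is
not evidence of a call).  Candidate runs closer than 10 ms merge (the
same rule the I/O layer applies to detections from external tools), and
runs shorter than 5 ms are dropped.  Call boundaries are placed half a
hop outside the first and last detected frame centers.

Tunable parameters, with defaults:

| parameter | default | units | why |
|---|---|---|---|
| `fft_length` | 512 | samples | standard bioacoustics STFT resolution at 250 kHz (488 Hz/bin) |
| `overlap_fraction` | 0.75 | — | 0.512 ms hop; boundary precision of ~2 hops |
| `band_low`, `band_high` | 40, 130 | kHz | the pup isolation-call band |
| `entropy_threshold` | 0.85 | — | white noise across ~175 band bins scores ≈ 0.89–0.94; tonal frames ≪ 0.85 |
| `power_floor_db` | 10 | dB over median | rejects low-entropy silence; median is robust when calls are sparse |
| `min_duration_ms` | 5 | ms | below the shortest credible call |
| `merge_gap_ms` | 10 | ms | consistent with the inter-call minimum |

The entropy threshold, floor, and minimum duration have no published
reference values; they are calibrated on synthetic audio only and are
exposed as parameters.  One caveat worth knowing: the canonical band is
40–130 kHz, yet low-pitched flat calls have peak frequencies *below*
40 kHz — the taxonomy and the band disagree at the low edge.  Detection
of such calls requires lowering `band_low` (e.g. to 30 kHz); the
default keeps the canonical band.

Per-call acoustic features come from the frequency contour (per-frame
argmax frequency in band, with its power): duration is the frame span
plus one hop; peak frequency is the contour frequency at the
maximum-amplitude frame; bandwidth is the contour's frequency extent;
slope is the least-squares line through (time, frequency) in kHz/s.
The slope estimator is a choice — step-shaped calls have no single
well-defined slope — and is documented as such: the taxonomy below uses
slope bands wide enough that the line fit is adequate for flat and
sweep-like calls.

## The eight-cluster taxonomy

Each call is assigned to one of eight clusters by interval rules on
(peak frequency, duration, bandwidth, slope): high-pitched short (1),
three step-down types (2–4), step-up (5), frequency-modulated (6),
low-pitched flat (7), and low-pitched short (8).  The rule intervals
neither partition feature space nor cover it, so assignment is made
total and deterministic in three steps:

1. a call satisfying all four criteria of exactly one cluster gets it;
2. among several full matches, a fixed priority order
   (7, 8, 2, 1, 3, 5, 4, 6 — the most prevalent call types first) wins;
3. with no full match, the *nearest archetype* wins: the cluster with
   the smallest summed normalized distance to its intervals (per-feature
   scales 10 kHz, 50 ms, 10 kHz, 200 kHz/s), ties again by priority.
   Fallback assignments are flagged `low_confidence`; an alternative
   policy returns `NA` instead.

Approximate bounds in the source taxonomy ("~40 ms", "~150 ms",
"~50 kHz", "low slope, 18") are widened into closed intervals by
documented half-widths (±15 ms, ±50 ms, ±5 kHz, ±18 kHz/s), kept in one
constants table.  Step-down types 2–4 are distinguished by these
numeric bands only; no step-morphology detection is attempted.

Because rules overlap (a call can fully satisfy both clusters 2 and 4),
each rule also carries a bounded **archetype box**: a sub-region of its
intervals that no other cluster matches in full.  The boxes serve two
roles: they are the self-consistency check of the classifier (uniform
samples from a box must come back with that box's label, which holds by
construction of the boxes and is asserted over 8 × 500 seeded samples),
and they are the feature distributions of the synthetic generator
(truncated normals centered in the box, SD = width/6).

## Temporal organisation

The inter-call interval (ICI) is the time from one call's end to the
next call's onset.  Three classes with **closed lower bounds**: gaps of
at least 150 ms separate *sequences*, gaps of at least 2000 ms separate
*bouts*, and the shortest meaningful gap between distinct calls is
10 ms (closer detections merge at load).  A gap of exactly 150 ms is
therefore between-sequence and exactly 2000 ms between-bout.  Since
clock times are doubles, "at least" is evaluated with a 1e-9 ms guard so
that nominally exact boundary gaps are never misclassified by
floating-point rounding.

Per-recording summaries: latency to the first call; mean ICI over *all*
gaps regardless of class (a switch restricts to within-sequence gaps
for sensitivity analysis); sequence and bout counts; mean calls per
sequence and sequences per bout as ratios of totals; and per-minute
call counts binned by call onset (a call spanning a bin edge counts
once, in its onset bin).  Recordings without calls get zero counts and
missing latency/ICI, flagged so they can be excluded the way animals
that never vocalize are.  Session length defaults to 300 s and is
configurable.

## Within-bout transition ("syntax") models

Transitions are ordered pairs of consecutive calls *within the same
bout*; pairs never span a bout boundary, and a singleton bout
contributes none.  From pooled pairs the model computes counts (the
diagonal is repetitive use of a type), joint relative frequencies,
row-normalised conditional probabilities, a retention mask, and column
sums:

- **Exclusion**: transition types with joint frequency strictly below
  0.01 are excluded; exactly 0.01 is retained.  "Frequency" is read as
  joint relative frequency among all pooled pairs, not conditional
  probability — the two thresholds in the workflow (0.01 exclusion,
  0.075 display) otherwise collapse into one; a switch applies the
  exclusion to conditional probabilities instead.
- **No renormalization**: excluded mass is *not* redistributed before
  column sums (a flag renormalizes for sensitivity analysis).
- **Column sums** over retained conditional probabilities quantify how
  likely each cluster is to be the next call.  They are sums across
  source rows, not probabilities, and can exceed 1.
- The 0.075 threshold is display-only: it masks weak edges in flow-path
  graphs (DOT export) and never enters the arithmetic.

Group comparison pools pairs per group, reports per-edge and per-column
differences, and attaches two-sided permutation p-values from shuffling
*recording-level* group labels — recordings, not pairs, are the
exchangeable units — with Benjamini–Hochberg control across edges and
across columns.

## Group designs and permutation inference

Two designs are supported: a developmental trajectory (recordings at
postnatal days 6, 9, 12) and maternal potentiation (first vs second
isolation on day 10, the second after brief reunion with the dam).
Mixed-design ANOVA is deliberately replaced with permutation analogues:

- **Between-group contrasts** permute *litters*, not pups: littermates
  are correlated, so whole litters are reassigned between groups,
  preserving litter blocks exactly.  All litter-to-group assignments
  are enumerated when feasible (e.g. choose(8, 4) = 70 at four litters
  per group, giving a p granularity of 1/70), Monte Carlo otherwise.
  A group with a single litter triggers a loud fallback to
  subject-level permutation.
- **Potentiation** is a paired sign-flip test on within-subject deltas
  (second minus first isolation), exact over all `2^n` sign patterns up
  to n = 20 (enumerated meet-in-the-middle), Monte Carlo beyond.
- **Cluster proportions** are arcsine-transformed
  (`y = asin(sqrt(p))`) per subject before contrasting, with BH
  adjustment across clusters; raw and transformed effects are both
  reported.
- Missing sessions are flagged, never silently imputed; an optional
  flag reproduces mean-imputation from the intact values of the same
  group and phase.

## The synthetic cohort generator

The generator emulates the *structure* of the data, not any particular
animal: per recording a latency, then bouts at a Poisson rate, sequences
per bout and calls per sequence as shifted-Poisson counts, gaps drawn
from log-normals **truncated to their interval class** (within-sequence
< 150 ms, between-sequence 150–2000 ms, between-bout 2000 ms + an
exponential tail).  Cluster labels follow a sticky Markov chain
(`0.3 I + 0.7 × mixture`) restarting at each bout; features come from
the archetype boxes.  Default cell sizes are 8 pups per group × sex
(16 per group) in 4 litters per group, close to realistic cohort
tables.  Subject- and litter-level log-normal rate multipliers
(SD 0.2 and 0.05 on the log scale) supply realistic heterogeneity; the
small litter component reflects the common finding that call counts do
not differ much between litters.

Because gaps are truncated to their class, the segmenter recovers the
generative sequence/bout partition *exactly* — a deliberate
idealization that makes ground truth well-defined.  Real data have gaps
that straddle thresholds; passing the structural-recovery test
therefore shows the segmenter is faithful to its definition, not that
sequences are unambiguous in real recordings.  An `overlap_mode` flag
draws the gaps untruncated instead, for stress-testing segmentation
near the thresholds (ground truth is then intentionally not
recoverable).  Likewise the archetype features guarantee high label
recovery; real calls blur cluster boundaries.

Treatment effects are applied to the treated group with free
magnitudes — *directions* follow the phenotype this model family
reports (fewer calls, longer calls, lower peak frequency, narrower
bandwidth, longer ICIs, later onset, excess transitions into the flat
cluster, absent potentiation), while magnitudes are design parameters
chosen by a power calculation so that each effect is detectable with
the permutation machinery at 16 subjects per group: count multiplier
0.5, duration ×1.3, peak −5 kHz, bandwidth ×0.75, ICI ×1.5, latency
+6 s, transition excess +0.2, potentiation ×1.6 in controls vs ×1.0 in
treated.  The binding constraints in that calculation were the
compound-Poisson variance of per-recording call counts against the
1/70 granularity of the exact litter permutation, and the
retention-mask variability of the column-sum statistic.  They are
**not** estimates of any published effect and must not be read as such.

## Validation: what is computed, at what size

The test suite asserts, among others: exact agreement of the segmenter
with an independently coded brute-force oracle on 1,000 random call
trains spanning the thresholds (including exact-boundary gaps);
transition-model algebra (row-stochasticity to 1e-12, joint frequencies
summing to 1, strictly-below exclusion, column sums against a
hand-coded loop, and the worked four-call bout 7→7→1→7 giving row-7
probabilities 0.5/0.5, row-1 probability 1, column sums 1.5 and 0.5);
classifier totality, determinism, and 100% archetype recovery on
8 × 500 samples; a detection closed loop of 20 synthetic 60-s
recordings with 50 calls each at 20 dB in-band SNR, requiring F1 ≥ 0.95
and mean boundary error within 2 hops; STFT agreement with an
independent implementation (`signal::specgram`); and a 200-replicate
parameter-recovery study at 16 subjects per group in which every
injected effect must be detected with the correct sign at α = 0.05 in
at least 80% of replicates while the null configuration stays within
Monte-Carlo range of the nominal level.  `scripts/acceptance.R` re-runs
these computations from scratch and writes the resulting quantities as
JSON.

## Known limitations

- Audio lives in memory as numeric vectors; no WAV reader/writer is
  shipped.  Call-table input (Raven selection tables, call CSVs) is the
  primary path for real data.
- The slope of step-shaped calls is a line-fit convention, not a
  morphological measurement; clusters 2–4 are separated numerically.
- The VAE/UMAP-style unsupervised clustering that originally produced
  such taxonomies is out of scope by design; the rule engine makes the
  published taxonomy auditable instead.
- The generator draws call durations independently of the gap process;
  real pups coordinate the two (e.g. long calls tend to lengthen the
  following gap).
- Greenhouse–Geisser-corrected mixed ANOVA, Newman–Keuls post hocs, and
  Grubbs outlier pruning are not reimplemented; permutation analogues
  stand in, and they answer slightly different questions (exchangeability
  rather than sphericity-corrected F tests).
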