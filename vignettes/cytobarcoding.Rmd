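---
title: "Combinatorial barcoding and debarcoding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combinatorial barcoding and debarcoding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytobarcode)
```

## The barcoding scheme as a constant-weight code

A k-of-n live-cell barcoding scheme assigns each sample a binary key over `B`
barcode channels with exactly `k` positives. `generate_complete_scheme()`
enumerates all `choose(B, k)` keys; five channels with `k = 3` give the
10-plex used for CD29/CD98/CD45-based multiplexing, and a sixth channel
extends it to a 20-plex without changing anything downstream.

Constant weight is the load-bearing property. Two distinct keys of equal
weight must differ in at least two positions, so the union of two keys (the
signature of a doublet) has weight at least `k + 1` and matches no key.
`validate_scheme()` asserts this Hamming-distance property explicitly rather
than trusting the construction, because users can read hand-edited key files
with `read_key_file()`.

Row order is a convention, not a measurement: keys are emitted in
lexicographic order of their positive-channel index sets, and default sample
names are `BC01...BCnn`. Any canonical order would do; lexicographic makes
regeneration deterministic and key files diffable. Partial schemes (fewer
rows than `choose(B, k)`) are accepted on read and flagged informationally,
since real panels sometimes reserve keys.

```{r}
scheme <- generate_complete_scheme(k = 3)
scheme_key_matrix(scheme)[1:3, ]
```

## The event model and what the simulator emulates

No public event data accompanies this workflow, so the simulator is a
first-class module: it generates batches whose structure matches what the
debarcoders assume, with per-event ground truth for scoring.

Stain intensities are lognormal: within a sample, a barcode-positive channel
draws from LogNormal(log(`pos_median`), `log_cv`) and a negative channel from
LogNormal(log(`neg_median`), `log_cv`). The lognormal is the standard
first-order model for antibody-stain intensity on mass cytometers; medians
(rather than means) parameterize it because they are what one reads off an
intensity histogram. Defaults — `pos_median = 200`, `neg_median = 2` ion
counts, `log_cv = 0.5` — were chosen once as a realistic, separable-but-not-
trivial regime: at these settings the positive and negative arcsinh modes sit
about 4 transformed units apart with visible overlap in the tails, so
debarcoding is easy but not degenerate. They are conventions, documented
here, not measured facts.

Other structure:

* **Doublets** are the channelwise *sum* of two independent singlets from
  uniformly random distinct samples (ion clouds add when two cells are
  acquired as one event); a max-composition alternative was rejected as less
  physical. The doublet count is chosen so the realized doublet fraction of
  all events equals `doublet_rate` (default 0.05, a typical post-filter
  doublet burden). Doublet components are drawn live; dead status applies to
  singlets only.
* **Dead cells** (default `dead_rate = 0.02`, a realistic post-stain
  mortality for cultured lines) keep their sample label, with the palladium
  viability channel drawn from a dead distribution whose median is 50× the
  live one — palladium enters compromised membranes far more efficiently.
* **Rh (DNA) and event length** are drawn for every event: Rh lognormal
  around `rh_cell_median = 150`, event length Gaussian (mean 30, sd 3 pulse
  units), widened and lengthened (×1.5, sd 6) for doublets so the
  event-length gate has something to act on.
* A single integer seed drives one global generator; acquisition order is
  shuffled.

What the simulator does *not* emulate: beads and bead normalization (vendor
software territory), spillover and isotopic impurity, acquisition-time drift,
and real per-channel staining heterogeneity. A green simulation test
therefore establishes that the algorithms are implemented correctly on data
satisfying their assumptions — not that any particular instrument run will
reach the same yields.

## Preprocessing

Events are cleaned in the standard order: `gate_cells()` keeps events with
arcsinh-transformed Rh intensity at or above `rh_min` and event length inside
`length_range`; `gate_live()` keeps events with transformed Pd at or below
`pd_max`. Rh/Pd gates operate on transformed values so thresholds are stable
across signal scales; event length is compared raw because it is already a
bounded instrument parameter. Gating is idempotent and order-independent,
and both functions return kept indices for traceability.

The arcsinh cofactor defaults to 5, the mass-cytometry convention (the choice
matters little here because thresholds are expressed in transformed units).
Gate defaults (`rh_min = 2`, `length_range = c(5, 75)`, `pd_max = 2.75` —
the midpoint of the simulator's live/dead transformed Pd modes) are explicit
numbers tuned to the simulator's stated world; on real data they correspond
to gates normally drawn by eye and should be set per experiment.

`rescale_barcode_channels()` maps each transformed barcode channel to
`[0, 1]` by its 1st–99th percentile window (clamped), not min–max: a single
hot outlier would otherwise compress the whole channel. A constant column
cannot be rescaled and is set to zero with a warning rather than an error,
so one dead channel does not kill a batch.

## Separation-threshold debarcoding

`assign_events()` scores each event against each key as

```
score(e, s) = min over key-positive channels of x  -  max over key-negative channels of x
```

on the rescaled `[0, 1]` intensities, assigns the argmax key, and defines the
event's *separation* as the best score clamped at zero. The score is defined
key-wise rather than as a top-k rule so partial schemes work; for a complete
constant-weight scheme the two are provably identical — separation equals the
gap between the k-th and (k+1)-th highest rescaled values — and that
equivalence is a tested property, not an assumption. Exact ties between
distinct keys (including the all-zero event) are left unassigned with
separation 0; this is the conservative resolution of a case the procedure's
description leaves open.

`apply_threshold()` then unassigns events with separation below the
threshold. The default 0.3 is the operating point used for automated
assignment in the validation experiments this package reproduces. The
comparison is `>=` so an event exactly at the threshold is kept; capture is
monotonically non-increasing in the threshold.

Two deliberate simplifications relative to the original single-cell
debarcoder lineage, both noted as extension points: there is no
Mahalanobis-distance outlier filter, and rescaling is a single global
percentile pass rather than an iterative per-population rescale. The second
means the effective threshold may sit slightly differently than in tools
that rescale per assigned population; with well-separated stains the
difference is immaterial, which the cross-method concordance tests check.

## Hierarchical-gating debarcoding

`hierarchical_gate_debarcode()` reproduces the manual procedure as a Boolean
rule: event → sample `s` iff transformed intensity exceeds the per-channel
cutoff `t_j` on every key-positive channel of `s` and does not exceed it on
every key-negative channel. For a complete constant-weight scheme an event
matches at most one key; non-matching events are unassigned. Whether manual
gates were historically drawn on raw or transformed axes is not knowable
from published figures; transformed axes were chosen because monotone
transforms leave Boolean gates equivalent while making cutoffs scale-stable.

`estimate_channel_thresholds()` replaces the human: per channel it minimizes
the weighted within-class variance of a two-class split (Otsu's criterion on
the sorted 1-D values), placing the cutoff at the midpoint of the optimal
gap. It is deterministic; ties resolve to the lowest candidate split, and no
split is placed inside a run of equal values. A constant channel is flagged
and given threshold `+Inf` (nothing positive) rather than failing the batch.

## Reporting

`compute_yield()` reports the capture rate — assigned events over live gated
cells. The denominator deserves a sentence: published "% of all cells
captured" figures rarely state whether the denominator precedes or follows
the viability gate; this package fixes it as *live gated cells* and says so,
which makes capture rates comparable across runs. Per-sample counts are
reported both as fractions of assigned events (the per-barcode distribution
view) and of live cells (which, with the unassigned fraction, sum to one).
The separation histogram uses bin width 0.02 over `[0, 1]`, fine enough to
see the doublet population pile up near zero. `score_concordance()` compares
calls against simulator truth: a truth-by-call confusion table, singlet
accuracy over *assigned* singlets, and doublet rejection. With no assigned
singlets the accuracy is `NA` (not applicable), never 0.

## Numerical and degenerate-input choices

* Separation is clamped to `[0, 1]`; tied assignments carry separation 0.
* Zero live cells yields an empty-report flag, not a division by zero.
* Zero-event FCS files round-trip with channel structure intact.
* FCS output is always 3.1, float32, little-endian list mode; reading
  accepts 3.0/3.1 float, double, and uniform-width integer data (promoted to
  double, with legacy log amplification applied when `$PnE` requests it).
  Float32 quantization is the precision floor for round-trips.
* The doublet count is `round(rate / (1 - rate) × n_singlets)`, so the
  realized doublet share of all events equals the configured rate.

## Known limitations

The simulator's independence assumptions (no spillover, no channel
correlation beyond the key, no drift) make it a verification harness, not a
forecast of instrument yields. Real batches with dim or variable staining
will show lower capture at the same threshold, and the global-rescale
simplification can shift the effective threshold relative to per-population
implementations. Error-correcting (distance > 2) code design and
doublet rescue are out of scope by design.
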