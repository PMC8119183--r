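# cytobarcode

Design and debarcode combinatorial live-cell barcoding schemes for mass
cytometry (CyTOF).

Live-cell barcoding stains each sample with metal-isotope-conjugated
antibodies against ubiquitous surface antigens (CD29, CD98, CD45) in a unique
isotope combination before pooling, so many samples can be acquired as one
multiplexed batch without fixation or permeabilization. `cytobarcode` is for
the computational side of that workflow: it builds the k-of-n key matrices,
simulates barcoded batches with known ground truth, and assigns pooled events
back to their source samples with QC reporting.

## The model

A barcoding scheme over `B` barcode channels is a binary key matrix
`K ∈ {0,1}^(S×B)` with constant row weight `k` (each sample is positive on
exactly `k` channels). With `B = 5` channels (112Cd, 113In, 114Cd, 115In,
116Cd) and `k = 3` there are `C(5,3) = 10` keys — a 10-plex; adding a sixth
channel gives `C(6,3) = 20`. Any two distinct constant-weight keys differ in
at least two positions, so a doublet — two cells acquired as one event, whose
barcode signal is the channelwise sum and hence the *union* of two keys — can
never look like a valid key.

Two debarcoding procedures are implemented:

* **Separation-threshold assignment.** Barcode intensities are
  arcsinh-transformed (cofactor 5), percentile-rescaled to `[0,1]` per
  channel, and each event is scored against every key:
  `score(e, s) = min_{j: K[s,j]=1} x_ej − max_{j: K[s,j]=0} x_ej`.
  The event is assigned to the highest-scoring key; its *separation* is that
  score clamped at zero (for a complete scheme, the gap between the k-th and
  (k+1)-th highest rescaled values). Events with separation below a threshold
  (default **0.3**) are left unassigned — this is what rejects doublets and
  ambiguously stained cells.
* **Hierarchical Boolean gating.** The manual-gating procedure: an event
  belongs to sample `s` iff it is above a per-channel cutoff on all `k`
  key-positive channels and below it on the remaining `B − k`. Cutoffs can be
  supplied or estimated automatically by minimizing within-class variance
  (Otsu's criterion on the 1-D transformed intensities).

Preprocessing follows the standard CyTOF cleanup: cell events are identified
by DNA-intercalator (Rh) intensity and the event-length parameter, and dead
cells are removed on the palladium viability channel. A lognormal
stain-intensity simulator generates whole batches — singlets, channelwise-sum
doublets, dead cells — with per-event ground truth, so every stage is
testable offline.

## Worked example

```r
library(cytobarcode)

scheme <- generate_complete_scheme(k = 3)   # the 10-plex 5-choose-3 design
scheme
#> <barcode_scheme> 10 samples, 5 channels, k = 3
#>    sample `112Cd` `113In` `114Cd` `115In` `116Cd`
#>  1 BC01         1       1       1       0       0
#>  2 BC02         1       1       0       1       0
#>  ...
#> 10 BC10         0       0       1       1       1

sim <- simulate_barcoded_events(
  scheme, sim_config(events_per_sample = 1000, doublet_rate = 0.05, seed = 42))

gate  <- gate_config()
cells <- gate_cells(sim$events, gate)       # Rh+ / event-length cell gate
live  <- gate_live(cells$events, gate)      # palladium viability gate

asg <- debarcode_events(live$events, scheme,
                        debarcode_params(separation_threshold = 0.3))
yield <- compute_yield(asg, total_events = nrow(sim$events),
                       gated_cells = length(cells$kept))
yield
#> events: 10526 total, 10526 gated cells, 10309 live
#> assigned: 9786 of 10309 live cells (capture rate 94.93%)
#>   BC01              981  10.02% of assigned
#>   BC02              984  10.06% of assigned
#>   ...
#>   BC10              977   9.98% of assigned
#>   unassigned        523
```

The capture rate is the fraction of live, gated cells assigned to a barcode;
the per-barcode shares near 10% show the 10-plex debarcoded evenly. The 523
unassigned events are dominated by the simulated 5% doublets, which the
separation threshold rejects. Against the simulator's ground truth:

```r
truth_live <- sim$truth[cells$kept[live$kept], ]
glance(score_concordance(asg, truth_live))
#>   singlet_accuracy doublet_rejection n_singlets n_doublets
#> 1                1             0.994       9783        526
```

Every assigned singlet was returned to its true sample, and 99.4% of doublets
were rejected. `autoplot(yield)` draws the per-barcode distribution bar
chart; `autoplot(asg)` the separation-score histogram; `tidy()`/`glance()`
methods return the same numbers as tibbles.

A command-line interface wrapping these functions (subcommands `scheme`,
`simulate`, `debarcode`, `report` and an end-to-end `run` driven by a YAML
config) ships in `inst/cli/cytobarcode.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/cytobarcode.R", package="cytobarcode"))')" \
  scheme --k 3 --out key.csv
```

## Acceptance script

`scripts/acceptance.R` recomputes the package's headline simulation statistic
from scratch — it generates an equal-abundance 10-plex batch (2,000 singlets
per sample, no doublets or dead cells), debarcodes it at separation threshold
0.3, and reports the mean per-barcode share of assigned events as a
percentage:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
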