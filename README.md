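# epp — automated cytometry phenotyping by Exhaustive Projection Pursuit

Manual analysis of flow and mass cytometry data proceeds by *projection
pursuit*: an expert inspects two-dimensional marker projections, draws a
gate where populations separate, and repeats inside each gate. It works,
and every sorter and analysis tool understands its output — but it is slow,
subjective, and has no guarantee of finding every separation the data
support.

`epp` automates the procedure end to end. For each population it

1. **qualifies** marker dimensions by the Kullback–Leibler divergence of
   their sample distribution from an uninformative reference (moment-matched
   normal; for mass cytometry also an exponential on the non-zero values),
   estimated from the order statistics by m-spacings, with thresholds 0.04
   and 0.2;
2. **estimates the 2-D density** of every qualified dimension pair on a
   257×257 grid — bilinear binning, Gaussian kernel of width `W` (1% of
   scale; 2.5% for mass) smoothed spectrally under reflective boundaries —
   plus a squared-kernel companion grid giving the pointwise sampling
   variance of the estimate;
3. **modal-clusters** the grid by a descending-density sweep guarded by a
   noise floor (a ±2W-spot window must hold more than σ² = 9 events), and
   builds the plane **cluster graph** of modes, boundary chains and
   meeting vertices;
4. applies **density-based merging**: an edge survives only if both of the
   modes it separates exceed its saddle density by z = 3 standard errors,
   `t = (f̂(mode) − f̂(saddle)) / √(V̂(mode) + V̂(saddle)) > z`;
5. **enumerates every candidate separation** — each continuous boundary
   splitting the clusters into two contiguous groups — by edge removal and
   vertex merging on the bit-vector dual graph;
6. **scores** each candidate by the estimated events within ±W of the
   boundary, `score = n · 2W · ∮ f̂ dℓ` (optionally divided by the balance
   factor 4P(1−P)), splits on the best one, and **recurses** until no
   statistically supported split remains.

The leaves of the resulting binary gating tree are *algorithmic
phenotypes*: populations the data cannot justifiably subdivide. Output is
a conventional gating tree (JSON with RDP-simplified gate polygons) plus a
per-event CSV of leaf assignments and Mahalanobis distances, so results
drop into existing review and sorting workflows. If the kernel is too
narrow for the structure (more than 12 clusters or 32 graph edges), it is
doubled and the pass restarted — the algorithm is adaptive and fully
deterministic.

## Worked example

Four well-separated populations on a 2-D panel, generated with known
labels and gated automatically:

```r
library(epp)

g   <- generate(fixture_library("four_grid", n = 40000, seed = 7))
fit <- epp(g$events)          # mode = "best_balance" by default
summary(fit)
#> EPP gating result (best_balance): 40000 events, 0 censored, 4 leaves
#>   leaf_id  label     n fraction
#> 1       1 M2-M1- 10224    0.256
#> 2       2 M2-M1+  9847    0.246
#> 3       3 M2+M1-  9940    0.248
#> 4       4 M1+M2+  9989    0.250

table(predict(fit), g$labels)   # leaves vs generator components
#>        1     2     3     4
#> 1  10224     0     0     0
#> 2      0     0  9847     0
#> 3      0  9940     0     0
#> 4      0     0     0  9989

plot(fit)                        # root split with its gate polygon
write_tree_json(fit, "tree.json")
write_assignments_csv(fit, "assignments.csv")
```

Each leaf recovers one generator component exactly (100% purity here); the
labels are heuristic `marker±` annotations accumulated along the gating
path. `fit$tree` exposes every split's dimension pair, boundary polygon,
events-near-boundary score and balance fraction `P`; `fit$log` records the
per-population decisions (dimensions qualified, kernel widenings, chosen
splits).

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/epp.R synth --fixture four_grid --n 40000 --seed 7 --out events.csv
Rscript inst/cli/epp.R run --input events.csv --out tree.json --assignments out.csv
Rscript inst/cli/epp.R compare --assignments-a out.csv --assignments-b ref.csv \
        --events events.csv --out match.csv
```

`compare` writes a match table of shared event counts plus Jaccard and
Central Similarity coefficients (the latter restricts each population to
its central 80% by Mahalanobis distance, so tail disagreements do not count
against a match).

## Scope

Compensation/unmixing, live/dead and doublet pregating are assumed done
upstream. Only pairwise projections are searched (by design — the output
must remain an ordinary gating tree). Gating-ML/FlowJo workspace export and
QFMatch-style cluster alignment are out of scope; the similarity module
compares labelings by event overlap only.
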