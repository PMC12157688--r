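---
title: "Exhaustive projection pursuit: models, parameters and design choices"
author: "epp package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exhaustive projection pursuit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Phenotyping in flow and mass cytometry means recognising populations of
cells that share characteristic marker expression, and historically it is
done by *projection pursuit*: an analyst looks at two-dimensional
projections of the data, draws a gate where two groups of events are
separated by empty space or a density valley, and repeats inside each gate
until no further separation is visible. `epp` automates exactly this
procedure. Its core claim is statistical rather than heuristic: a
population is split only where the two-dimensional event density shows a
dip that is significant relative to the sampling variability of the density
estimate, so every leaf of the resulting gating tree is a population that
the data cannot justifiably subdivide — an *algorithmic phenotype*.

The pipeline per population is:

1. **Qualification.** Each phenotyping dimension is screened with a
   Kullback–Leibler divergence of its sample distribution from a
   moment-matched normal (and, for mass cytometry, an exponential fitted to
   the non-zero values, since low mass-channel signals are zero-inflated
   with a roughly exponential tail). Dimensions that look like a uniform
   positive or negative stain carry no separation information and are
   skipped. Divergence is estimated from the order statistics by an
   m-spacing construction with $m = \lceil\sqrt n\rceil$:
   $\hat D = \tfrac1n \sum_i \log\frac{(j_{hi}-j_{lo})/n}
   {F(x_{(j_{hi})})-F(x_{(j_{lo})})}$ with indices clamped at the sample
   ends. The clamped form (rather than a fixed $2m/n$ numerator) makes the
   estimator exactly zero when the sample sits on the reference quantiles,
   which is the behaviour the thresholds assume. Thresholds are 0.04
   (normal) and 0.2 (exponential). Qualified dimensions are paired
   exhaustively; if fewer than two qualify, the most promising pair by
   divergence is still examined, so every population gets at least one
   look.

2. **Density estimation.** Events of a dimension pair are binned onto a
   $257\times257$ grid by bilinear (area) weighting and smoothed with an
   isotropic Gaussian kernel under reflective boundary conditions, computed
   spectrally on the even extension of the grid — the cosine-transform
   trick, exact up to FFT round-off. The kernel width $W$ starts at 1% of
   full scale (2.5% for mass cytometry) and doubles whenever downstream
   stages find the structure too fine (more than 12 modal clusters, more
   than 32 graph edges, or an unchainable boundary). A companion grid
   smoothed with the *squared* kernel provides the pointwise sampling
   variance of the density estimate,
   $\widehat{\mathrm{Var}}\hat f(g) \approx (K^2 * w)(g)/n^2$, which the
   merging test consumes. Squaring a Gaussian of width $2W$ gives a
   Gaussian of width $W\sqrt2$, which is what makes the doubling schedule
   cheap in a DCT implementation; the package recomputes both grids per
   pass but tests the identity.

3. **Modal clustering.** Grid points are swept in descending density.
   A point whose four nearest neighbours are all unassigned founds a
   cluster (it is a local mode); a point adjacent to two clusters becomes a
   boundary point; otherwise it joins its neighbour's cluster. A noise
   floor forbids founding clusters where the local event support is too
   thin: a window of $\mathrm{round}((4W(G-1))^2)$ grid points (the
   $\pm 2W$ spot size) slid along the density-sorted grid points must carry
   more than $\sigma^2 = 9$ events of mass. Points below the floor are
   classified outward in contiguity layers, each layer one step from the
   already-classified set, so sparse territory is divided at the
   (Chebyshev) midline between clusters. Contiguity marks seven of the
   eight neighbours, cycling the omitted diagonal modulo 4 to keep the
   marking roughly radially symmetric.

4. **Density-based merging.** Boundary chains between cluster pairs become
   the edges of a plane *cluster graph* (faces = clusters, vertices =
   points where three or more clusters meet). For each edge, in descending
   order of its highest (saddle) density, the dip is standardised:
   $t_i = (\hat f(m_i) - \hat f(s))/\sqrt{\hat V(m_i)+\hat V(s)}$ for the
   two separated modes $m_1, m_2$. Unless both exceed $z = 3$ the edge is
   removed, the faces merge (keeping the higher mode), parallel edges
   splice, and the scan restarts — the restart matters because merges can
   change which mode an edge separates. The surviving faces are clusters
   with statistically supported separations.

5. **Separation enumeration.** With more than two clusters, a usable gate
   is a *continuous* boundary splitting the faces into two *contiguous*
   groups. These are enumerated on the dual graph (one node per face, one
   edge per shared boundary), where faces and edges are bit positions and
   every operation is integer arithmetic: remove a dual edge, merge its
   endpoints, OR together edges that become parallel, and push the
   simplified graph; a graph reduced to a single dual edge is a candidate
   separation. An ordering rule on removed edge indices plus memoisation of
   visited states keeps the search from revisiting partitions. The
   package's test-suite proves the emitted set equal to a brute-force
   enumeration of connected two-part face partitions on hundreds of random
   graphs.

6. **Scoring and recursion.** Each candidate boundary is scored by the
   estimated number of events within a strip $\pm W$ around it,
   $n \cdot 2W \sum \hat f \,\mathrm{d}\ell$ — a proxy for misallocated
   events, so lower is better. In *best-separation* mode the raw score is
   minimised, which tends to clip off small clean populations first; in
   *best-balance* mode (the default) the score is divided by $4P(1-P)$,
   where $P$ is the event fraction on one side, favouring even splits the
   way a human analyst would. The winning split divides the events by grid
   ownership and the procedure recurses into both children until no pair
   of dimensions yields a candidate (or a configured minimum population
   size is reached).

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `W_init` | 0.01 (fluor.), 0.025 (mass) | fraction of scale | initial kernel SD; less is inappropriate on a 257 grid |
| `grid_size` | 257 | nodes/axis | $2^8+1$, DCT-friendly |
| `sigma` | 3 | — | noise floor needs $>\sigma^2$ events per spot window |
| `dbm_z` | 3 | SE multiples | dip significance threshold |
| `kld_threshold_normal` | 0.04 | nats | qualification vs normal |
| `kld_threshold_exponential` | 0.2 | nats | qualification vs exponential (mass) |
| `max_clusters` / `max_edges` | 12 / 32 | — | complexity caps; exceeding either doubles `W` |
| `mode` | `best_balance` | — | split selection |
| `min_events_abs` / `min_events_rel` | 0 / 0 | events / fraction | optional stopping floors (off) |
| `rdp_tolerance` | 0.01 | fraction of scale | output polygon simplification |

The algorithm is deterministic: there is no seed, and two runs on the same
input produce byte-identical gating trees (a tested invariant).

## What the synthetic generator emulates — and what it does not

Display-transformed cytometry populations are reasonably modelled as
near-normal components on the unit square; `mixture_spec()` draws truncated
(by rejection, not clipping) multivariate normals with known component
labels, and its `mass_like` style adds the zero-inflated exponential
low-signal behaviour of mass channels. The canonical fixtures freeze the
study conditions the tests use: separations of at least 8 component SDs
for the recovery fixtures (`two_blobs`, `triangle_blobs`, `four_grid`), an
uninformative `N(0.5, 0.05^2)` marginal to exercise qualification
(`pair13_only`), a 2% satellite beside two broadly overlapping majors for
the mode contrast (`tiny_plus_overlap`; the satellite sits at
(0.78, 0.5), close enough that its valley carries real density, so the
balance penalty actually bites), and thirteen narrow spikes that force the
kernel-widening path (`many_spikes`).

What passing these tests shows is that the machinery — density
estimation, modal clustering, the dip test, the enumeration, the
recursion — does what it claims under controlled conditions. What it does
not show is performance on real cytometry data, which departs from the
generator in known ways: spillover/unmixing residuals correlate channels,
populations are skewed and heavy-tailed after imperfect transforms,
doublets create spurious double-positive groups, and acquisition drift
violates exchangeability. Real-data behaviour also depends on upstream
choices (compensation, logicle width selection, pregating) that are
explicitly out of the package's hands.

## Numerical choices and degenerate inputs

* Ties in the descending-density sweep break by (row, column) order;
  boundary-cell events go to the lowest adjacent cluster id; equal scores
  break lexicographically by dimension pair then boundary bitset. All
  tie-breaks exist purely to make results deterministic.
* The noise-floor window uses the density at the *start* (lowest-density
  end) of the first qualifying window.
* Bit-vector sets are exact integer-valued doubles (`2^i`), which keeps
  bit 31 usable where R's signed 32-bit integers reserve it; all unions
  formed by the algorithm are of disjoint sets, so OR is addition.
* Leaf covariances are ridge-regularised by $10^{-6}\,\mathrm{tr}/D$
  before Mahalanobis distances; fully degenerate leaves report distance 0.
* Empty input, header-only CSV, constant dimensions, and populations too
  small to clear the noise floor ($n \le \sigma^2$) are all valid inputs
  that produce leaves rather than errors.
* The logicle transform solves the standard biexponential with a
  root-found decay parameter and inverts it by vectorised bisection to
  below `1e-9` relative error; `W = 0` (the arcsinh-like mass scale) is
  supported, and the mass-cytometry rescaling constant is exposed as
  configuration since conventions differ between instruments.

## Open design points, resolved

* *Spacing estimator.* Only the ingredients (order statistics + reference
  CDF) are canonical; this package fixes the m-spacing form above and
  treats the thresholds as calibrated against it. The tests pin the
  estimator's bias: a matching normal at $n = 10^5$ stays an order of
  magnitude below the 0.04 threshold.
* *Exponential test scope.* Applied in mass mode only, where zero-inflated
  channels motivate it; a flag can force it elsewhere.
* *Dip test laterality.* Significance is required against **both** modes
  (conservative); `dbm_both_modes = FALSE` switches to either-mode.
* *Balance factor.* The balanced score divides by $4P(1-P)$, the standard
  symmetric penalty that is 1 at an even split.
* *Small-population stopping.* The floors suppress recursion **into** a
  small child (the child becomes a leaf) rather than suppressing the split
  that created it.
* *Polygon simplification is presentation-only.* Events are split by grid
  ownership; the Ramer–Douglas–Peucker polygons in the JSON are for
  display and interchange, and a test bounds their gating distortion at
  the 1% tolerance to under 1% of events.
* *Central similarity trimming* is per set: each population keeps its own
  central 80% by Mahalanobis distance and the Jaccard comparison is
  restricted to the union of the kept cores. The trim fraction is a
  parameter.

## Problem sizes

The test-suite and the acceptance script run entirely on generated data:
recovery fixtures use 20–40k events, calibration loops 100 replicates at
$n = 500$ and $n = 5\times10^4$, qualification loops 100 replicates at
$n = 10^5$, and the enumeration is verified on 50 grid-derived cluster
graphs plus hundreds of random abstract graphs. These sizes were chosen to
make the statistical assertions sharp (binomial error well inside the
asserted bounds) while keeping a full run in the low minutes on one core.

## Known limitations

* Only pairwise (2-D) projections are searched, by design; populations
  separable only in 3 or more dimensions jointly will not be split.
* The dip test inherits the KDE's bandwidth: structure much finer than
  `W_init` on the display scale is smoothed away before testing.
* The cluster graph is capped at 32 edges and 12 faces per pass; denser
  modal structure is handled by widening, which can merge genuinely
  distinct but tightly packed modes (they are typically re-found deeper in
  the recursion, as the `many_spikes` fixture demonstrates).
* Leaf labels are heuristic marker annotations (`CD4+CD8-` style tokens
  accumulated along the gating path), not biological assessments.
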