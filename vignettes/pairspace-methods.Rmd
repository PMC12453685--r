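---
title: "Methods: models, parameters and numerical choices in pairspace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical choices in pairspace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairspace)
```

# Scope

`pairspace` operates on two central data structures of 3D genomics: the
binned contact matrix (interaction frequencies for all bin pairs of a
HiC/HiChIP experiment) and the BEDPE file (one pairwise interaction per
row, two 1D "feet"). This vignette documents the models and the
numerical decisions behind each operation — what is assumed, what is
tunable, and where a design was genuinely open and we chose.

# Coordinates and canonical form

All BED/BEDPE coordinates are 0-based half-open; bin `b` at resolution
`r` covers `[b*r, (b+1)*r)`, so bin arithmetic is exact. Every BEDPE row
is canonicalized so that foot1 is the upstream (lower-coordinate) foot;
for interchromosomal rows the order follows the chrom-sizes file when
one is available and a numeric-aware natural chromosome order (chr2
before chr10) otherwise. Canonicalization never drops rows, which keeps
read/write round-trips lossless.

# Numeric spaces

Three linear numeric spaces are supported. `none` returns raw counts.
`cpm` divides by the sample's total valid pairs and scales by one
million. `aqua` multiplies CPM by a spike-in factor, by default
`total_pairs / spike_pairs`; the factor is a plain user-overridable
number so that any published spike-in scaling variant can be injected.
Samples carrying a spike-in pair count default to `aqua`, others to
`cpm`; an explicit user choice always wins. Two-sample deltas are
computed in the caller-chosen space of each sample — mixing spaces is
permitted (it changes the sign structure of global trends, which is
precisely what spike-in normalization is for) but warned about. The
spike-in factor is applied to pair counts only, not to any 1D marginal.

# The inherent distance-decay model

Contact frequency decays roughly as a power law in genomic distance,
which makes a single raw-count threshold meaningless across distances.
The inherent model maps every intrachromosomal pixel into a 0–1 score
that is distance-free: 0 is the standard contact level of
*non-interacting* loci and 1 the standard level of *interacting*
regulatory elements.

## Fitting

For a selection of diagonal distances `d` (in bins), we take two
quantiles of the nonzero pixel values at exactly that distance, pooled
across chromosomes: `quantile_lo = 0.5` (the median — the standard
non-interacting level) and `quantile_hi = 0.99` (the standard
interacting level). Each quantile series is then replaced by a
least-squares power law `log v = log k − alpha * log d_bp`. Both curves
are therefore smooth in distance and the model is four numbers plus
bookkeeping. The fit is deterministic given the matrix.

Numerical choices, all exposed as arguments:

* **Distance selection.** All integer bin distances 1–20, then
  log-spaced individual distances out to the maximum. We evaluate
  quantiles at *individual* distances rather than pooling ranges:
  pooling mixes different decay levels into one sample and biases the
  quantiles off the power law, whereas per-distance quantiles keep a
  noise-free power-law matrix exactly on the fitted line.
* **Support thresholds.** A distance enters the fit only with
  `min_pixels = 50` nonzero pixels, and only where at least
  `min_nonzero_frac = 0.8` of its possible pixels are nonzero. The
  second rule matters in sparse regimes: once the mean count drops below
  ~1, the median of the *nonzero* counts saturates at 1 regardless of
  distance (zero-truncation plus count discreteness), which would
  flatten the fitted decay. Excluding sparse distances removes that
  bias; on deeply sequenced real matrices at 1–5 kb the rule is
  typically inactive at the distances that matter.
* **Chromosome pooling.** Fitting pools chromosomes by default
  (`per_chrom = TRUE` fits one model per chromosome); chromosomes
  contributing fewer than `min_pixels` are excluded with a warning.
* **Degeneracy.** A model whose fitted top curve does not strictly
  exceed its background curve at every fitted distance cannot score and
  is rejected (`require_gap = TRUE`). A perfectly flat or perfectly
  noise-free matrix is degenerate in this sense — the decay exponent is
  still recoverable from it by setting `require_gap = FALSE`.
* **Resolutions.** The model targets 1 kb and 5 kb bins; other
  resolutions fit with a warning (a second warning beyond 25 kb, where
  distance-decay scoring is of doubtful value).

## Scoring

`score(v, d) = (log v − log B(d)) / (log T(d) − log B(d))`, clamped to
[0, 1]. The anchors are exact by construction: `v = B(d)` gives exactly
0, `v = T(d)` exactly 1, and the log-midpoint `sqrt(B*T)` exactly 0.5.
Zero (absent) pixels score 0 by definition, so thresholding treats
missing contacts as non-interacting; positive values are floored at a
small `eps` (half the smallest positive value seen in the fit) before
the logarithm. We deliberately do not add `eps` inside the logs of the
anchors themselves — that would shift the 0/1 anchor values, and
exactness there is part of the score's contract. The diagonal (`d = 0`)
is never scored. Scoring is intrachromosomal only, since distance is
undefined across chromosomes.

# Extraction

`extract_single` reports every pixel in scope (a range or a TAD file;
TAD scopes are per-TAD extractions, deduplicated) whose distance is at
least `min_dist` bins and whose score reaches the threshold. The
default `min_dist = 2` excludes the diagonal and first off-diagonal,
which in HiChIP are dominated by self-ligation products.

`glob_loops` agglomerates single bins into connected components under
"Chebyshev bin distance ≤ radius + 1". With this convention `radius`
counts the maximum number of *gap* bins between conjoined structures:
radius 0 means touching (8-neighbour adjacency). Component feet are
per-axis bounding spans, the component score is the member maximum
(never a sum — globbing must not reward size), and near-diagonal
components whose bounding feet overlap are kept but flagged in a `note`
column rather than silently dropped.

Flare detection operates on inherent scores, not raw counts, so deep
loci do not dominate: a bin's marginal is the sum of scores of its
off-band pixels in scope, and anchors are bins whose marginal *strictly*
exceeds `mean + flare_z * SD` of the scope marginals. The strict
inequality is deliberate: a perfectly flat marginal landscape has zero
standard deviation, and a `>=` rule would then flag every bin. Flare
crossings report anchor-by-anchor pixels; by default the crossing pixel
itself must also pass the score threshold (`pixel_threshold = FALSE`
reports all nonzero crossings of detected flares).

# Query formulas

The query window of a BEDPE row is the rectangle of bins covered by
foot1 x foot2, optionally expanded by whole bins per side (clipped at
chromosome ends with a warning). `center` reads the pixel at the bins
containing each foot's midpoint (even-width feet use the bin containing
`floor((start+end)/2)`). `mean` divides by the *full* window pixel
count including zeros — windows are geometric objects and sparse absence
means zero contacts — with `mean_nonzero = TRUE` as the alternative
reading. Maximum ties break to the smallest `(bin1, bin2)` in row-major
order, making relocation deterministic. Deltas apply the formula per
sample and subtract, which for `max`/`center` differs from the formula
of the pixelwise difference; the latter is available via
`delta_pixelwise = TRUE`. `fix = FALSE` relocation under a delta anchors
on the case (first) sample. Relocation is only defined for `max` and
`center`; `sum`/`mean` have no defining bin and error.

# Set operations

Intersection classes label each foot with the sorted comma-join of the
names of overlapping annotation intervals (≥ 1 bp, half-open), `"0"`
for none, giving tags like `P-E` that can be grep-filtered. Absence
detection (`invert`) keeps rows with no hit on either foot. For boolean
reporting the `require` switch selects either/both/upstream/downstream.

Union merges rows whose foot1 intervals *and* foot2 intervals overlap,
replaces them with per-axis span unions, and repeats to the transitive
fixpoint — so merged areas can exceed the geometric union of the
inputs, which is intended: union builds a coordinate scaffold for
re-querying. Scores and tags are dropped (a `keep_score` flag
re-attaches the member maximum). The fixpoint is order-independent.

Clustering is purely graph-structural: feet overlapping by ≥ 1 bp merge
into nodes (book-ended adjacency is off by default, available via
`adjacency = TRUE`), rows are edges, and connected components get tags
`cluster_1, cluster_2, ...` ordered by leftmost node for determinism
(ids are per-run, not stable across inputs). A single row is the
minimal cluster; interleaved but foot-disjoint chains stay separate
clusters even when their 1D ranges overlap.

Cluster summaries report both "total range" (the bounding width) and
"total size of cluster loops" (the summed anchor widths) since either
reading of a cluster's extent is defensible; total CPM is the sum-formula
CPM query summed over the cluster's loops.

# Profiles

Contact windows and virtual-4C profiles are thin, exact views of the
dense normalized window (the 4C profile is the viewpoint bin's row).
Gene-centered windows pad the gene span by `max(10 x gene length,
200 kb)` per side — enough context to see a typical regulatory
neighbourhood at any gene size.

APA centers a `(2w+1)^2` block on each loop's midpoint bins and averages
blocks elementwise (a mean, not a sum, so the pile-up is comparable
across loop-set sizes). Loops whose block would cross the diagonal or a
chromosome edge are skipped and counted. The enrichment score is the
center value over the mean of the lower-left `floor(w/2)`-sized corner
block — the short-distance corner, the usual convention for this
statistic — with the corner size configurable. Because the corner sits
closer to the diagonal than the center, a pure decay background yields
scores slightly below 1; distance-preserving shifted controls (translate
each loop along the diagonal) are the appropriate null and sit near 1.
PDF rendering is intentionally out of the numeric core; all outputs are
plain matrices and tables.

# Synthetic data

`make_matrix` emulates the plaid HiChIP structure: background mean
`k * d^(-alpha)` per bin-distance `d`, planted loops multiplying single
pixels by a fold, flare anchors multiplying whole rows/columns, and
either exact means (`noise = "none"`) or Poisson draws
(`noise = "poisson"`), all deterministic under one integer seed
(default 1729). `noise = "none"` keeps real-valued means rather than
rounding so that the generated decay is exactly the power law — the
point of the noise-free mode is that model recovery on it has no
excuse. Spike-in is emulated at the metadata level only
(`spike_pairs`), since the normalization consumes nothing else.

What the generator does *not* emulate: TAD/compartment block structure,
restriction-fragment and mappability bias, overdispersion beyond
Poisson, and the heavy-tailed per-distance count distributions of real
HiChIP. The last point matters for interpreting tests: with a purely
Poisson background, the 99th-percentile top curve sits only
`~2.3 * sqrt(mu)` above the background, so ~1% of background pixels
reach score 1 by construction and single-bin extraction on synthetic
data has an irreducible false-positive floor that real matrices (whose
top quantiles are driven by genuine structure) do not show. Passing
tests on this generator demonstrate correctness of the arithmetic and
recoverability of planted structure, not loop-calling specificity on
real data.

# Validation study sizes

The test and acceptance runs use one 2.25 Mb chromosome at 5 kb bins
(~1e5 pixel means, ~6e4 nonzero pixels under Poisson), 20 planted loops
at 5-fold over background, decay `k = 100, alpha = 1`, seed 1729 —
small enough to run in seconds, large enough that the decay exponent is
recovered within 5% under Poisson noise and within 1e-6 noise-free.

The end-to-end differential chain (extract → union → delta query →
rank) is validated on a *noise-free* pair of samples sharing 20 truth
loops with one loop's fold raised 5 → 20, scored against a
constructed truth-decay model. This isolates the pipeline mechanics:
the chain's output is then fully deterministic and the fold-changed
loop must rank first with a wide margin. Under Poisson noise the same
chain inherits the generator's false-positive floor described above
(union chains the dense background globs into large blobs whose delta
maxima are noise-dominated), which is a property of the synthetic
background's tails, not of the operations; noisy recovery is covered
separately by the planted-loop extraction test.

# Known limitations

* No statistical significance or FDR for extracted loops — extraction
  is thresholding in a normalized space, and ranking is left to
  downstream sorting.
* No matrix balancing (KR/ICE); the supported spaces are none/CPM/AQuA
  plus the inherent score.
* Inherent scoring is intrachromosomal; interchromosomal pixels are
  queryable and plottable but not scoreable.
* The native matrix format is the sparse triplet TSV; `.cool`/`.hic`
  containers are not read directly — export to triplets first.
* Cluster ids are deterministic within a run but not stable identifiers
  across different inputs.
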