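---
title: "Generalized niche-space metrics: model, algorithms and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalized niche-space metrics: model, algorithms and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichehull)
```

## The model

A community is a set of $S$ taxa, each represented by one point
$x_i \in \mathbb{R}^n$ of taxon-mean niche coordinates — isotope ratios in
‰, trophic position, diet fractions, traits. Five dispersion metrics
summarize its structure:

* per-axis **range** $\max_i x_{ij} - \min_i x_{ij}$;
* **CD**, the mean Euclidean distance of taxa to the centroid
  $\bar{x} = S^{-1}\sum_i x_i$ (overall spread / trophic diversity);
* **NND**, the mean over taxa of the distance to the nearest other taxon
  (density of species packing), and **SDNND**, the sample standard
  deviation of those nearest-neighbor distances (evenness of packing);
* **CHV**, the Lebesgue measure of the convex hull of
  $\{x_1,\dots,x_S\}$ (total occupied niche space), defined only when
  $S > n$ and the points genuinely span all $n$ dimensions.

Everything is computed on the **raw axis scales**. This is deliberate:
practitioners mix ‰, trophic-position units and dietary percent in a
single space, and the metrics are then interpreted on those units. The
consequences are documented rather than hidden — per-axis ranges are not
rotation-invariant, and a unit change on one axis changes every distance
metric. An optional `standardize = TRUE` flag z-scores each axis first,
but it is off by default because raw scales are the contract.

Assumptions worth stating: taxa are exchangeable points (no abundance
weighting); the Euclidean metric treats all axes as commensurate; and a
taxon-mean point is a sufficient summary of the taxon for the metric
itself, with within-taxon variation handled entirely by the resampling
layer.

## Convex hull volume in $n$ dimensions

No pre-packaged hull library is assumed. `convex_hull_volume()` enumerates
supporting hyperplanes directly: for every subset of $n$ points the
hyperplane through them is computed (null vector of the centered subset
via QR), and the subset lies on a hull facet iff all remaining points fall
on one side. Facets are deduplicated by their vertex sets — so several
co-hyperplanar points on one face are handled exactly once — and each
facet's $(n-1)$-measure is computed recursively in an orthonormal in-plane
coordinate frame, down to the $n = 1$ base case (max − min, which is also
the defined CHV for one-dimensional communities, as the consistent limit
of Lebesgue measure). The volume is assembled as a fan of pyramids over
the centroid, $V = \sum_f \mathrm{vol}_{n-1}(f)\, h_f / n$. Complexity is
$\binom{S}{n} \cdot S$, exact and fast at the community sizes these
metrics are used at ($S \lesssim 100$ in low dimensions); correctness is
cross-checked in the test suite against the shoelace formula in 2-D,
rejection-sampling Monte Carlo in 3-D, and $1/n!$ unit simplices in
$n = 2\dots6$.

Numerical choices:

* **Degeneracy**: if the singular values of the centered coordinate matrix
  indicate affine rank $< n$ (relative tolerance $10^{-10}$), the direct
  call raises a degenerate-geometry error rather than returning 0 — flat
  data and a genuinely tiny hull are different findings.
* **Side tests** use an absolute tolerance of $10^{-9}$ scaled by the
  point-cloud extent.
* **$S \le n$** is a hard error when `convex_hull_volume()` is called
  directly (the user asked for exactly that quantity) but a warning plus
  `NA` inside `compute_all_metrics()`, so the other metrics still flow.
  $S = n + 1$ (a simplex) is allowed: the stated requirement is the strict
  inequality $S > n$.

## Resampling and confidence intervals

Both schemes return **percentile CIs**: equal-tailed empirical quantiles
of the replicate distribution, with R's default type-7 quantile rule
(linear interpolation between order statistics; samples `1:100` at level
0.95 give 3.475 and 97.525). Percentile intervals are the minimal faithful
reading of "resampling distribution" CIs; bias-corrected variants are out
of scope. The default is $B = 10{,}000$ replicates at level 0.95.

**Non-parametric** (`nonparametric_bootstrap()`): per replicate, each
taxon's $k_t$ individuals are redrawn with replacement from its own $k_t$
records, taxon means recomputed, metrics recomputed. Resampling is
independent across taxa. Because each taxon draws from a private RNG
substream keyed by a deterministic hash of its name combined with the root
seed, adding or removing a taxon does not perturb any other taxon's
draws, and a fixed seed gives bit-identical output.

**Parametric** (`parametric_resample()`): per replicate, every
(taxon, axis) cell is drawn independently from
$\mathcal{N}(\mu, \sigma)$ truncated to the axis's declared bounds — the
shape of Bayesian mixing-model output (point estimate ± SD), truncated to
mathematically possible ranges such as $[0, 1]$ for diet fractions.
Sampling is by inverse-CDF transform, not rejection, so the draw count per
replicate is fixed and streams are seed-stable. Bounds with no admissible
probability mass are an error. Axes without user-declared bounds are
**unbounded** — in particular, no $[1, \infty)$ truncation is assumed for
trophic position, since only the diet-fraction case has an uncontroversial
mathematical range; declare bounds explicitly if you want them.

**Degenerate replicates**: a bootstrap replicate can collapse onto a
lower-dimensional subspace (e.g. resampled points collinear in 2-D), where
CHV is undefined. Such replicates are dropped from the CHV distribution
only, with the count recorded in `n_used` and a warning; all other metrics
keep every replicate. If more than half the replicates are degenerate the
CHV CI itself is reported undefined. Whether the original analyses dropped
or errored on such replicates is not documented anywhere we know of;
dropping-with-report is the conservative choice that keeps the remaining
information.

**Comparison** (`compare_communities()`): two communities differ on a
metric exactly when their CIs fail to intersect; intervals are closed, so
a shared endpoint counts as overlap. No p-values are produced — CI
non-overlap is the entire inferential device, by design.

**SDNND divisor**: sample SD ($S - 1$), matching the default of `sd()` in
the computing environment this methodology grew up in; configurable in
the sense that the nearest-neighbor distances themselves are exported.

## Amino-acid CSIA helpers

Trophic position uses
$\mathrm{TP} = ((\delta^{15}N_{Glu} - \delta^{15}N_{Phe}) - \beta)/\mathrm{TDF} + 1$
with shipped defaults $\beta = 3.4$‰ (producer-level offset between the
trophic amino acid Glutamic Acid and the source amino acid Phenylalanine)
and $\mathrm{TDF} = 7.6$‰ (per-step enrichment). Both are parameters, not
constants: published estimates vary across systems, so any value can be
passed. δ¹³C amino-acid profiles are normalized by subtracting the mean of
the *present* values (absent amino acids — e.g. Tyrosine below detection —
stay absent and are excluded, never imputed); the operation is idempotent
and the result sums to zero. `build_derived_community()` assembles the
analysis space (e.g. TP plus five diet fractions, $n = 6$) and
automatically attaches $[0,1]$ or $[0,100]$ bounds to fraction/percent
axes so the parametric resampler truncates correctly. Mixing-model
inference itself is **not** reimplemented — the package consumes mean/SD
output of that shape.

## The synthetic scenario generator

`generate_scenario()` produces paired 2-D/3-D communities whose first two
axes are *identical*, so any metric difference is attributable to the
third axis alone, plus invasion variants that add exactly three new taxa.
The base cloud is uniform in a 10 × 10 ‰ window with a minimum mutual
separation of 1‰ (so nearest-neighbor structure is non-trivial); the
third axis band is centered at −20‰. Defaults were calibrated once, at
design time, so that each archetype's documented qualitative signature
holds with margin across seeds, and then frozen:

* narrow vs wide third-axis widths default to 1‰ vs 10‰ (wide = 10×
  narrow);
* the correlated archetype uses slope 0.3 plus small jitter, bounding the
  inflation of any inter-taxon distance by $\sqrt{1 + 0.3^2} \approx 1.044$
  so CD/NND/SDNND stay within 15% of their 2-D values while the hull still
  gains a dimension;
* dispersed invaders sit at 0.5/1.5/2.5 × the 8‰ shift, making their
  mutual third-axis gaps exceed any pre-invasion nearest-neighbor
  distance, so NND and SDNND rise;
* the no-change invasion is a filled 4 × 4 lattice (spacing 2‰) with
  three vacancies — two at hull-interior nodes, one at a mid-radius edge
  node — and a checkerboard third axis of amplitude 0.4‰, which makes
  ranges, IR, NND and SDNND exactly invariant under invasion and keeps
  CD/CHV within 7%.

What the generator does **not** emulate: real covariance structure between
axes, non-normal within-taxon variation, measurement error correlated
across individuals, unbalanced sampling, or the coordinates of any real
dataset. A green scenario test therefore establishes that the metrics
respond to constructed geometry as documented — not that any particular
field system behaves this way.

`generate_individuals()` adds i.i.d. normal within-taxon noise (default
SD 0.1‰, a typical instrument-plus-tissue replicate scale for isotope
data, and small relative to the ≥ 1‰ taxon separations of the base cloud)
around taxon means, again with per-taxon substreams.

## Ingestion policy

CSV dialect is fixed (comma, `.` decimal, UTF-8, mandatory header, first
column the taxon id) — no locale inference. Missing values are errors by
default; `drop_incomplete = TRUE` drops offending rows with a logged
report. Nothing is ever imputed, mirroring how below-detection amino acids
are excluded rather than filled in. Axis bounds and run settings live in a
JSON sidecar (`read_axes_config()`), keeping data files plain; YAML is not
supported because no YAML parser is available in the supported dependency
set. Both ingestion paths — taxon means directly, or individual-level
records collapsed via `taxon_means()` — are first-class, since published
datasets come both ways.

## Known limitations

* Facet enumeration is exponential in $n$; beyond $n \approx 7$ or a few
  hundred taxa a dedicated hull library would be preferable.
* Percentile bootstrap CIs undercover when the statistic is strongly
  biased at small $k_t$; the coverage test pins the well-behaved regime
  (small within-taxon noise relative to taxon separation) only.
* CHV grows with $S$ under resampling-free comparison of unequal-sized
  communities; the resampling layer accounts for sampling variability,
  not for this size sensitivity.
* No hull-overlap statistic between two communities is provided — only
  per-metric CI comparison.
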