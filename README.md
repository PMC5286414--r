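# nichehull

Community-wide niche metrics in *n* dimensions, with resampling confidence
intervals.

Ecologists routinely summarize the structure of a community in a
δ¹³C–δ¹⁵N stable-isotope bi-plot using the classic Layman metrics: the
range of each axis, the mean distance of species to the community centroid
(CD, overall trophic diversity), the mean nearest neighbor distance (NND,
density of species packing), its standard deviation (SDNND, evenness of
packing), and the convex hull area (CHV, total occupied niche space).
Modern datasets carry far more than two axes — additional isotopes (δ³⁴S,
δ¹⁸O, δ²H), compound-specific amino-acid signatures, trophic position,
mixing-model diet fractions, fatty acids, traits. **nichehull** computes
the same five metrics in any number of dimensions and attaches
resampling-based confidence intervals so two communities can be compared
statistically by CI overlap.

For a community of *S* taxa with coordinate vectors
*x₁, …, x_S* ∈ ℝⁿ and Euclidean distance *d*:

- **Range** (per axis *j*): max *x_{ij}* − min *x_{ij}*
- **CD** = (1/S) Σᵢ d(*xᵢ*, *x̄*), with *x̄* the per-axis mean (centroid)
- **NND** = mean over taxa of min_{j≠i} d(*xᵢ*, *x_j*); **SDNND** = their
  sample standard deviation
- **CHV** = Lebesgue measure of the convex hull of {*xᵢ*} (area for n = 2,
  volume beyond); requires *S* > *n*

Two resampling schemes provide 95% (configurable) percentile CIs:

- **non-parametric** — when individual-level measurements exist, each
  taxon's *k* individuals are redrawn with replacement (independently
  across taxa), taxon means recomputed, metrics recalculated, 10,000 times;
- **parametric** — when only per-taxon mean ± SD estimates exist (the shape
  of Bayesian mixing-model output), each taxon × axis value is drawn from a
  normal distribution truncated to the axis's mathematically admissible
  range (diet fractions to [0, 1]).

The package also includes amino-acid CSIA helpers (trophic position from
the Glu–Phe δ¹⁵N offset, per-sample mean-normalization of δ¹³C profiles,
δ-notation conversion), a synthetic scenario generator for the canonical
"what can a third axis reveal?" and species-invasion archetypes, and a
command-line interface.

## Worked example

Five Ohio-River-style fish taxa (synthetic coordinates) in a 2-D isotope
space:

```r
library(nichehull)

cm <- community_matrix(
  rbind(gar     = c(-26.4,  9.1),
        buffalo = c(-22.8, 11.6),
        drum    = c(-24.1, 13.9),
        sauger  = c(-21.2, 14.8),
        catfish = c(-25.5, 12.2)),
  axes = axis_descriptor(c("d13C", "d15N"), unit = "permil"))

compute_all_metrics(cm)
#> <metric_set> S = 5 taxa, n = 2 axes
#> range_d13C range_d15N         cd        nnd      sdnnd        chv
#>  5.2000000  5.7000000  2.4487549  2.6621920  0.4700185 11.0900000
```

The community spans 5.2‰ of δ¹³C and 5.7‰ of δ¹⁵N; taxa sit on average
2.45‰ from the centroid, nearest neighbors are about 2.7‰ apart with
little unevenness (SDNND 0.47), and the hull encloses 11.09‰². With
individual-level replicates (here simulated: 10 individuals per taxon,
within-taxon SD 0.4‰), the bootstrap attaches CIs:

```r
obs <- generate_individuals(cm, k = 10, sd = 0.4, seed = 1)
cis <- nonparametric_bootstrap(obs, resampling_config(replicates = 10000L, seed = 1L))
cis
#> <metric_ci_set> nonparametric scheme, B = 10000, level = 0.95, seed = 1
#>       metric      point     lower      upper  boot_mean    boot_sd n_used
#> 1 range_d13C  5.2100052 4.8493807  5.5726568  5.2086370 0.18618905  10000
#> 2 range_d15N  5.8495491 5.5226151  6.2016482  5.8519082 0.17191626  10000
#> 3         cd  2.4755681 2.3889963  2.5772817  2.4796458 0.04810916  10000
#> 4        nnd  2.7072881 2.5718909  2.8274687  2.7022644 0.06485300  10000
#> 5      sdnnd  0.3681663 0.1837917  0.6161213  0.3975428 0.11100703  10000
#> 6        chv 10.9174817 9.7731805 12.1465752 10.9278654 0.61187158  10000
```

`compare_communities(cis_a, cis_b)` then flags exactly the metrics whose
CIs fail to overlap. Trophic position from amino-acid δ¹⁵N uses the
conventional equation with β = 3.4‰ and TDF = 7.6‰:

```r
trophic_position(21.0, 10.0)   # Glu 21.0, Phe 10.0 -> TP 2
#> [1] 2
```

## Command line

```sh
Rscript -e 'nichehull::nichehull_cli()' metrics   --input community.csv --out metrics.csv
Rscript -e 'nichehull::nichehull_cli()' bootstrap --input individuals.csv --replicates 10000 --seed 1 --out ci.csv
Rscript -e 'nichehull::nichehull_cli()' compare   --a ci_before.csv --b ci_after.csv
Rscript -e 'nichehull::nichehull_cli()' simulate  --archetype invasion_dispersed_third --seed 1 --out-dir fixtures/
```

Axis bounds and run settings can be supplied in a JSON sidecar via
`--axes-config`; every run can emit a JSON manifest (input hashes, seed,
settings) for reproducibility. An installable wrapper lives at
`system.file("exec", "nichehull", package = "nichehull")`.

## Further reading

The methods vignette (`vignettes/niche-metrics.Rmd`) documents the model
and its assumptions, the hull-volume algorithm, the resampling schemes and
their numerical choices, what the synthetic scenarios do and do not
emulate, and known limitations.
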