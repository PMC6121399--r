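---
title: "Areal cluster analysis of disease incidence: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Areal cluster analysis of disease incidence: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesospat)
```

`mesospat` analyzes disease incidence observed on a small number of areal
units — typically administrative regions like provinces — for spatial
structure: does incidence cluster, where are the hot spots, and does the
pattern track candidate exposures? This vignette records the statistical
model, the decisions behind every tunable default, and what the package's
validation does and does not establish.

## The data model

Three structures carry an analysis. A **region set** is an ordered list of
units with unique ids and planar centroids (polygons optional; centroids are
area-weighted shoelace centroids when only boundaries are supplied, because
vertex means are biased wherever digitization density varies). The input
order is the canonical index used by every downstream vector and matrix. A
**case table** holds one record per unit, year and sex stratum with a case
count and a mid-year population; the combined stratum is always derived as
male + female, and explicitly supplied combined rows must agree with that
sum — silent double counting is the classic error in registry extracts.
**Covariate vectors** map unit ids to exposure measurements.

Coordinates are treated as planar Euclidean throughout. Inputs must be in a
projected CRS (meters, not degrees); the package performs no reprojection
and no geodesy, which is the standard simplification for distance-band
weights on country-scale areal data.

## Rates

The per-unit raw morbidity rate is cumulative cases over cumulative
person-years, scaled to 100,000:
$$SS_i = \frac{\sum_{t} k_{it}}{\sum_{t} p_{it}} \times 10^5 .$$
The person-years denominator (yearly mid-year populations summed over the
period) is exact under changing populations and equals mean population
times years when the population is constant. Rates are deliberately *raw*:
age standardization requires age-resolved case counts that registry
province-level extracts of rare cancers often lack, and is out of scope.
Choropleth classification defaults to five quantile classes (robust to the
right skew typical of rare-disease rates); equal-interval bins are
available, and values tied with a breakpoint fall in the lower class.

## Spatial weights

All statistics consume a fixed-distance-band weight matrix: $w_{ij} = 1$
iff $0 < d(i,j) \le d$ between centroids. The default threshold is the
maximum over units of the nearest-neighbor distance — the smallest radius
at which no unit is isolated, which is what GIS tools compute as the
"calculated" band. Binary weights are the default for every statistic (the
G family requires them); row-standardized weights are supported for Moran's
I, whose $S_0$-normalized form is exact under both styles. Units left
without neighbors ("islands") abort the pipeline by default because silent
zero rows corrupt inference; with `allow_islands = TRUE` they are carried
as missing and labelled `not_evaluated`. Contiguity (queen/rook) weights
are intentionally not offered: the distance band plus an explicit GAL
adjacency file covers the method, and polygon-topology inference is a
different problem. Weights exchange uses the plain-text GAL format.

## Global statistics and their null moments

Moran's I is computed in the $S_0$-normalized cross-product form with the
double sum over $i \neq j$. Its null expectation is $-1/(n-1)$; for the
16-unit frame that motivated the package this is $-1/15 = -0.0667$. Two
closed-form variances are implemented: the Cliff–Ord normality moments and
the randomization (permutation) moments involving the sample kurtosis. The
pipeline defaults to **randomization**, since incidence rates are bounded,
skewed, and nothing like Gaussian. The Getis–Ord G statistic is restricted
to nonnegative variables and binary weights, as its definition requires.
Its permutation variance is computed exactly: the denominator of G is
invariant under relabeling, so the first two permutation moments of the
numerator follow from a combinatorial decomposition of ordered index pairs
(identical, reversed, one shared index, disjoint) — algebraically the
Getis–Ord moment formulas, validated in the tests against a Monte-Carlo
permutation oracle.

Both statistics also carry a permutation test (default 999 relabelings,
seeded) using the counting rule $(1 + \#\{\text{as extreme}\})/(1 +
n_{perm})$. The default alternative is one-sided "greater": the scientific
hypotheses in disease clustering are about *positive* spatial association;
a two-sided option exists. The z-score and normal p are always reported
alongside, and the pipeline guarantees `z == (observed - expected)/sqrt(variance)`
in its output tables.

## Local statistics

`local_gi()` implements both the plain $G_i$ (self excluded from numerator
and denominator) and $G_i^*$ (self included with unit weight). The starred
form is the default in the pipeline's hot-spot tables because conventional
GIS hot-spot maps use it. z-scores come from the Ord–Getis moments of each
variant: for $G_i$, exact finite-sampling moments conditional on the focal
value (which reduce to the classic $E(G_i) = W_i/(n-1)$ formula for binary
weights); for $G_i^*$, the full-randomization moments with the
$n$-denominator. Hot/cold labels bin z at 1.645/1.960/2.576 — the
90/95/99% rendering convention of standard GIS software.

`local_moran()` uses Anselin's LISA with the second moment $m_2$ computed
with denominator $n$. That scaling is chosen deliberately: it makes the
decomposition identity $\sum_i I_i = S_0 \, I$ hold exactly, which the test
suite asserts on every random instance — a strong internal consistency
check tying the local and global code paths together. Significant units
(conditional-permutation p at or below `alpha`, default 0.05) are typed by
Moran-scatterplot quadrant, where the spatial lag is the neighbor mean and
both the value and the lag are compared to their means.

Conditional permutation holds the focal unit's value fixed and reassigns
the remaining $n-1$ values at random (999 draws, seeded). It is the
package's default local inference because it is assumption-light and
doubles as the Monte-Carlo oracle for the analytic moments. One behavioral
consequence worth knowing: a lone extreme value in an otherwise homogeneous
background is *not* significant under conditional permutation — with the
focal value fixed and all other values equal, every reassignment yields the
same statistic. Significance of a spatial outlier requires its neighborhood
to differ from the exchangeable background, which is the correct behavior,
not an artifact. Benjamini–Hochberg FDR control over the per-unit p values
is available but **off by default**, matching how local cluster maps are
conventionally reported; it is a sensitivity-analysis flag, not a detection
default.

## Correlation

Spearman's $r_s$ is the Pearson correlation of midranked values, with
pairing by unit-id intersection and an explicit report of dropped units —
exposure measurements frequently cover only a subset of the frame.
Midranks matter because registry-style covariates carry ties. A two-sided
permutation p (shuffling one margin) accompanies the estimate.

## The synthetic study generator

The generator emulates the structure the analysis assumes, on a unit-spaced
square lattice (default $4 \times 4 = 16$ units, matching a province-scale
frame) over 1999–2013:

| parameter | default | rationale |
|---|---|---|
| `baseline_rate` | 0.5 /100k person-years | rare-cancer order of magnitude; national mesothelioma-type incidence, below the ~0.7 implied by the most affected provinces |
| `population_log_mean`, `_sd` | log(2e6), 0.45 | the spread of Polish province populations (~1–5.5M) |
| `relative_risk` | 2 | a moderate, plausibly detectable environmental excess |
| `cluster_radius` | 1 grid unit | a compact cluster: seed plus rook neighbors |
| `sex_split` | 0.64 male | the 64%/36% male/female case split reported for mesothelioma |
| `covariate_noise_sd` | 0.25 (rate units) | exposure proxy correlated with, but far from collinear with, true risk |
| population jitter | ±1% per year | exercises the person-years denominator without adding real variance |

Per unit and year, stratum case counts are Poisson with mean
`true_rate x sex_share x population / 1e5`; recorded per-sex denominators
are half the unit population, so the male stratum carries the higher rate,
as in real mesothelioma registries. The truth record (cluster membership,
true rates) supports sensitivity/specificity scoring via
`parameter_recovery_report()`.

What the generator does **not** emulate: real administrative geometry
(irregular polygons, heterogeneous areas), exposure–disease latency (for
mesothelioma the lag can exceed 40 years; the generator's covariate is
contemporaneous with risk), spatially structured background risk beyond the
single planted cluster, and reporting artifacts such as under-registration.
Passing tests therefore demonstrate that the statistics and their inference
are correct *given* Poisson sampling around a piecewise-constant risk
surface — not that the pipeline's labels on any real registry are
substantively right.

## Numerical choices and degenerate inputs

Constant variables are rejected with explicit errors (both Moran forms, the
G family and rank correlation are undefined there); all-tied rate vectors
classify into a single class with a warning; duplicate centroids warn
(zero-distance links) rather than abort; variances are floored at zero
against floating-point cancellation; permutation counting uses the
add-one rule so p values never reach zero; ties at classification
breakpoints go to the lower class; ties among permuted statistics count as
"as extreme" (a small conservative bias). All permutation machinery is
seeded, and a pipeline run is byte-identical given the same inputs and
seed; the run log records every defaulted decision (threshold, weight
style, alternative, bins) so a run can be audited.

## Validation strategy and problem sizes

The test suite validates every statistic against literal double-loop
transcriptions of the definitions on 200 random instances (up to 49
units), checks the LISA decomposition identity to 1e-10, calibrates the
global permutation test's type-I error on a 6x6 lattice (500 replicates of
199 permutations, accepted within [0.03, 0.07] at the nominal 0.05), checks
the randomization variance of I against 200,000 random permutations within
2%, and measures planted-cluster recovery on a 7x7 frame (200 replicates:
sensitivity of $G_i^*$ at relative risk 4 with a 1.5/100k baseline and 2M
populations; specificity about 0.95 under relative risk 1). These problem
sizes keep the whole suite around three minutes on one CPU while leaving
Monte-Carlo error well inside the asserted bands.

## Known limitations

Small-$n$ frames (a dozen to a few dozen units) put normal approximations
for the global statistics under strain — that is why permutation inference
is the default and the analytic moments are reported as a cross-check, not
the other way round. The G family requires naturally positive variables;
centered or signed covariates should go through Moran's I only. No spatial
regression, no space-time scan statistics, no age standardization, no
geodesic distances, and no polygon-contiguity weights: each is either a
different method family or requires inputs this package deliberately does
not assume.
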