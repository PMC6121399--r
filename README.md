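# mesospat

Spatial autocorrelation analysis of areal disease incidence.

`mesospat` implements the province-scale disease-mapping workflow used in
registry-based spatial epidemiology of rare, exposure-driven cancers such as
malignant mesothelioma: cumulative raw morbidity rates per areal unit,
fixed-distance-band spatial weights, global and local spatial autocorrelation
statistics with analytic and permutation inference, hot-spot and LISA cluster
maps, and rank correlation of incidence with exposure covariates (for
example, asbestos-cement roofing stock or airborne fiber concentrations). It
is aimed at epidemiologists and spatial analysts who have a polygon (or
centroid) frame of administrative units, a stratified case/population table,
and want a reproducible, scriptable alternative to point-and-click GIS
hot-spot tools.

Because registry microdata typically cannot be redistributed, the package
ships a first-class synthetic study generator — a lattice of areal units
with lognormal populations, stratified Poisson case counts, a planted
spatially clustered relative risk, and a correlated exposure proxy — so that
every stage of the pipeline, including its statistical calibration, can be
tested end to end.

## The statistics

For a variable $x_i$ observed on $n$ areal units with spatial weights
$w_{ij}$ (all sums over $i \neq j$):

- **Raw morbidity rate**: $SS = \frac{\sum_j k_j}{\sum_j p_j} \times 100{,}000$,
  cumulative cases over cumulative person-years (mid-year populations summed
  over the study years), unadjusted for age.
- **Global Moran's I**:
  $I = \frac{n \sum_i \sum_j w_{ij}(x_i-\bar x)(x_j-\bar x)}{S_0 \sum_i (x_i-\bar x)^2}$
  with $S_0 = \sum_i\sum_j w_{ij}$; null expectation $E(I) = -1/(n-1)$,
  variance from the Cliff–Ord normality or randomization moments.
- **Global Getis–Ord G**:
  $G = \frac{\sum_i \sum_j w_{ij} x_i x_j}{\sum_i \sum_j x_i x_j}$ for a
  nonnegative variable and binary weights, with exact permutation moments.
- **Local Getis–Ord $G_i(d)$ / $G_i^*$**: the share of the variable total in
  unit $i$'s distance-band neighborhood, excluding ($G_i$) or including
  ($G_i^*$) the unit itself; z-scores from the Ord–Getis moments, hot/cold
  bins at 90/95/99% confidence.
- **Local Moran's I (LISA)**:
  $I_i = \frac{x_i-\bar x}{m_2} \sum_j w_{ij}(x_j-\bar x)$ with
  $m_2 = \sum_k (x_k-\bar x)^2 / n$, so that
  $\sum_i I_i = S_0 \, I$; significant units are typed
  High–High / Low–Low / Low–High / High–Low by Moran-scatterplot quadrant,
  with conditional-permutation p values.
- **Spearman's $r_s$** with midrank tie handling, for exposure–incidence and
  male–female rate associations.

Weights come from the fixed distance band: $w_{ij} = 1$ iff
$0 < d(i,j) \le d$, with the default threshold the maximum nearest-neighbor
centroid distance (the smallest band giving every unit a neighbor).
Coordinates are treated as planar Euclidean — supply projected-CRS data.

## Worked example

Simulate a 16-unit study (15 years, male/female strata, a planted
relative-risk-3 cluster around unit `U_1_1`) and run the full pipeline:

```r
library(mesospat)
cfg   <- sim_config(rng_seed = 42, relative_risk = 3, cluster_seed_unit = "U_1_1")
study <- simulate_cases(cfg)
res   <- run_pipeline(study$regions, study$cases,
                      covariates = study$covariates, n_perm = 999, seed = 42)
res
#> pipeline_result over 16 units; 3 strata
#>
#> Global statistics:
#>   stratum   statistic observed expected  variance      z  p_normal p_perm
#> 1     all     moran_i  0.15835 -0.06667 0.0353423 1.1969 0.1156717  0.107
#> 2     all getis_ord_g  0.24808  0.20000 0.0003578 2.5418 0.0055135  0.010
#> 3    male     moran_i  0.09788 -0.06667 0.0352296 0.8767 0.1903297  0.183
#> 4    male getis_ord_g  0.24199  0.20000 0.0003663 2.1941 0.0141127  0.013
#> 5  female     moran_i  0.25475 -0.06667 0.0349294 1.7198 0.0427356  0.029
#> 6  female getis_ord_g  0.25869  0.20000 0.0003578 3.1031 0.0009575  0.002
```

`expected` is the analytic null value ($-1/15 = -0.0667$ for Moran's I on 16
units; $S_0/(n(n-1))$ for G), `z` the standard normal deviate
`(observed - expected)/sqrt(variance)`, `p_perm` the one-sided permutation p
(999 relabelings). Here the concentration statistic G is clearly significant
in every stratum while Moran's I reaches significance only for women —
with 16 units and a compact cluster, G is the more sensitive of the two.

The Gi* hot-spot table flags the planted cluster seed:

```r
subset(as.data.frame(res$local$gi_star$all), label != "not_significant")
#>   unit_id statistic        z     p_normal p_perm  label
#> 6   U_1_1 0.5798733 3.867743 0.0001098474  0.002 hot_99
```

and the correlation report recovers the built-in exposure–incidence
association and the male/female concordance:

```r
res$correlations
#>                      pair       r_s  n p_perm
#> 1   male_rate~female_rate 0.6411765 16  0.010
#> 2 exposure_index~all_rate 0.8294118 16  0.001
```

`run_pipeline(..., out_dir = "out")` writes `rates.csv`, `weights.gal`,
`global_stats.csv`, per-stratum local tables and `run_log.txt`; a thin CLI
wrapper lives at `inst/scripts/mesospat.R` (`simulate` and `run`
subcommands).

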