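---
title: "Methods: neighbourhood hot-spot analysis of hospitalisation rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neighbourhood hot-spot analysis of hospitalisation rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoodspot)
```

This vignette is the package's own account of its methods: the statistical
procedure each stage implements, the assumptions behind it, the parameters
that matter and why their defaults are what they are, and the numerical and
design choices made where the design was genuinely open.

## 1. The analysis in one paragraph

Patient-level discharge records are classified into pneumonia-associated
hospitalisations (non-severe: principal pneumonia diagnosis; severe:
principal sepsis or respiratory-failure diagnosis with a secondary pneumonia
diagnosis). Per neighbourhood, annual directly age-standardised rates per
100,000 are computed and averaged over the study years. A semivariogram
model fitted to the rate surface defines a *range of spatial
autocorrelation* — the distance beyond which neighbourhood rates are
effectively uncorrelated — which is validated against the first peak of an
incremental global Moran's *I* z-score profile and then used as the fixed
bandwidth of distance-band spatial weights. Local Moran's *I* with
conditional permutation inference classifies each neighbourhood as hot spot
(HH), cold spot (LL), spatial outlier (HL/LH) or not significant, and
patients pooled across hot spots are compared with patients pooled across
cold spots.

## 2. Cohort definition

`classify_severity()` matches ICD-9-CM codes exact-or-prefix on dot-stripped
strings ("482" covers the 482.x family). The default code lists are a
reconstruction of the Lindenauer-style claims definition — pneumonia 480–486
and 487.0; sepsis 038.x, 995.91, 995.92, 785.52; respiratory failure 518.81,
518.82, 518.84, 799.1 — and are fully overridable through `code_map()`,
which enforces that the pneumonia set is disjoint from the other two.
Severity classes are mutually exclusive by construction: the principal
diagnosis decides non-severe, and only non-pneumonia principals are eligible
for severe.

`filter_cohort()` keeps adults (age ≥ 18) in known residential regions whose
*admission* date falls in the study window (inclusion is by admission, not
discharge, since a study window phrased as "admitted during" refers to
admissions). Every excluded record carries exactly one reason, evaluated in
a fixed order (`missing_principal`, `not_case`, `under_18`,
`unknown_region`, `non_residential`, `outside_study_window`), so the kept
count plus the exclusion tally always equals the input count.

## 3. Direct age standardisation

For age group $g$ with $e_g$ events and population $n_g$, the age-specific
rate is $r_g = e_g / n_g \times 10^5$; the adjusted rate is
$R = \sum_g p_g\, r_g$ with standard weights $p_g$ renormalised over the
groups present (so a single-group region's adjusted rate equals its crude
rate, and splitting a group into sub-groups with equal rates leaves $R$
unchanged — both are tested invariants).

Choices made where the source analysis left details open:

* **Age bands** default to 18–44, 45–64, 65–74, 75–84, 85+ — conventional
  adult standardisation bands; configurable via `standard_population()`.
* **Standard weights** derive from the US 2000 standard million restricted
  to the adult bands and renormalised, treating single years as uniform
  within each 5-year standard band.
* **"Average annual"** is the arithmetic mean of the annual adjusted rates,
  not pooled events over pooled person-years; the two coincide when
  populations and rates are constant over years (tested).
* **Degenerate inputs**: an age group with zero population and zero events
  is skipped with a warning (its weight is renormalised away); zero
  population with positive events is an error, because it indicates a
  mismatch between records and denominators.

The **reliability screen** flags an outcome when, among regions with any
events, more than `max_fraction` (default 0.5) have a non-zero total count
below `count_floor` (default 10): adjusted rates built from counts under 10
are too unstable to cluster, which is why a sparse outcome such as
ventilator-associated pneumonia skips cluster analysis. **Quartile classes**
are rank-based with class sizes differing by at most one (lower classes
absorb the remainder) and ties broken by region id; if every rate is equal
there is no gradient to classify and all regions fall in Q1 with a warning.

## 4. Semivariogram and the range of spatial autocorrelation

The empirical semivariogram is the classical Matheron estimator over lag
bins: $\hat\gamma(h) = \frac{1}{2N(h)}\sum_{(i,j)\in h}(v_i - v_j)^2$. The
default binning is 12 equal-width lags up to half the maximum pairwise
distance; bins with no pairs are flagged empty, never silently dropped.

Model fitting minimises the Cressie-weighted SSE
$\sum_h N(h)\,(\hat\gamma_h - \gamma_\theta(h))^2 / \gamma_\theta(h)^2$ over
$\theta = (c_0, c, a)$ for the spherical, exponential and gaussian families,
keeping the family with the smallest weighted SSE. The weights stabilise
small-count bins, standard practice for variogram estimation. Numerics:
Levenberg–Marquardt (`minpack.lm::nls.lm`) with box constraints
($c_0, c \ge 0$, $a$ within $[10^{-6}, 20] \times$ max lag), multi-start
over three initial effective ranges (25/50/75% of the max lag) and two
initial nugget fractions; a division guard of $10^{-8}\bar\gamma$ protects
the weights. On noiseless input the truth is recovered to better than
$10^{-3}$ relative (tested).

The reported range is always the **effective range**: $a$ for spherical,
$3a$ for exponential, $\sqrt{3}\,a$ for gaussian (95% of the sill for the
latter two). A fit is declared a failure — "no range of spatial
autocorrelation definable" — when any of these hold:

* fewer than 4 usable lag bins;
* the optimiser fails for every family/start;
* the fitted effective range exceeds the maximum lag (the model never
  plateaus inside the observed window);
* the structured fraction $c/(c_0+c)$ falls below 0.05 (essentially pure
  nugget);
* the fitted effective range is at or below the first lag centre. This last
  rule is a resolution argument: a flat, pure-nugget empirical variogram is
  fitted equally well by *any* nugget/sill split with a range smaller than
  the first bin, so such a range is not identifiable and claiming one would
  be spurious.

A failed fit propagates: the pipeline skips clustering for that outcome and
records the status, mirroring how an analysis that cannot define a range
performs no cluster detection.

**Pipeline cutoff.** When `run_pipeline()` fits the variogram it uses a
shorter cutoff — one third of the maximum pairwise distance — rather than
the standalone half-distance default. Rate surfaces with a strong localised
cluster (exactly what a hot-spot analysis expects to find) inflate
semivariance at long lags, and the monotone model families will chase that
rise into "range exceeds maximum lag" failures; restricting the fit to the
first third of the distance window, the conventional trend-robust choice in
geostatistical software, keeps the fit focused on the short-range structure
that defines the bandwidth. Both cutoffs are available everywhere via
`max_lag`.

## 5. ISA validation

`isa_profile()` recomputes global Moran's *I* over increasing distance
bands, each with expectation $E[I] = -1/(n-1)$ and variance under the
randomisation assumption, hence a z-score per distance. The first peak
(z exceeding both neighbours; leftmost point of a plateau; a first band
higher than the second also counts) estimates the scale of strongest
clustering. Defaults: the first band is the smallest distance at which every
region has a neighbour; 10 bands up to half the maximum pairwise distance.
A monotone profile reports the last distance flagged "no interior peak", and
bands leaving regions neighbourless are flagged, not dropped. The
semivariogram range and the ISA first peak are different estimators of
related but distinct quantities, so the package's consistency check asks
only for factor-of-2 agreement, which simulations with a known 5 km range
meet for a clear majority of replicates.

## 6. Local Moran's I and conditional permutation inference

With deviations $z_i$ from the global mean and row-standardised
distance-band weights (binary available via `row_standardise = FALSE`),

$$I_i = \frac{z_i}{m_{2,i}} \sum_j w_{ij} z_j, \qquad
  m_{2,i} = \frac{\sum_{k \ne i} z_k^2}{n-1}.$$

The second-moment convention excluding the focal region is the default; the
pooled $\sum_k z_k^2 / n$ convention is a switch, and the brute-force test
oracle follows whichever is active, because published implementations differ
on this point. Regions with no neighbour inside the bandwidth are reported
as isolates and excluded from inference rather than silently dropped.

**Inference.** For region $i$, the observed value stays fixed while its
$k_i$ neighbours' values are redrawn $B$ times without replacement from the
other $n-1$ values; the pseudo p-value is $(G+1)/(B+1)$, with $G$ the count
of permuted $I_i$ at least as extreme as observed in the direction of the
observed sign (the common LISA convention; a two-sided alternative is
available). The smallest attainable pseudo p is exactly $1/(B+1)$, and with
the default $B = 999$ significance is assessed at the 5% level with no
multiple-testing correction, matching common practice for this analysis.
Each region draws from an independent stream seeded by the master seed and
the region id's rank, sampling from the *sorted* value pool — this makes
results simultaneously independent of evaluation order and exactly invariant
under a consistent relabelling of regions (both tested).

**Calibration.** Under a spatially unstructured null the two sign-directed
tails are disjoint and each carries mass $\alpha$, so the event
"pseudo p ≤ α" occurs at rate $\approx 2\alpha$ — the well-known
anti-conservatism of one-sided LISA pseudo p-values. The quantity that *is*
calibrated at $\alpha$ is the rate of false **cluster** detections, i.e.
labels HH or LL (positive $I_i$ with p ≤ α); the spatial-outlier labels
HL/LH carry the mirror $\alpha$. The package's calibration test therefore
measures the false hot/cold-spot rate, which sits within [0.03, 0.07] at
$\alpha = 0.05$ over 500 null replicates (B = 199). Users who want the raw
rejection event calibrated at $\alpha$ should halve $\alpha$ or use the
two-sided alternative.

**Classification.** Significant regions are labelled by quadrant — HH
($z>0$, lag $>0$), LL, HL, LH — with one $\alpha$ applied to all four
classes (whether outliers were filtered at the same level as clusters was
left open by the analysis this package follows; one level for all is the
simplest defensible choice). A region exactly at the global mean, or with a
zero lag, stays NS regardless of p.

## 7. Hot-vs-cold comparisons

Patients are pooled across all HH regions and all LL regions. Mean age is
compared with the Wilcoxon rank-sum test (exact enumeration below a combined
n of 20 without ties; otherwise normal approximation with tie-corrected
variance and continuity correction — `stats::wilcox.test` provides exactly
this contract). Length of stay is summarised as median and IQR using Tukey's
lower/upper-half hinges (`stats::fivenum`). Every categorical variable is
tested per category as a 2×2 hot/cold × category/other Pearson χ² without
continuity correction (df = 1 for every test, matching the per-category
design; an omnibus test is deliberately not used). Cells with expected
counts below 5 are flagged; missing category values are excluded from that
variable's tests and tallied explicitly; p-values are reported to two
decimals with "<0.01" flooring. A variable with a single category, or a
category producing a zero margin, is skipped with a warning.

## 8. What the synthetic generator emulates — and what it does not

`simulation_config()` defaults define the study conditions the package is
validated under:

| parameter | default | rationale |
|---|---|---|
| grid | 14 × 14 cells of 2000 m, 8 non-residential | 188 residential neighbourhoods of ~4 km², the scale of a large city's neighbourhood units |
| study years | 2010–2014 | five annual rate surfaces |
| latent field | spherical, $c_0=0$, $c=0.25$, range 5000 m | log-scale field whose range matches the ~5–6 km ranges such analyses report |
| base rate | 440 / 100,000 person-years | ≈ 140k hospitalisations over 5 years among ~6.4M adults |
| mean region population | 30,000 adults | big-city neighbourhood denominators |
| severity mix | 56.5% / 43.5% | observed non-severe/severe split |
| setting mix | CAP 62.4, HCAP 27.2, HAP 8.7, VAP 1.7% | observed setting-of-acquisition split |
| hot block | 4 × 4 cells, rate × 2.5 | a contiguous elevated-burden district at the grid edge |
| LOS | lognormal, median 10 d (σ=0.81) hot / 5 d (σ=0.89) cold | medians and IQR shapes of severe hot/cold patients |
| in-hospital death | 24.5% hot / 10.1% cold | severe hot/cold contrast |
| race/ethnicity, age mixes | hot/cold conditional | hot spots younger, more non-Hispanic Black/Hispanic |

The field is drawn by dense Cholesky factorisation of the covariance over
centroids (exact for grids up to a few thousand cells; the nugget enters as
independent noise), and multipliers are $\exp(\text{field} - c/2)$ so the
mean multiplier is ≈ 1 and `base_rate` keeps its interpretation. Event
counts are Poisson with mean population × base_rate × multiplier / 100,000
per region × age group × year. Identical configurations (including the seed)
reproduce byte-identical outputs.

Deliberate non-goals, which bound what passing tests show about real data:
no realistic geography (a square grid, not real polygons), no census
demographics, no geocoding error, no seasonal or pandemic structure in
admissions, no readmission/transfer linkage (records are hospitalisations,
not persons), and **no age gradient in hospitalisation risk** — event means
follow the population × rate formula uniformly across age groups, so
hot/cold age contrasts arise only from the cluster-conditional population
age mixes and are milder than those of real patients. The hot block is a
sharp rectangle; real hot spots have soft edges, so label counts around a
real cluster's rim will be noisier than in the planted-block test.

## 9. Problem sizes used for validation

The test suite validates parameter recovery at desk scale, chosen to give
stable Monte Carlo estimates: variogram range recovery and ISA consistency
on a 20 × 20 grid over 20 seeds; null calibration on a 7 × 7 grid over 500
replicates with B = 199; planted-cluster recovery (3 × 3 block at 3× rate on
a 20 × 20 grid) over 20 seeds; oracle equivalence of global and local
Moran's I against independent brute-force double sums on fixtures up to 25
nodes at $10^{-12}$ tolerance; and the full pipeline end to end on a 10 × 10
grid, including byte-identical reruns. `scripts/acceptance.R` runs the full
default-scale study (188 regions, ~135k records, B = 999) in a few minutes.

## 10. Known limitations

* The variogram families are isotropic and stationary; a strong planted
  cluster technically violates stationarity, which is precisely why the
  pipeline uses the shorter fitting cutoff (§4).
* One-sided pseudo p-values are anti-conservative for the raw rejection
  event (§6); the package documents and tests the calibrated cluster-label
  rate instead of hiding the distinction.
* No multiple-testing correction across regions, by design fidelity to the
  analysis being reproduced; with ~190 regions, a handful of false labels at
  α = 0.05 is expected and should be read accordingly.
* Adjusted-rate confidence intervals and empirical-Bayes smoothing are out
  of scope, as are kriging, anisotropy, Getis–Ord G*, space–time scanning
  and regression modelling of cluster membership.
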