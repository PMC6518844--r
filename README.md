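# hoodspot

Neighbourhood-level hot-spot analysis of pneumonia-associated
hospitalisations.

`hoodspot` is an R package for small-area spatial epidemiology of hospital
discharge data. It was built around one concrete question: *which
neighbourhoods of a large city carry a significantly elevated burden of
pneumonia hospitalisation, and how do the patients in those hot spots differ
from patients in cold spots?* Because patient-level all-payer discharge data
are restricted, the package ships a synthetic study generator with a
programmed, spatially autocorrelated rate surface, so that every stage of the
analysis can be exercised, tested and calibrated end to end on data whose
truth is known.

## The analysis

1. **Case classification** (`classify_severity()`, `filter_cohort()`).
   A *non-severe pneumonia-associated hospitalisation* is an inpatient
   discharge with a principal ICD-9-CM diagnosis of pneumonia; a *severe*
   one has a principal diagnosis of sepsis or respiratory failure with a
   secondary diagnosis of pneumonia. Adults (≥ 18) resident in residential
   neighbourhoods and admitted within the study window are kept; every
   exclusion is tallied under one reason.

2. **Direct age standardisation** (`build_rate_surface()`). Per
   neighbourhood and year, age-specific rates
   `r_g = events_g / population_g × 100 000` are weighted by standard
   population proportions `p_g` and summed, `R = Σ_g p_g r_g`; annual
   adjusted rates are averaged over the study years. Outcomes dominated by
   small counts (`reliability_screen()`) are excluded from clustering.

3. **Range of spatial autocorrelation** (`empirical_variogram()`,
   `fit_variogram_model()`). The Matheron semivariogram
   `γ̂(h) = (1/2N(h)) Σ (v_i − v_j)²` is fitted by Cressie-weighted least
   squares to spherical/exponential/gaussian models; the fitted *effective
   range* is the distance beyond which rates are effectively uncorrelated.
   If no range can be defined the outcome skips clustering. The range is
   cross-validated against the first peak of an incremental global Moran's
   *I* z-score profile (`isa_profile()`).

4. **Cluster detection** (`lisa()`). The effective range becomes the fixed
   bandwidth of distance-band spatial weights. Local Moran's
   `I_i = (z_i/m_{2,i}) Σ_j w_ij z_j` is tested by conditional permutation
   (999 draws by default; pseudo `p = (G+1)/(B+1)`), and significant regions
   are classified as hot spots (HH), cold spots (LL) or spatial outliers
   (HL/LH).

5. **Hot vs cold comparison** (`compare_clusters()`). Mean age (Wilcoxon
   rank-sum), length-of-stay median/IQR, and per-category 2×2 χ² tests
   (df = 1) for sex, race/ethnicity, setting of acquisition, disposition and
   in-hospital death.

`run_pipeline()` orchestrates all stages per outcome (overall, severe, CAP,
HCAP, HAP, VAP) and writes CSV/GeoJSON/JSON artifacts plus a provenance
manifest.

## Worked example

```r
library(hoodspot)

cfg  <- simulation_config(seed = 42)   # 188 residential regions, 5 study years
sim  <- simulate_study(cfg)
pipe <- run_pipeline(sim$regions, sim$records, sim$population,
                     outcomes = c("overall", "severe"), B = 999, seed = 42)
print(pipe)
#> Hot-spot analysis pipeline
#> cohort: 133312 hospitalisations kept, 0 excluded
#>   overall  ok  range 6249 m, HH 24, LL 40
#>   severe   ok  range 6187 m, HH 24, LL 39
```

The cohort composition mirrors the programmed case mix — 43.5% of the
133,312 hospitalisations are severe, 62.7% CAP, 27.0% HCAP, 8.7% HAP, 1.7%
VAP. The overall rate surface yields:

```r
print(pipe$outcomes$overall$variogram)
#> Semivariogram model (spherical)
#>   nugget c0: 6.575e+04   partial sill c: 1.323e+05   sill: 1.981e+05
#>   range parameter a: 6248.9 m   effective range: 6248.9 m
summary(pipe$outcomes$overall$lisa)
#>      HH      LL      HL      LH      NS ISOLATE
#>      24      40       7      12     105       0
```

so rates are spatially correlated out to about 6.2 km, and 24 neighbourhoods
form hot spots (the generator planted a contiguous high-rate block plus a
5 km-range random field). Comparing severe-pneumonia patients in hot vs cold
spots recovers the programmed contrasts: mean age 44.9 vs 49.5 years, median
length of stay 9 vs 5 days, in-hospital death 21.6% vs 9.5% (χ² df = 1,
p < 0.01).

Real data enter the same way: `read_regions()` (GeoJSON, projected planar
metres), `read_records()` and `read_population()` (CSV), or a validated
config file via `read_pipeline_config()`.

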