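# t1ecv

Quantitative MRI analysis of skeletal calf muscle for the study of
peripheral artery disease (PAD): voxelwise inversion-recovery T1 mapping,
per-compartment T1 metrics, and extracellular volume fractions (ECV),
with the statistical layer used to compare patient groups — plus a
synthetic mid-calf phantom and cohort generator so the entire pipeline is
verifiable against known ground truth without patient data.

Intended users: imaging scientists and biostatisticians working with
MOLLI-style inversion-recovery acquisitions of the lower extremities who
need a tested, scriptable re-implementation of the compartment-level
T1/ECV analysis chain.

## The model

Each voxel's signal across inversion times follows the three-parameter
inversion-recovery model

```
y(TI) = A − B · exp(−TI / T1)
```

with `A` the signal scale and `B` the inversion amplitude. `ir_fit()`
estimates `(A, B, T1)` per voxel by Levenberg–Marquardt least squares
(compiled, analytic Jacobian), restoring the sign that magnitude
reconstruction discards by exhaustively testing every monotone polarity
candidate. `fit_t1_map()` applies the fit image-wide; invalid voxels
(non-convergence, bound-limited T1, degenerate amplitude) are flagged,
never silently zeroed.

Per compartment — anterior (AM), lateral (LM), deep posterior (DM)
muscle groups, soleus (SM) and gastrocnemius (GM) — the analysis reports
the peak (maximum), mean, and minimum T1 and the cross-sectional area;
the blood pool T1 averages the per-artery peaks of the anterior tibial,
posterior tibial and peroneal arteries. ECV then follows from
pre/post-contrast T1 and hematocrit:

```
ECV = (1 − hct) · [1/T1m_post − 1/T1m_pre] / [1/T1b_post − 1/T1b_pre]
```

The statistical layer reproduces the study design: Shapiro–Wilk-gated
t / Mann–Whitney–Wilcoxon group comparisons, chi-square / Fisher exact
tests, univariate linear regression (standardized β, R², adjusted r²),
and two-way random-effects average-measures ICC with 95% CI.

## Worked example

```r
library(t1ecv)
set.seed(1)

ti <- c(90, 240, 756, 923, 1440, 2106, 2790)   # MOLLI schedule, ms
y  <- ir_signal(ti, A = 1000, B = 1950, t1 = 1400, magnitude = TRUE)
fit <- ir_fit(abs(y + rnorm(7, 0, 20)), ti)
fit
#> Inversion-recovery fit: y = A - B * exp(-TI/T1)
#>   A = 1029, B = 1966, T1 = 1460.4 ms
#>   7 samples (magnitude), polarity index 4, rss = 1611
```

The fitted T1 of 1460 ms recovers the true 1400 ms within the noise; the
polarity index 4 says the first four samples lay below the null point.
The same machinery scales to a full synthetic mid-calf section:

```r
ph       <- generate_phantom(phantom_config(dims = c(64, 64), seed = 42))
mask     <- region_union(ph$regions)
map_pre  <- fit_t1_map(ph$pre,  mask = mask)
map_post <- fit_t1_map(ph$post, mask = mask)
map_pre
#> T1 map: 64 x 64 pixels, 1221 fitted voxels (1221 valid)
#>   T1 (ms): 5% 1649 | median 1891 | 95% 2192

compartment_metrics(map_pre, ph$regions$labels$AM)
#> T1 metrics: peak 2346.7 | mean 1857.5 | min 1492.3 ms; CSA 539 mm2 (246 voxels)

b_pre  <- blood_pool_t1(map_pre,  ph$regions)
b_post <- blood_pool_t1(map_post, ph$regions)
am_post <- compartment_metrics(map_post, ph$regions$labels$AM)
100 * compute_ecv(2346.7, am_post$peak_t1_ms, b_pre, b_post, 0.40)
#> [1] 26.3
```

The anterior-compartment ECV of 26.3% lands in the configured range.
Note the region *peak* (2347 ms) sits well above the underlying voxel T1
(1835 ms): a maximum over ~250 noisy fits is upward-biased, which is why
the cohort generator calibrates configured peak values as observed
quantities (see the methods vignette).

Cohort-scale work goes through `cohort_config()` → `generate_cohort()` →
`analyze_cohort()` (or `run_pipeline()`, which also writes CSV tables
and a provenance record).

## Acceptance script

`scripts/acceptance.R` regenerates the calibrated synthetic cohort
(50 PAD + 50 control subjects, 64 × 64 grid, SNR 50 Rician noise), runs
the full fit → ROI → ECV pipeline on every subject, and writes the
recovered group medians (anterior and soleus ECV per group, and the
PAD-group five-compartment averaged native peak T1) as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
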