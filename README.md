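# ctpsharp

Contour-sharpness analysis for dynamic (4D) myocardial CT perfusion.

Dynamic CT perfusion acquires one low-dose 3D volume per heart beat while
a contrast bolus passes through the myocardium. Temporal averaging — the
voxel-wise arithmetic mean of N consecutive volumes centred on a reference
beat, `I_N(x) = (1/N) Σ I(x, t_i)` — reduces noise by `1/√N` but blurs
edges whenever the heart moves between beats; iterative-style
reconstruction trades sharpness for noise in a similar way. `ctpsharp` is
for imaging researchers who want to quantify that trade-off. It measures
myocardial contour sharpness on a line probe crossing the heart in the
4-chamber view, at four representative edges (RV/septum, septum/LV,
LV/lateral wall, lateral wall/epicardium), using two edge-spread
statistics:

* **d (mm)** — distance between the 25% and 75% crossings of the edge's
  normalised grey-value range (for a Gaussian edge of width σ,
  d = 1.3490 σ);
* **m (HU/mm)** — the edge slope, `m = 0.5 · range / d`.

Small d and large m mean a sharp contour. The package implements the full
pipeline: NIfTI 4D I/O, reference-beat selection (maximal LV−RV blood-pool
contrast), windowed temporal averaging, trilinear line-probe sampling with
sub-sample crossing interpolation, and the paired statistical cascade
(Shapiro–Wilk gate, repeated-measures ANOVA or Friedman overall test,
paired t or Wilcoxon signed-rank single comparisons, Bonferroni
correction — 15 pairs and a printed threshold of 0.003 for six averaging
levels). A configurable 4D digital cardiac phantom (gamma-variate
first-pass enhancement, acquisition blur, noise, beat-to-beat motion
jitter, FBP-like and IR-like reconstruction surrogates) makes every stage
testable without patient data.

## Worked example

Simulate a small cohort, average each subject's series at several levels,
measure the four edges of every averaged volume, and compare m across
levels:

```r
library(ctpsharp)

sp     <- phantom_spec(matrix = 128, n_slices = 4, motion_amp_mm = 0.5)
cohort <- generate_cohort(8, sp, seed = 7)
pr     <- cohort_probes(cohort)
avg    <- build_averaged_set(cohort, levels = c(1, 2, 4, 8))
tab    <- measure_cohort(avg, pr$probes, pr$sections)
head(as.data.frame(tab), 4)
#>   subject_id recon_variant averaging_level edge_label  d_mm m_hu_per_mm
#> 1        S01      fbp_like               1          1 1.405        39.6
#> 2        S01      fbp_like               1          2 0.893       138.7
#> 3        S01      fbp_like               1          3 1.138       115.9
#> 4        S01      fbp_like               1          4 0.988        89.3

sharpness_stats(tab, "m", factor = "averaging_level", edge = "pooled")
#> Contour sharpness m, edge pooled, by averaging_level (8 subjects, parametric branch)
#>   overall RM-ANOVA: statistic 39.869, p = 7.508e-09
#>   6 pairwise comparisons, Bonferroni alpha 0.008333 (<0.008)
#>   condition  mean     sd
#> 1         1 87.93 10.539
#> 2         2 82.91  8.448
#> 3         4 78.22  5.982
#> 4         8 64.10  3.203
```

Each measurement row is one (subject, reconstruction, averaging level,
edge). The report shows the cascade on the pooled per-subject means: the
values were normal at every level (parametric branch), the
repeated-measures ANOVA detects a level effect, and the per-level means
fall from 87.9 to 64.1 HU/mm — the edge slope degrades as more beats are
averaged, which is exactly the noise-for-sharpness trade temporal
averaging makes. `sharpness_summary(tab, "d")` prints the matching
condition-by-edge table of `mean (SD)` cells.

The end-to-end pipeline (simulate → average → measure → test → plots +
manifest) is one call:

```r
run_pipeline(run_config(n_subjects = 29, output_dir = "results/run1",
                        seed = 17))
```

or, from a shell, `inst/cli/ctpsharp run-all --config run.yaml --seed 17
--out results/`.

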