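# lesionmap

Voxel-wise lesion mapping for cohorts of binary masks in a shared template
space. The package targets the question that drives meningioma imaging
studies — *where* do lesions sit, and do two clinical phenotypes prefer
different locations? — for any setting where per-patient lesions have been
registered to a common brain template (MNI-like) and segmented to binary
occupancy masks.

## What it computes

Let $M_i(v) \in \{0,1\}$ be patient $i$'s occupancy at voxel $v$.

* **Stereospecific frequency heatmap** — the superposition
  $C(v) = \sum_i M_i(v)$ and its percentage $100\,C(v)/n$, plus the
  demographic/location summary table of the cohort.
* **p-value heatmap** — for a two-group phenotype split (age ≥ 56 vs
  younger, male vs female, WHO grade I vs II+III, GTR vs STR, marker
  positive vs negative, …), each voxel's 2×2 table
  $(a, b, c, d)$ of occupying vs tumor-free patients per group is tested
  with the two-tailed Fisher's exact test,

  $$p_0 = \frac{(a{+}b)!\,(c{+}d)!\,(a{+}c)!\,(b{+}d)!}{a!\,b!\,c!\,d!\,n!},$$

  summing all tables with the observed margins whose point probability
  does not exceed the observed one (log-space enumeration, memoised across
  voxels). Significant voxels are grouped into connected clusters
  (6/18/26-connectivity) and labelled by a deterministic 15-category
  location atlas.
* **Normalized tumor volume** — `voxel_count × voxel_volume` per patient,
  compared across location groups with Kruskal–Wallis and Dunn's post hoc.
* **Laterality** — occupancy-weighted centroid side (left/right/midline
  with a 2 mm buffer) and exact binomial tests of hemispheric balance.
* **Recurrence-free survival** — Kaplan–Meier curves and log-rank tests
  under the usual dichotomisations (age, grade, Ki67, volume, extent of
  resection).
* **Synthetic cohorts** — a seeded generator reproducing the marginal
  structure of a large meningioma series (location weights, grade, sex,
  recurrence rates 2.8/7.9/53.8% for grades I/II/III, lognormal volumes
  with median 22.828 cm³), with optional planted regional enrichment of a
  phenotype for power/recovery studies.

Masks and maps are NIfTI (via RNifti); cohort tables and all outputs are
CSV; an end-to-end pipeline (`run_pipeline()` / `write_report()`, or the
`exec/lesionmap` command line) is fully reproducible from a config and a
seed.

## Worked example

```r
library(lesionmap)

grid  <- make_grid(c(45, 54, 45), c(4, 4, 4))   # MNI-like 4 mm grid
atlas <- build_region_atlas(grid)

# synthetic cohort of 1,000 patients in which high-grade lesions prefer
# the falx with an odds multiplier of 8
eff <- effect_spec("who_grade", c("II", "III"), "falx", 8)
gen <- generate_cohort(
  simulation_config(n_patients = 1000, seed = 42, effect = eff), atlas)

build_frequency_map(gen$masks, n = gen$cohort$n)
#> <frequency_map> n = 1000; max count 250 (25%)

pm <- compute_pvalue_map(gen$cohort, gen$masks, default_splits()$grade)
pm
#> <pvalue_map> split 'grade' (nA = 104, nB = 896); 62202 tested voxels,
#> 2538 below alpha = 0.05; 2020 distinct tables

head(as.data.frame(extract_significant_clusters(pm, atlas)), 3)
#>   cluster_id n_voxels peak_neglog10_p centroid_x centroid_y centroid_z     region
#> 1         11     1641       17.357382   1.404022 -13.473492   49.25046       falx
#> 2          1      454        2.555586 -11.004405  23.744493  -18.56388 background
#> 3         13      148        2.096577 -43.675676   5.216216   45.21622  convexity

rfs <- rfs_comparison(gen$cohort, default_splits()$grade)
round(rfs$test$statistic, 2); signif(rfs$test$p, 3)
#> [1] 26.71
#> [1] 2.36e-07
```

The 104 grade II+III patients were planted to prefer the falx; the largest
significant cluster (1,641 voxels, peak −log₁₀ p ≈ 17) recovers exactly
that region, the smaller clusters are chance structure at the 0.05 display
threshold, and the grade split shows the expected inferior recurrence-free
survival (log-rank p ≈ 2×10⁻⁷, driven by the 53.8% grade III recurrence
rate).

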