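---
title: "Voxel-wise lesion mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise lesion mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lesionmap` analyses cohorts of binary lesion masks that all live on one
template grid (an MNI-like space), the situation that arises after
registering patient MRI to a standard brain and segmenting each lesion as a
region of interest. It was built around meningioma mapping — a tumor whose
clinical behaviour depends heavily on its dural attachment site — but
nothing in the machinery is tumor-specific. This vignette explains the
statistical model, the tunable parameters, what the synthetic cohort
generator does and does not emulate, and the numerical decisions made where
the design was genuinely open.

## The frequency heatmap

Given $n$ patients with binary occupancy masks $M_i$ on a common grid, the
stereospecific frequency map is the voxel-wise superposition
$C(v) = \sum_i M_i(v)$, reported also as a percentage $100\,C(v)/n$. The
denominator is always the full cohort $n$, not the number of patients whose
lesion reaches the voxel's slice: the map answers "what share of all
patients have tumor here". Display clipping (`clip_for_display`, default
cap 5%) only affects export for colour scales; the map itself is never
modified. Percentages in tabular summaries are rounded half away from zero
to one decimal, the convention of printed demographic tables.

## The voxel-wise Fisher test

For a two-level phenotype split (group A of size $n_A$, group B of size
$n_B$), each voxel yields a 2×2 table: $a$ and $b$ are the numbers of
occupying patients per group, $c = n_A - a$ and $d = n_B - b$ the
tumor-free counts. The point probability of a table under fixed margins is
hypergeometric,

$$p_0 = \frac{(a+b)!\,(c+d)!\,(a+c)!\,(b+d)!}{a!\,b!\,c!\,d!\,n!},$$

computed in log space with `lgamma`. The two-tailed p-value follows the
method of small p-values: enumerate every table with the observed margins
and sum the point probabilities not exceeding the observed one. Two
numerical guards matter:

* a relative tolerance of `1e-7` on the comparison absorbs floating-point
  ties between mathematically equal tables;
* when every table in the support qualifies, the p-value is returned as
  exactly 1 rather than a rounding-error sum, so degenerate and perfectly
  balanced voxels are exact.

Tables are canonicalised (smaller group first) before enumeration, which
makes group-swap symmetry bitwise exact instead of merely approximate.
Across a map, distinct $(a, b)$ pairs are computed once and memoised —
voxel tables repeat massively, so a hundred thousand voxel tests collapse
to a few hundred enumerations; the count of distinct tables is logged as
the dominant-cost observable.

A voxel is *tested* when at least `min_count` patients (default 1) occupy
it across both groups. Untested voxels carry $p = 1$, which is the
analytical value of the all-empty table, so the choice only affects which
voxels are reported, not their values. No multiple-comparison correction is
applied by default — the p-value heatmap is an exploratory visualisation in
the lesion-mapping tradition; Benjamini–Hochberg adjustment over tested
voxels is available as an opt-in (`fdr = TRUE`) and reported separately as
a q-map.

Significant clusters are connected components of
$\{\text{tested} \wedge p < \alpha\}$ under 6-, 18- or 26-neighbourhood
connectivity (default 26, the usual choice in cluster reporting), ranked
by voxel count with ties broken by component id, and labelled with the
atlas category at the cluster centroid.

## Volumes, laterality, survival

Normalized lesion volume is exactly `voxel_count × voxel_volume`. The grid
derives its voxel volume from the affine (product of spacings), but an
explicit override is accepted for workflows whose reported single-voxel
volume differs from the stored spacing — reported meningioma pipelines
quote figures such as 0.08 mm³ that match no standard template spacing, so
the override keeps volume arithmetic faithful to such conventions without
distorting the geometry. Group comparisons use Kruskal–Wallis with
tie-corrected mid-ranks; the post hoc is Dunn's test with the pooled
rank-variance standard error and Bonferroni adjustment over all pairs —
Bonferroni because "Dunn's multiple comparison" does not by itself pin a
family-wise scheme, and the conservative choice is reproducible. The 2×2
demographic association (sex by grade group) is Pearson chi-square
*without* continuity correction; on the reference counts this reproduces
the conventional reported value (p ≈ 0.005).

Laterality is assigned from the occupancy-weighted centroid in world
coordinates: RAS+ orientation means negative $x$ is the left hemisphere.
Centroids within `epsilon` (default 2 mm) of the mid-sagittal plane are
midline — the buffer absorbs registration slop and blobs straddling the
falx. Midline lesions are excluded from the exact two-sided binomial test
of left/right balance and reported separately. Centroid assignment was
preferred over majority-voxel because it behaves continuously for lesions
that straddle the midline.

Recurrence-free survival uses the Kaplan–Meier product-limit estimator
(events before censorings at tied times, the standard convention) and the
one-degree-of-freedom log-rank test. Dichotomisations mirror common
practice: age at the cohort median (56 years by default), WHO grade I vs
II+III, Ki67 above 5%, preoperative volume at a configurable cutoff
(22.828 cm³ by default), GTR vs STR. Records missing the stratifying
covariate are excluded from that analysis and counted, never imputed.

## The synthetic cohort generator

The generator exists so the whole pipeline is testable without imaging
data. Its defaults are fixed to the marginal structure of a large
single-center meningioma series: 15 location categories with weights
230/179/126/94/10/86/109/32/84/14/66/21/3/22/31 over 1,107; grade weights
993/101/13; female share 785/1107; per-grade recurrence rates
2.8%/7.9%/53.8%; EOR shares 945 GTR/105 STR/57 missing; age
normal(56, 14) clipped to 13–85 years. Lesion volumes are lognormal with
median 22,828 mm³; the log-scale spread 1.4 was back-solved from the
reported 95% confidence interval of that median (20.64–25.37 cm³ at
n = 1,107) via the asymptotic standard error of a lognormal median.
Marker positivity rates (p53 30%, Ki67>5% 20%, EMA 85%, PR 60%, CD34 40%)
are plausible round figures, not literature estimates; analyses treat them
only as arbitrary binary phenotypes.

Spatially, each patient receives a solid sphere of the drawn volume,
centred at the sampled category's seed coordinate with Gaussian jitter of
one voxel, clipped to the grid; bilateral categories flip a fair coin for
hemisphere. The far upper tail of the volume distribution is truncated at
the grid's physical volume (redraw, then clamp), since a lesion cannot
exceed the space it lives in; configurations whose *median* volume exceeds
the grid fail immediately as infeasible. Every draw comes from a
per-patient stream derived from `(seed, patient index)`, so cohorts are
bit-reproducible and insertion-order independent. An `effect_spec`
multiplies one region's sampling weight by an odds factor for a chosen
phenotype, planting a known spatial association for recovery tests; with
no effect, phenotype and location are independent by construction, which
is the basis of the type-I calibration tests.

What the generator does *not* emulate: MRI intensities, dural-tail or
plaque morphology, multifocal disease, lesion eccentricity (spheres only —
the analyses consume occupancy, not shape), spatial correlation between
covariates and hemispheres, and any real follow-up time distribution
(event times are uniform on the horizon, censoring is administrative at
the horizon, 60 months by default). Passing tests on synthetic cohorts
therefore validate the statistical machinery and its calibration under a
clean null — they do not certify behaviour on real registration artefacts,
segmentation noise, or informative censoring.

The default grid is 45×54×45 at 4 mm, an MNI-like bounding box that keeps
desk-scale runs fast (a 500-patient map computes in well under a second);
the region atlas places its 15 seed spheres at fixed template-like
coordinates, midline categories straddling $x = 0$ and the rest mirrored
across it.

## Problem sizes used by the test suite

The suite verifies the Fisher engine against exhaustive enumeration for
every 2×2 table with $n \le 40$; type-I calibration on 20 null cohorts of
500 patients at the full default grid (rejection fraction of tested voxels
bounded by 0.06 — in practice it sits near 0.01 because Fisher is strongly
conservative at sparse voxels); planted-effect recovery at 1,000 patients
with an odds multiplier of 8 on the falx region (at least 80% of the
region's tested voxels below 0.05, and the region ranked as the largest
cluster); survival power on 3,000 synthetic patients. These sizes are the
package's chosen study conditions for desk-scale validation.

## Known limitations

* One reference table rounds inconsistently in its source (two location
  percentages are one unit in the last printed digit away from any single
  rounding rule); the summary surface uses round-half-away-from-zero
  throughout and documents the two discrepant rows in its tests.
* The voxel-wise tests are marginal: no covariate adjustment, no
  permutation-based cluster inference, no spatial smoothing.
* Laterality of anatomically midline categories is decided purely by the
  centroid-with-buffer rule; there is no anatomical prior.
* Survival machinery is deliberately limited to KM/log-rank; no Cox
  models.
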