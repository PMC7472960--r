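Package: lesionmap
Title: Voxel-Wise Lesion Mapping with Frequency and Fisher Exact Heatmaps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for voxel-wise mapping of binary lesion masks in a shared
    template space: stereospecific lesion-frequency heatmaps, per-voxel
    two-tailed Fisher's exact test p-value heatmaps comparing two phenotype
    groups, significant-cluster extraction, normalized lesion volume
    statistics (Kruskal-Wallis with Dunn's post hoc), hemispheric laterality
    assignment and testing, and recurrence-free survival stratifications
    (Kaplan-Meier with log-rank tests). Includes a synthetic cohort
    generator that emulates the marginal structure of a large single-center
    meningioma series, so the full pipeline is testable without imaging
    data, and an end-to-end pipeline driver with a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    survival,
    igraph,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
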