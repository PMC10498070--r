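Package: amygparc
Title: Tractography-Based Amygdala Parcellation and Amygdala-Prefrontal
    Connectivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end, reproducible pipeline linking stereotyped
    (anxious) behavior in macaques to amygdala-prefrontal functional
    connectivity. Implements streamline tractography over per-voxel fiber
    orientation distributions, connectivity-profile cross-correlation and
    spectral clustering to parcellate a seed structure, silhouette- and
    Dice-based selection of the number of subregions, group maximum
    probability maps, seed-based resting-state functional connectivity with
    Fisher z transformation, voxel-wise two-sample t maps with Monte-Carlo
    cluster-extent correction, exact Mann-Whitney rank-sum statistics, and
    behavior-connectivity correlation. A synthetic-cohort generator with
    planted ground truth (two seed subregions, a group-dependent
    seed-to-frontal coupling deficit, and behavior rates negatively coupled
    to connectivity) exercises the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
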