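# amygparc

Linking anxious (stereotyped) behavior to amygdala–prefrontal functional
connectivity in macaques: a reproducible R implementation of the full
analysis chain used in maternal-deprivation studies — tractography-based
amygdala parcellation, group maximum probability maps, seed-based
resting-state functional connectivity with Monte-Carlo cluster-extent
correction, and behavior–connectivity correlation — exercised end-to-end
on a synthetic cohort with planted ground truth.

## Who this is for

Researchers who analyze connectivity-based parcellations and seed-based
RSFC group contrasts (in primate or clinical imaging) and want the whole
chain — behavior scoring, exact rank-sum statistics, streamline
tractography over fiber-orientation fields, spectral-clustering
parcellation with data-driven cluster-number selection, denoising, group
t-maps with cluster correction, and brain–behavior correlation — as
tested, seedable R functions rather than a mosaic of external tools.

## The model in brief

* **Behavior.** Stereotypy rate = summed episode seconds / recorded
  minutes (s/min, ≤ 60). Group contrast: exact Mann–Whitney rank-sum
  (null counts by the generating-function recursion
  `N(u; n1, n2) = N(u−n2; n1−1, n2) + N(u; n1, n2−1)`,
  `p = min(1, 2·P(U ≤ min(u, n1n2−u)))`) or pooled-variance t
  (`df = n1+n2−2`), chosen by a Shapiro–Wilk screen.
* **Parcellation.** Seed-voxel connectivity profiles (streamline arrival
  counts on a 3 mm grid) → cross-correlation → spectral clustering on
  `W = (r+1)/2` (normalized Laplacian embedding + seeded k-means) →
  cluster number by silhouette + cross-subject Dice → group MPM with a
  neighbor-probability tie-break.
* **RSFC.** Denoise (drop 10 volumes, 3 mm FWHM masked smoothing,
  0.01–0.1 Hz ideal band-pass, band-passed nuisance regression), seed
  FC as Fisher `z = atanh(r)`, voxel-wise pooled-t group map, cluster
  extent calibrated by Monte-Carlo simulation matched to the group design.
* **Brain–behavior.** Pearson/Spearman correlation (p from
  `t = r·sqrt((n−2)/(1−r²))`) between stereotypy rate and mean cluster
  FC, both groups pooled.

See `vignettes/methods.Rmd` for assumptions, parameter defaults and design
decisions.

## Worked example

```r
library(amygparc)

# the printed statistics of the emulated study, recomputed from their
# printed inputs
exact_rank_sum_p(26, 14, 11)   # behavior: MD vs MR
pooled_t_p(3.552, 14, 11)      # cluster-mean FC: MD vs MR
correlation_p(-0.5451, 25)     # behavior vs FC, pooled

# a full synthetic-cohort analysis (25 subjects, 24^3 grid)
spec   <- cohort_spec(rng_seed = 101)
cohort <- simulate_cohort(spec)
report <- analyze_cohort(cohort, run_config(rng_seed = 101,
                                            n_iterations = 500))
report
```

Output:

```
rank-sum (exact): statistic = 26, p (two-tailed) = 0.004194, n = 14 vs 11
pooled t: statistic = 3.552, p (two-tailed) = 0.001698, df = 23, n = 14 vs 11
pearson correlation: statistic = -0.5451, p (two-tailed) = 0.004834, df = 23, n = 25

== amygdala-prefrontal pipeline report ==
behavior: MD vs MR rate comparison p = 3.769e-07 (pooled t)
parcellation: k = 2 (stable: TRUE)
rsfc: 1 significant cluster(s); extent threshold 45 voxels
  primary cluster: subregion 1, 143 voxels, peak t = -11.612
correlation (pooled): r = -0.8694, p = 1.697e-08
```

Reading the numbers: the exact tie-free p for the printed `U = 26` is
0.0042 (the source prints .0039, consistent with tied ranks in the raw
data); the synthetic cohort recovers the planted two-subregion amygdala
(`k = 2`), detects the planted MD<MR coupling deficit as a negative-t
cluster over the frontal target, and reproduces the planted negative
behavior–connectivity relation. A cohort directory can also be written,
analyzed and re-analyzed stage by stage from the shell via
`inst/scripts/amygparc.R` (`simulate | behavior | parcellate | rsfc |
correlate | full`).

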