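---
title: "Methods: tractography-based amygdala parcellation and amygdala-prefrontal connectivity"
author: "amygparc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tractography-based amygdala parcellation and amygdala-prefrontal connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Early adversity — modelled in macaques by maternal deprivation (MD) at
birth, against mother-reared (MR) controls — is associated with anxious,
stereotyped behavior (pacing, swinging, self-directed behaviors) and with
altered coupling between the amygdala and the prefrontal cortex. The
analysis this package implements links the two observations in a single
pipeline:

1. **Behavior.** Stereotyped-behavior episodes are scored from timed video
   recordings; a subject's *stereotypy rate* is the summed episode
   duration (seconds) divided by the recorded time (minutes), an s/min
   rate bounded by 60. Groups are compared with an exact Mann-Whitney
   rank-sum test or a pooled-variance t test, chosen by a Shapiro-Wilk
   normality screen.
2. **Parcellation.** Each voxel of an amygdala seed mask is characterized
   by its whole-brain anatomical connectivity profile from Monte-Carlo
   streamline tractography over per-voxel fiber orientation
   distributions. Profiles are cross-correlated (seed voxel x seed voxel),
   the correlation matrix is clustered spectrally, the number of clusters
   is selected by silhouette plus cross-subject reproducibility (Dice),
   and per-subject parcellations are merged into a group maximum
   probability map (MPM).
3. **Connectivity.** BOLD runs are denoised (volume dropping, 3 mm FWHM
   masked smoothing, 0.01-0.1 Hz band-pass, nuisance regression), each MPM
   subregion's mean time series is correlated with every brain voxel, and
   the Fisher-z maps are compared between groups with voxel-wise pooled t
   tests under Monte-Carlo (AlphaSim-style) cluster-extent correction.
4. **Brain-behavior link.** The per-subject mean Fisher z over the
   surviving cluster is correlated with the stereotypy rate, pooling both
   groups (per-group correlations are secondary outputs; both Pearson and
   Spearman are reported, because published accounts of such analyses name
   either).

Because the raw behavioral and imaging data of the motivating study are
not deposited, the package ships a synthetic-cohort generator with planted
ground truth; every statistical claim the test suite makes is made about
quantities the generator controls.

## Statistical kernel

**Exact rank-sum test.** The null distribution of the Mann-Whitney U
statistic for tie-free samples of sizes $n_1, n_2$ is built by the
generating-function recursion
$N(u; n_1, n_2) = N(u - n_2;\, n_1{-}1, n_2) + N(u;\, n_1, n_2{-}1)$,
and the two-tailed p-value is $\min(1,\, 2 P(U \le \min(u, n_1 n_2 - u)))$.
The implementation is validated against full enumeration of all
$\binom{n_1+n_2}{n_1}$ rank arrangements for every $n_1 + n_2 \le 12$ and
every $u$. With ties the test falls back to the normal approximation with
tie correction and flags the result. Of note: for the printed group
comparison $U = 26$ at $n = 14$ vs $11$ the tie-free exact two-tailed p is
0.0042; the printed value (.0039) is not reproducible under any tie-free
convention and most plausibly reflects tied ranks in the original data —
the same caveat the printed $U = 11$, $p = .5606$ forces for the MR sex
contrast.

**Pooled t, correlations, Fisher z.** The t test uses the pooled-variance
statistic with $df = n_1 + n_2 - 2$ (the printed p-values at
$t = 3.552, df = 23$ and $t = 1.331, df = 12$ are consistent with pooled,
not Welch, degrees of freedom). Correlation p-values use
$t = r\sqrt{(n-2)/(1-r^2)}$ with $df = n - 2$ for both Pearson and
Spearman. Fisher's transform is $z = \operatorname{atanh}(r)$ with $|r|$
clipped at $1 - 10^{-7}$ (seed voxels correlate 1 with themselves) and a
`clipped` flag.

## Streamline tractography

Orientation input is a field of up to two axial distributions per voxel
(mean direction, concentration $\kappa$, volume fraction). A sample is
the mean axis plus isotropic Gaussian perturbation of scale
$1/\sqrt{\kappa}$, renormalized — an axial von Mises-Fisher stand-in. At
each step one sample is drawn from each available distribution, each is
flipped into the hemisphere of the previous direction (directions are
axes), and the sample closest in angle to the previous direction is
taken; the streamline advances a fixed step and terminates on leaving the
brain mask, exceeding the step budget, or turning more than the curvature
limit. The *initial* sample is taken in the hemisphere of the stored mean
axis, which makes a one-ended corridor deterministic: all samples launched
at its near end arrive at its far end. Arrival counting is one increment
per (streamline, voxel) pair — "number of traces arriving", not visits.

Defaults are 5000 samples per seed voxel, 0.5 mm steps, an 80° curvature
limit and 2000 steps; none of these is dictated by the emulated study, so
they are declared, configurable constants. The pipeline and the shipped
analyses run 200 samples and 200 steps per seed voxel: on the phantom
(below) the profile correlation structure is already essentially
noise-free at that depth, and the parcellation results are insensitive to
raising it.

Profiles are stored on a 3 mm target grid by block *summation*
(`downsample_counts`), which conserves total counts exactly; a single
streamline can therefore contribute up to 27 (factor³) to one coarse
cell, so coarse counts may exceed the per-voxel sample count.

## Parcellation

The affinity for spectral clustering is $W = (r + 1)/2$ with a zeroed
diagonal (maps correlation onto $[0,1]$ without free parameters; an
exponential kernel was rejected because it introduces a bandwidth). The
embedding uses the top-k eigenvectors of $D^{-1/2} W D^{-1/2}$,
row-normalized, partitioned by seeded k-means with 50 restarts — fully
deterministic given the seed.

The number of clusters is chosen by computing, for each candidate k, the
mean within-subject silhouette under distance $d = 1 - r$ and the mean
across-subject-pair Dice after label alignment, and maximizing the sum of
the two rank scores (ties resolve to the smaller k). Label alignment
maximizes total per-cluster Dice over all label permutations — exact for
the k ≤ 8 regime this package targets, and equivalent to the Hungarian
assignment. A selection whose mean matched Dice falls below $1/k + 0.25$
(chance for balanced random partitions is about $1/k$) is flagged
unstable.

The MPM assigns each seed voxel the label most subjects gave it; exact
ties go to the label with the higher mean probability over the voxel's
6-connected in-mask neighbors, and any remaining tie to the lowest label
index, so the map is deterministic.

## RSFC and cluster correction

Denoising order is drop → smooth → band-pass → regress. The band-pass is
an ideal FFT-bin filter (hard cutoffs at 0.01 and 0.1 Hz, bin-inclusive).
Nuisance regressors (six motion parameters, white-matter mean, CSF mean,
global mean) are themselves band-passed before the OLS: regressing after
filtering keeps the residuals *exactly* orthogonal to the raw regressors
(their in-band parts by least squares, their out-of-band parts because
the residuals live in the band subspace), which a regress-then-filter
order cannot guarantee, and avoids reintroducing filtered-out nuisance
variance. Masked Gaussian smoothing uses
$\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per axis and renormalizes by the
smoothed mask, so constants inside the mask are preserved.

Cluster-extent correction estimates, by Monte Carlo, the minimal cluster
size whose occurrence under smooth noise is rarer than the cluster-level
alpha. Two null models are available:

* the classic single-field model (smoothed, standardized Gaussian field,
  thresholded two-sided at the voxel p), and
* a group-design-matched model that simulates $n_1 + n_2$ smooth fields
  per iteration and thresholds their pooled-t map at
  $t_{1-p/2}(n_1{+}n_2{-}2)$.

The pipeline uses the group-matched model: at small degrees of freedom a
group t field forms larger suprathreshold clusters than a single Gaussian
field at the matched voxel-level rate (on a 20³ mask at voxel p < .01 the
single-field cutoff is ~40 voxels but the t field needs ~45-50), so the
classic construction inflates the family-wise error rate (~0.09 at
nominal .05 in our calibration, consistent with the cluster-inference
literature), while the matched null controls it (≤ 0.05 empirically).
Clusters are formed two-sided but never mix signs, with 26-connectivity
by default; cluster sizes are reported in voxels and mm³ (voxel count
times voxel volume).

## The synthetic cohort

The generator plants, on a 24³ grid at 1 mm: a two-part seed ("amygdala"
subregions A and B, 27 voxels each), 5³-voxel frontal targets T1
("IFG-like") and T2, white-matter corridors wiring A→T1 and B→T2 only,
a CSF block, and a brain mask. The target gyri are bordered by a 2-voxel
non-brain sulcal rim (sparing the corridors), as at a cortical surface;
without it the 3 mm smoothing blurs gyral signal into a shell of
neighboring brain voxels and detected clusters spread well beyond the
planted target.

Orientation fields put high-concentration ($\kappa = 50$) +x axes on the
corridors (each axis perturbed per subject by 0.1 rad of angular noise)
and low-concentration ($\kappa = 0.5$) random axes elsewhere, so
off-corridor streamlines wander and terminate.

BOLD runs (180 volumes, TR 2 s) are built from band-limited
(0.01-0.1 Hz) unit-variance latent signals: subregion A carries $s_1$,
T1 carries $c\, s_1 + \sqrt{1-c^2}\,\varepsilon$ per voxel, so the
expected seed-T1 correlation is the subject's coupling $c$ attenuated by
the white-noise factor $1/\sqrt{1 + \sigma_w^2}$ ($\sigma_w = 0.3$ by
default). B and T2 are wired identically through an independent latent
with a group-invariant coupling of 0.35, and all other voxels carry
independent band-limited plus white noise. Couplings are 0.2 (MD) versus
0.5 (MR) with 0.05 between-subject SD — calibrated once so that the
planted group difference is detected with comfortably more than 90% power
at n = 14 vs 11, then frozen. Stereotypy rates are linear in the true
coupling (intercept 12 s/min, slope −20, noise SD 2 s/min, floored at 0),
and episode logs are synthesized from log-normal episode durations (mean
≈ 20 s) laid into eight 15-minute sessions so that the emitted episodes
reproduce the target rate exactly. The recorded total defaults to 120
minutes (eight 15-minute videos); it is a config option because published
protocol descriptions sometimes normalize by a different nominal total,
which scales absolute rates but not group contrasts.

What the generator does *not* emulate: hemodynamic response shape,
scanner drift and physiological artifacts, realistic macaque anatomy or
registration error, distance-dependent tractography biases, and
observer noise in behavior scoring. Passing tests therefore demonstrate
that the pipeline recovers planted effects under its own statistical
assumptions, not that those assumptions hold in any given real data set.

## Problem sizes used by the shipped analyses

The test suite runs the full pipeline on twenty 25-subject cohorts (the
first ten also serve the parcellation-recovery checks), uses 500
Monte-Carlo iterations for cluster thresholds, 200 null cohorts for the
family-wise-rate calibration on a 20³ mask, and 200 streamline samples
per seed voxel — sizes chosen so the whole suite completes on a single
CPU in well under half an hour while keeping every Monte-Carlo margin
several standard errors wide.

## Known limitations

* Registration, slice-timing and field-map correction are out of scope;
  all volumes must already share one grid.
* The exact rank-sum null assumes no ties; tied data fall back to the
  tie-corrected normal approximation (flagged in the result).
* The spectral embedding uses a dense eigendecomposition — appropriate
  for seed structures of up to a few thousand voxels, not whole-brain
  parcellations.
* The Monte-Carlo cluster null assumes stationary smoothness equal to the
  applied kernel; estimating smoothness from residuals is not
  implemented.
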