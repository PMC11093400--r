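---
title: "Methods: subject-specific functional localizer analysis with gssfroi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subject-specific functional localizer analysis with gssfroi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gssfroi)
```

## What the package computes

`gssfroi` implements the analysis chain behind precision-fMRI functional
localizer studies of the *L2 after-effect* — the difficulty bilinguals
experience when producing their native language (L1) immediately after using
their second language (L2). The scientific question such studies ask is
whether the neural signature of this effect lives in the language network,
in the domain-general multiple-demand (MD) network, or in task-specific
networks, and the methodological machinery is general: localize functional
networks *per subject*, constrain the subject-specific regions by a
group-level parcellation, and test condition effects with crossed
mixed-effects models at the network level.

The chain is:

1. **First-level GLM** (`fit_glm`): voxelwise ordinary least squares on each
   run, with one double-gamma-HRF-convolved regressor per condition, an
   intercept, a discrete-cosine high-pass basis (100 s cutoff), and optional
   nuisance columns. Contrasts are mapped to z through the t distribution at
   the residual degrees of freedom; runs are combined within subject by
   inverse-variance fixed effects (`fixed_effects_combine`).
2. **GSS parcellation** (`gss_parcellate`): each subject's z-map is
   thresholded at its top 5% most active voxels; the binarized maps are
   summed into an overlap map; voxels active in more than five subjects are
   kept; the resulting proportion map is smoothed with an 8 mm FWHM Gaussian
   and segmented by a watershed into group parcels; parcels whose mean
   per-subject size falls below 10 voxels are excluded; remaining parcels are
   validated per subject by a z > 2 cluster rule.
3. **fROI definition and extraction** (`define_subject_froi`,
   `extract_psc_table`): within each group parcel, each subject's top 10%
   most responsive voxels (by localizer z) form the fROI; percent signal
   change (PSC) of the task conditions is averaged over fROI voxels. For
   analyses where the selection statistic and the estimate would otherwise
   share data, `crossvalidated_psc` defines the fROI on the held-in run(s)
   and estimates on the held-out run.
4. **Inference** (`fit_network_lmm`): per network,
   `psc ~ condition_code + (1 + condition_code | subject) + (1 + condition_code | roi)`
   fitted by REML, with the condition deviation-coded (−0.5/+0.5) so the
   slope is the condition difference and the intercept the grand mean;
   Satterthwaite degrees of freedom; a condition-by-network interaction model
   and per-ROI paired tests with Benjamini–Hochberg correction complete the
   picture.

Because real multi-session fMRI data are not required for validating any of
this logic, the package ships a forward model (`simulate_bold_run`,
`run_study`) that generates multi-subject phantom studies in which every
ground truth — network geometry, subject topography, response amplitudes,
noise — is known, so each stage can be checked against exact oracles and the
whole chain against its planted parameters.

## The forward model and what it does (and does not) emulate

A phantom study consists of ground-truth *networks* (unions of spheres on a
common grid, the stand-in for template-space networks), per-subject
*topographies* (the truth mask jittered by an integer voxel shift and a
dilation/erosion step, emulating cross-subject variability in functional
anatomy, with a configurable minimum overlap of 50% of the truth volume),
and *runs* built from the schedule generators:

* blocked localizer runs with the published block structure (e.g. the
  auditory language localizer: 6 + 6 task blocks of 18 s and four 12 s
  fixation blocks, 264 s per run; the spatial-working-memory MD task: 34 s
  blocks of four 8.5 s trials),
* event-related picture-naming runs: 7 s lead-in, 55 trials of 2 s, jittered
  inter-stimulus intervals on [0.607 s, 10.144 s] with mean 3.091 s, 8 s
  tail — 295 s per block. ISIs are drawn from a truncated exponential and
  affinely rescaled to the target mean; only the published min/max/mean are
  honoured, not the original design-optimization software.

Signal in responsive voxels is
`baseline × (1 + amplitude/100 × X(t))`, where `X` is the HRF-convolved
boxcar normalized by the peak of an isolated event, so `amplitude` *is* the
peak percent signal change — this makes simulate → GLM → PSC the identity in
the noiseless limit, a property the test suite asserts to 10⁻⁶. Noise is
additive AR(1) Gaussian (innovation SD 1% of baseline, φ = 0.3 by default)
plus a linear drift (2 signal units peak-to-peak). TR is 1.4 s and the
number of volumes is `ceiling(duration / TR)`, since per-run volume counts
are not published.

The generator does **not** emulate physiological noise, motion, distortion,
slice timing, spatial noise correlations, or multiband artifacts, and the
phantom geometry is far simpler than cortical topology. Passing tests on
phantoms therefore demonstrate the *correctness of the estimators and of the
pipeline logic* (selection rules, cross-validation structure, calibration of
the statistics), not robustness to every property of real data.

Some printed run totals are not fully decomposable from the published
component timings; where a few seconds were unaccounted for (Stroop: 394 s
vs. 16 × 18 + 5 × 18 + 8 s lead-in) the schedule builder adds a symmetric
tail fixation, and the verbal-fluency inter-block fixations (7–13 s) are
rescaled so the run totals 348 s. Only block- and trial-level timings feed
the analysis; these choices affect nothing downstream.

## Numerical and design choices

**HRF.** Canonical double gamma: gamma peak (delay 6 s, dispersion 1 s)
minus 1/6 × gamma undershoot (delay 16 s, dispersion 1 s), sampled at any
resolution and normalized by the *continuous* peak so a coarse kernel equals
the decimated fine kernel exactly.

**Estimation.** OLS without prewhitening. The default AR(1) coefficient of
the generator is low, and the suite verifies the consequences empirically:
under pure white noise the contrast z is standard normal (false-positive
rate at z > 3.1 below 0.002) and the estimator is unbiased. With strongly
autocorrelated noise OLS variance estimates would be optimistic; this is a
deliberate scope boundary, stated rather than hidden.

**PSC convention.** `100 × beta × peak(isolated-event regressor) /
baseline`, with the voxelwise GLM intercept as the default baseline (the
voxel mean is available by option). The intercept makes the noiseless
round-trip exact because the high-pass basis is zero-mean and the condition
regressors absorb all task signal.

**"8 × 8 × 8 Gaussian kernel".** Implemented as 8 mm FWHM per axis
(configurable): mm-FWHM is the neuroimaging norm and the analysis voxels are
2 mm. Smoothing uses half-sample-symmetric (reflective) boundaries, which
conserves total probability mass to machine precision.

**"More than five participants (~20%)".** For n = 41 the strict count rule
(> 5, i.e. ≥ 6) and the percentage are inconsistent (6/41 ≈ 15%); the count
rule wins and the percentage is treated as commentary. `min_subjects` is
configurable.

**Watershed.** Steepest-ascent basins on the positive support of the
smoothed map: every supra-floor voxel follows its largest strictly-greater
6-neighbour uphill; local maxima that are 26-adjacent (plateaus, twin peaks)
merge into one seed. Basins are 6-connected by construction, labels are
assigned in decreasing seed height with lexicographic tie-breaks, so the
atlas is bit-stable. By default the final parcels are additionally
restricted to the support of the thresholded overlap map
(`restrict_to_overlap`): smoothing then serves only to regularize the basin
topography, and parcels cannot bleed into territory no subject activated —
without this restriction a truncated-Gaussian skirt several voxels wide
would surround every parcel.

**Top-fraction ties.** `threshold_top_fraction` keeps exactly
`round(fraction × |mask|)` voxels, breaking ties at the cut by the fixed
linear-index order — determinism across platforms matters more than any
particular tie convention. fROI selection uses `max(1, floor(0.10 × |parcel|))`:
floor is conservative and the 1-voxel minimum keeps every fROI nonempty
(when a subject's activation misses a parcel entirely, the top-k voxels are
still taken, in keeping with standard subject-specific fROI practice).

**Cluster-wise validation.** Gaussian-random-field cluster correction is not
reimplemented. Parcel validation uses z > 2 plus a minimum 6-connected
cluster extent whose default (5 voxels) was set by a pure-noise Monte Carlo
(`calibrate_cluster_extent`) holding the family-wise error of an independent
standard-normal field on the 24³ demo grid near 5% (estimated 3% at extent
5, 22% at extent 4). The extent should be recalibrated for other grids.

**Mixed models.** The maximal model is fitted first; on non-convergence or a
singular fit the random-effects structure is simplified in a fixed order —
drop the random correlations, then the ROI slope, then the subject slope —
because the by-subject structure is what the within-subject design hinges
on. The trace of attempts is recorded in the fit object. If no mixed model
is estimable (e.g. noiseless degenerate data, or a single-ROI network), the
model falls back to the subject-level paired comparison, which in balanced
data gives the identical fixed effect. Degrees of freedom are Satterthwaite
approximations. The published "effect size" has no stated definition, so the
package computes Cohen's d_z on subject-level condition-difference means and
always labels it as such. Per-ROI tests use BH-FDR within network; tests are
two-sided at α = 0.05.

**Interaction coding.** In `fit_interaction_lmm` the first network is coded
+0.5, so the interaction estimate equals (condition effect in network A) −
(condition effect in network B); a positive value means the effect is
stronger in the first-listed network.

**Seeds.** Every stochastic operation takes an explicit integer seed and
restores the caller's RNG state; sub-seeds are derived deterministically
from the master seed plus stage/subject/run labels, so a whole study is a
pure function of its configuration and one integer.

## The default phantom study

`demo_study_config()` encodes the study conditions used throughout the
validation suite: 12 subjects on a 24³ grid of 2 mm voxels; two disjoint
networks of three radius-4 spheres each; localizer response 1.5% PSC; main
task response 1.0% with a planted condition effect of **0.07% PSC in network
A** (the magnitude of the published MD-network after-effect) and **0 in
network B**; between-subject amplitude SD 0.03; AR(1) noise with innovation
SD 1 (1% of baseline), φ = 0.3, drift 2. Problem sizes for the simulation
studies (12 subjects for recovery, 200 null phantoms for the
cross-validation bias demonstration, 500 simulated tables at 40 subjects ×
20 ROIs for mixed-model calibration) were chosen so each study estimates its
quantity with comfortable Monte-Carlo precision at desk scale.

With these conditions the suite verifies end to end that GSS parcels
recover both truth networks (Dice ≥ 0.6 against truth; in practice ≈ 0.8),
that no parcel spans both networks, that the planted 0.07% effect is
detected in network A while network B stays within two standard errors of
zero, and that the condition-by-network interaction carries the sign of the
plant. The headline statistics of the motivating study (e.g. an MD-network
effect of β = 0.072 with t(40) = 2.679 in 41 subjects' real data) are not
reproducible from synthetic data and are not targets; what the phantom
establishes is that the pipeline detects an effect of that size and
localization when it is present and does not invent one where it is absent.

## Known limitations

* OLS without prewhitening mildly miscalibrates variances under strong
  temporal autocorrelation; keep the AR(1) knob low or interpret z maps
  accordingly.
* The cluster-extent validation default is calibrated for unsmoothed,
  independent-voxel noise on a 24³ grid; spatially smoothed data need a
  larger extent (recalibrate with `calibrate_cluster_extent`).
* Watershed behaviour on exact plateaus is resolved by deterministic
  tie-breaking, not by topographic distance; smoothed overlap maps are
  generically free of plateaus.
* The crossed mixed model assumes exchangeable ROIs within a network;
  strongly heterogeneous networks are better served by the per-ROI models,
  which the package also provides.
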