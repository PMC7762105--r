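---
title: "Methods: voxel-based quantification of PDAC imaging subtypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel-based quantification of PDAC imaging subtypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(qdelta)
```

# The measurement model

Pancreatic-protocol CT acquires three phases: pre-contrast (NC), arterial
(AR, about 40 s after contrast injection) and portovenous (PV, 65–70 s).
`qdelta` assumes the three phases have been deformably registered onto one
voxel grid upstream — registration is a *precondition*, not an operation of
this package — and that three masks are supplied on that grid: the tumor
contour and two roughly 1 cm³ reference regions, one over normal pancreatic
parenchyma (NPP) and one over anterior abdominal fat (AAF).

The enhancement map of a phase is the voxelwise HU difference `phase − NC`.
The normalized enhancement (NE) of the tumor against a reference is the
percentage of tumor voxels whose enhancement strictly exceeds the reference
mean plus one reference SD, computed on the *same* enhancement map for
tumor and reference. Four features result per study (AR/PV × NPP/AAF).
The nAUC ratio summarizes contrast transport as time-weighted enhancement
of tumor over parenchyma, using whole-mask mean HU per phase; the weights
5 and 35 are fixed acquisition-timing constants taken as given, not
re-derived here.

Assumptions worth stating plainly: voxels are exchangeable within masks
(no spatial model), the reference regions are homogeneous tissue, and a
uniform grid makes voxel counting equivalent to volume integration. Ducts,
vessels and stent artifacts are assumed to have been excluded during
contouring, as in clinical practice.

# Parameters that matter

* `n_sd` (`normalized_enhancement()`, default 1, unitless) — how many
  reference SDs above the reference mean a voxel must exceed to count as
  enhancing. 1 is the clinical convention for this statistic; the general
  qEASL family allows other values, so it is exposed.
* `decision_threshold` (`fit_qdelta()`, default 0.5, probability) — the
  "most likely class" rule. The Youden-optimal point is reported alongside
  by `roc_analysis()` for sensitivity/specificity tables.
* `alpha` (`backward_eliminate()`, default 0.05) — retention p-value for
  the elimination loop, matching the convention of two-sided p ≤ 0.05
  significance used throughout.
* `magnitude_mm` (`perturb_contour()`) — the maximum boundary displacement
  of an emulated second rater, in mm. The analysis scripts use 1.5 mm
  (interrater) and 0.75 mm (repeat contouring by the same rater), of the
  order of 1–2 voxels on routine reconstructions.

# What the generators emulate — and what they do not

`simulate_phantom()` builds the *image-domain* path: a parenchyma
background with an anterior fat slab, a spherical tumor whose voxel-wise
enhancement gains are class-conditional Gaussians, and iid Gaussian CT
noise (default 8 HU). Geometry is deliberately simple — NE and nAUC depend
only on the intensity distributions inside the masks, so spheres and boxes
exercise every code path that anatomy would. Defaults: 64³ voxels at 1 mm,
parenchyma 40 HU gaining +60/+50 HU (AR/PV), fat at −100 HU and
non-enhancing, and tumors that are markedly hypo-enhancing for the
conspicuous "high-delta" class (+25/+20 HU) versus near-iso-enhancing for
"low delta" (+55/+46 HU). PDAC is classically hypovascular, so the
conspicuous class is modeled as the *more* hypo-enhancing one; the
class-conditional gains are plain arguments, so the direction is a
configuration choice, not a commitment.

`simulate_cohort()` bypasses image synthesis and draws the four NE features
directly from class-conditional truncated normals on [0, 100] — fast
statistical tests versus full-pipeline tests, with the phantom covering the
latter. The features are drawn independently given the class. Defaults
encode the operating regime the classifier is meant for: prevalence of
high delta 0.43; NPP-referenced features separated by ~2.2 pooled SDs
(univariate AUC ≈ 0.94/0.91) and AAF-referenced ones by ~0.85 SDs
(AUC ≈ 0.73/0.70); exponential overall survival with a high-vs-low hazard
ratio of 2 around a 36-month low-class median; independent exponential
censoring calibrated to a 20% censoring fraction; stroma area larger and
cellularity lower in the low-delta class; and an nAUC coupled
monotonically to NE(AR-NPP) with noise sized for a rank correlation near
0.5. These values were fixed once, from the regime the method targets,
before any acceptance outcome was observed.

What the generators do *not* emulate: real anatomy, partial-volume and
beam-hardening effects, stents, inter-phase motion or registration error,
scanner/protocol drift, correlated (streak) noise, or feature correlation
structure beyond the class labels. Passing tests therefore demonstrate the
*statistical machinery* — not that the classifier would reach the same
operating characteristics on patients. Because the cohort generator draws
the four features independently given class, backward elimination on the
synthetic cohort may legitimately retain an AAF feature; on patient data
the AAF features carry largely redundant information and drop out.

# Numerical choices

* **Strict threshold.** "One SD over the mean" is implemented as a strict
  `>`: a tumor identical to its reference scores NE = 0 rather than
  depending on tie conventions.
* **Sample SD** (denominator n − 1) for the reference SD, with a two-voxel
  minimum; a zero reference SD (possible only on noiseless synthetic data)
  degrades the threshold to the mean and warns, since real CT never has
  σ = 0.
* **Colormap binning:** 8 equal-width bins over the tumor's own [min, max]
  enhancement; the top edge closes the last bin; constant tumors map to
  bin 1.
* **Separation handling.** Logistic fits detect (quasi-)complete
  separation via glm convergence diagnostics and refit with a weak ridge
  penalty (10⁻⁶ on slopes, intercept unpenalized) under damped Newton
  iterations, flagging the result — a silent infinite coefficient would be
  unacceptable in a clinical-adjacent tool.
* **Elimination tests.** Wald p-values drive removal (the default of the
  common commercial implementations); a likelihood-ratio variant is
  provided. Ties in p-values are broken by column order; with untied
  p-values the outcome is order-invariant.
* **ROC.** Midrank (Mann–Whitney) AUC; DeLong variance for the CI and for
  the test against 0.5; Youden threshold ties resolved toward the lowest
  threshold; "positive" means score ≥ threshold.
* **ICC.** Single-measure absolute agreement, ICC(A,1): the repeat
  measurements being compared are individual NE values, not rater
  averages. The McGraw–Wong F bounds give the CI; the point estimate is
  identical under the random (interrater) and mixed (intrarater) two-way
  models.
* **Survival.** Efron tie handling in Cox fits (month-scale times tie
  often); KM medians are the earliest time with S(t) ≤ 0.5 and are
  reported as "not reached" rather than interpolated. One-year
  dichotomization counts an event before 12.0 months as failure, reaching
  12 months as success, and *excludes* patients censored before 12 months.
* **Fisher exact p** sums hypergeometric probabilities no larger than the
  observed table's (the standard two-sided convention). **Spearman** uses
  the exact permutation distribution (full enumeration) for n ≤ 9 without
  ties, the t approximation otherwise. The **t-test** is Welch's, since
  class variances need not be equal.
* **Contour perturbation.** The signed Euclidean distance to the mask
  interface (offset half a voxel from the last foreground center) is
  compared against a smooth Gaussian random field, normalized by its
  interior SD to a typical amplitude of half the requested magnitude and
  hard-clipped at the magnitude — so boundary displacement never exceeds
  `magnitude_mm`, the symmetric difference grows monotonically with the
  magnitude for a fixed seed, and magnitude 0 is the exact identity. The
  distance transform is the exact separable parabolic-envelope algorithm,
  implemented in-package because no installed dependency offers a 3D EDT.
* **Determinism.** Every stochastic operation takes a seed and runs under
  a saved-and-restored RNG state; the demo writes uncompressed `.nii`
  volumes so that re-runs are byte-identical (gzip embeds timestamps).

# Problem sizes

The test-suite and acceptance-script sizes are chosen to estimate each
property stably: 8³ grids for exhaustive voxel-count oracles (100 seeds);
n = 2000 with 100 replicates for coefficient recovery; n = 500 with 100
(elimination) or 200 (Cox, 20% censoring) replicates; 24³ phantoms for the
30-case agreement study; and a 101/90 train/holdout cohort for the
end-to-end run, mirroring the training/internal-validation sizes the
method is designed around.

# Known limitations

NE treats voxels as exchangeable, so it cannot distinguish spatial
enhancement patterns with equal histograms; the nAUC sampling here uses
whole-mask means rather than a particular manual sampling scheme; the
ridge fallback biases coefficients toward zero under separation (by
design, flagged); the agreement study perturbs contours synthetically and
so measures the pipeline's sensitivity to contour variation, not human
rater behavior; and all cohort-level operating characteristics quoted
anywhere in this package are properties of the synthetic generator, not
estimates for any patient population.
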