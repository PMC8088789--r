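---
title: "Methods: tract-specific lesion interaction measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tract-specific lesion interaction measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionometry)
```

This vignette is the package's own account of its methods: the
quantities it computes, the assumptions and conventions behind them,
the parameters a user might want to change, and the limitations of the
synthetic data used to validate the chain.

## The measurement model

The package treats a white-matter bundle as a set of streamlines
(polylines in world millimetres) and a lesion mask as a binary labelling
of a voxel grid. Every lesion-interaction quantity reduces to set
arithmetic on that grid:

* a bundle's **voxel set** `V(B)` is the set of voxels containing at
  least one streamline point;
* **bundle load** is `|V(B) ∩ L| / |V(B)|` for lesion voxel set `L`;
* **tractogram load** applies the same ratio to the union of all
  bundles' voxel sets;
* **lesion load** is `|L| / |H|` against the brain mask `H`;
* **Tractometry** is the point-weighted mean of a scalar map over all
  streamline points of a bundle;
* **lesionometry** is that mean restricted to the streamlines that
  intersect lesions.

### Voxelization dialect

Streamlines are first resampled to a step of half the smallest voxel
dimension, then each point is assigned to the voxel whose centre is
nearest (0-based indices, half-open bounds `[i − 0.5, i + 0.5)` in
continuous voxel coordinates). This is a *dialect choice*: point
membership after dense resampling rather than exact ray–voxel
marching. It is common tractometry practice, trivially oracle-checkable
by exhaustive enumeration, and the half-voxel step guarantees a
streamline cannot skip a voxel it passes through. The test suite
verifies that refining the step only ever adds voxels and that results
are stable from half-voxel steps downward. Exact marching could be added
later without changing any interface.

Lesion "intersection" is likewise defined on the voxel lattice of the
lesion mask — lesions arrive as voxel masks, so a continuous-geometry
definition would manufacture precision the input does not have.

### Missing lesionometry

A subject whose bundle has no lesioned streamlines has *no* lesionometry
value; the package records `NA`, never 0 (0 would be a valid FA). The
missing value propagates through hemisphere averaging, factor
construction (complete-case PCA; such subjects get `NA` scores) and the
statistics stage (per-analysis complete cases, with n reported). If too
few subjects have lesioned streamlines in a bundle to support a PCA at
all, that bundle's lesionometry factor is missing for everyone.

### Two lesionometry sampling modes

Two defensible readings of "sampling the streamlines that intersect
lesions" exist: average only the points lying inside lesion voxels
(`"portion"`), or average along the entire length of the intersecting
streamlines (`"full"`). Both are implemented and both means are always
written to the measure table; the pipeline's per-bundle lesionometry
*factor* uses `"full"` by default (configurable). The package makes no
claim about which mode is "correct" — portion mode isolates the lesioned
tissue itself, full mode captures the whole fibre population passing
through lesions, and they answer different questions.

### Hemisphere averaging and head-size normalization

Bilateral bundles are reduced to single measures as `(L + R) / 2`;
commissural bundles pass through. The lesion-load denominator is the
brain-mask voxel volume by default, with an externally supplied
intracranial volume as an option (`icv`), since "head size" is
operationalized differently across labs.

## Microstructure maps

* **Tensor fit**: log-linear least squares followed by reweighting
  passes with weights equal to the squared predicted signal, on the
  lower shell (b = 1200 s/mm² by default) plus b = 0 volumes. Two
  reweighting passes and a convergence tolerance of 1e−10 on the
  coefficients are the defaults; the literature names the estimator but
  rarely the iteration count, and on noiseless phantoms one pass already
  reproduces the log-linear solution exactly. Non-positive signals are
  clamped to a tiny positive value and *flagged in a QC mask* rather
  than silently fitted. FA/MD/RD come from closed-form symmetric 3×3
  eigenvalues (non-increasing order; negative eigenvalues flagged).
* **Spherical harmonics**: real, even-order, orthonormal basis
  (descoteaux07-style ordering), fitted by least squares on the high
  shell. The basis convention string is carried on every coefficient
  map because RISH values are only comparable within one convention.
  RISHℓ = Σₘ c²_{ℓm} is rotation-invariant; the tests verify invariance
  to random rotations of the gradient frame to 1e−6 relative.
* **AFD** is the spherical integral of the fODF, `c00 · √(4π)`. With
  spherical deconvolution out of scope, fODF coefficients are consumed
  from files or generated by the phantom; whether an upstream CSD tool
  uses a different normalization constant must be checked by the user.
* **NuFO** counts fODF peaks on a 642-vertex icosphere: local maxima at
  or above 0.1 of the global maximum (relative threshold), merged within
  25°, antipodes counted once. Both defaults are exposed; the field has
  no canonical values, and these follow common peak-extraction practice.

## Statistics stage

* **Per-bundle factors**: PCA on the correlation matrix of the seven
  z-scored metric means. Components with eigenvalue > 1 are retained;
  loadings below |0.3| are masked *for reporting only* (scores always
  use full loadings); only component 1 provides scores, with a warning
  if a second eigenvalue exceeds 1. The factor's sign is oriented so
  RISH0 loads positively, making higher scores mean healthier tissue.
  KMO ≥ 0.7 and Bartlett p < 0.0005 are checked and their violation is a
  recorded warning, not an error. No rotation is applied.
* **Bayesian Pearson screening**: the Bayes factor integrates the exact
  sampling density of r (Hotelling's form, Gauss hypergeometric by
  series) against a stretched-beta prior on ρ, width κ = 1 (uniform on
  (−1, 1)), and is reported null-over-alternative: BF < 1 favours an
  association and BF < 0.2 (at least moderate evidence) admits a
  measure to modelling. Bayes factors are prior-dependent; different
  software's defaults agree only up to prior sensitivity, roughly a
  factor of 1.5, which is the tolerance the tests use against reference
  values. The prior width is configurable. Screening is the only
  multiplicity control, and the report says so.
* **ANCOVA**: Type-III-style F tests by full-versus-reduced model
  comparison (equivalent to the conventional unbalanced-design
  treatment for models without interactions), partial
  η² = SS_effect / (SS_effect + SS_error), a separate slope-homogeneity
  model for the group × focal-measure interaction, Levene's test
  (centre = mean) and a covariate collinearity check (warn at
  |r| ≥ 0.8).
* **Group tests** report both pooled and Welch t; the headline statistic
  follows Levene's test at 0.05 (Welch under heteroscedasticity).
  Cohen's d uses the pooled sd; Hedges g applies
  `d · (1 − 3/(4N − 9))`.
* **Power**: the t-test sample size inverts the noncentral-t power
  function (ncp `d·√(n/2)`, df `2n − 2`); the correlation sample size
  inverts the exact power of the r test (critical value from the null
  t-transform, power by integrating the exact r density), with the
  Fisher-z approximation reported alongside. Both routines are verified
  by 10⁵-replicate Monte-Carlo simulation in the acceptance tests and
  are inverse-consistent (power(n) ≥ target, power(n − 1) < target).

## The phantom: what it emulates and what it does not

The generator produces, deterministically from a spec and seed: tube
bundles (a resampled centerline copied per streamline with a
perpendicular Gaussian offset, sd = `dispersion`, clipped to the tube
radius), ellipsoidal lesions rasterized by voxel-centre membership,
scalar maps with multiplicative lesion effects (MD/RD raised, FA, AFD,
NuFO, RISH0, RISH2 lowered) plus relative Gaussian noise, single-tensor
DWI (axial 1.7e−3, radial 3e−4 mm²/s along the local tangent, isotropic
7e−4 elsewhere; Rician noise as the magnitude of a complex Gaussian,
with a Gaussian option for analytic checks), and cohort tables whose
cognitive score is a linear function of one named tract measure plus IQ
and education covariates and Gaussian noise.

Defaults encode the study conditions the package targets: 2000
streamlines per bundle, 2 mm isotropic voxels, a 14 + 30 + 60 volume
gradient scheme at b = 0/1200/2400 s/mm², a 24/16 two-group cohort,
and a twelve-bundle inventory (genu, isthmus, and left/right
striato-prefrontal, striato-parietal, SLF I–III). Tissue baselines
(FA 0.5, MD 8e−4, RD 6e−4 mm²/s, AFD 0.6) are field-typical healthy
white-matter values chosen once. Ellipsoidal lesion geometry is a
computational stand-in, not a claim about lesion morphology.

What passing tests on these phantoms shows: the measure definitions,
their set arithmetic, the fitting round trips and the statistical
machinery are correct, and planted measure–score couplings are
recovered at realistic sample sizes. What they do not show: behaviour
under crossing-fibre anatomy, registration error, distortion,
segmentation noise, or realistic lesion shapes — none of which the
phantom models. One RNG stream per subject, derived from
(master seed, subject index), keeps cohorts reproducible under
out-of-order or parallel generation; separate generators draw from
offset seed spaces so a shared master seed never correlates, say,
measures with covariates.

## Numerical choices

* Degenerate inputs: empty lesion lists are valid (all-zero mask);
  empty bundles and all-NaN sampling are errors; an all-zero tensor has
  FA defined as 0; |r| = 1 saturates the Bayes factor (the density
  spike is clamped at |r| = 0.995); duplicate metric columns make the
  correlation matrix singular and KMO/Bartlett report as undefined
  while the PCA proceeds on the rank-deficient matrix.
* Ties and orientation: eigenvalues are reported non-increasing;
  factor sign is fixed by the RISH0 loading (or the first metric when
  RISH0 is absent); streamline tangents are sign-aligned before
  averaging into the DWI phantom's direction field.
* Geometry: streamline files are interpreted in world mm (TCK
  convention); TRK's voxel-mm corner-origin coordinates are converted
  on read through the header affine; any grid mismatch between paired
  volumes is a hard error — the package never resamples silently.
* Problem sizes in the test suite are deliberately compact: phantoms of
  14–24³ voxels with 25–200 streamlines per bundle for oracle
  comparisons (exhaustive enumeration scales poorly and adds nothing at
  larger sizes), n = 200 subjects for factor recovery, 100 simulated
  cohorts at n = 40 for the screening controls, and 10⁵ Monte-Carlo
  replicates for the power checks. The measure definitions are
  scale-free, so these sizes exercise every code path the full-size
  conditions would.

## Known limitations

* Voxelized loads depend on the voxel grid; comparing loads across
  resolutions requires resampling masks first (the package refuses to
  do this implicitly).
* The Bayes factor's exact numeric value depends on the prior; only its
  orientation, monotonicity and order of magnitude are
  software-independent.
* Lesionometry in portion mode can rest on few points for small lesions
  and is correspondingly noisy; the per-streamline flags are retained so
  users can inspect the sampling support.
* The PCA factor assumes one dominant component; when a second
  eigenvalue exceeds 1 the package warns and still uses component 1,
  mirroring the single-factor reporting convention of the tractometry
  literature rather than attempting rotation.
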