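---
title: "Metabolic networks in dementia with Lewy bodies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic networks in dementia with Lewy bodies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical models implemented in `dlbnet`,
the parameterisation of the synthetic cohort generator, and the rationale
for the numerical choices. It is a methods reference; the README shows a
worked analysis.

## 1. Data model

A *cohort* is a tibble with one row per subject: metadata columns
(`subject_id`, `group`, and optionally `age`, `sex`, `site`, `mmse`,
`dat_z_left`, `dat_z_right` or putaminal DaT ratios) followed by 77
regional FDG-PET SUVr columns named after the atlas regions. The
parcellation is the grey-matter subset of the Hammers maximum-probability
atlas (83 structures minus corpus callosum and the five ventricular/CSF
labels), shipped as a plain CSV with region labels, composite assignments
(frontal, parietal, occipital, temporal, insula, limbic, basal ganglia,
cerebellum) and representative volumes used as weights.

Regional values are analysed after **global-mean scaling**: each subject's
profile is divided by its volume-weighted whole-brain mean, so every
subject satisfies `sum(w_r * suvr_r) = 1` exactly and only *relative*
metabolism enters any analysis. Voxel-level inputs are supported through
`read_image_volume()` (NIfTI via `RNifti`), `gaussian_smooth()` (separable
3-D convolution, `sigma = fwhm / (2 * sqrt(2 * log(2)))`, reflect padding)
and `extract_voi_means()` (per-label means over an integer label map).

## 2. DaT stratification

Putaminal DaT-SPECT specific binding ratios are converted per hemisphere
to z-scores against a healthy-control normative sample, averaged across
hemispheres, and thresholded: subjects with mean putaminal z &le; &minus;2
are labelled dopamine deficient (`DLB_DATPOS`), the remainder
`DLB_DATNEG`. The boundary is *closed* (z = &minus;2 is deficient), so the
two strata partition the z axis without a gap. DLB subjects without DaT
data cannot be stratified and are excluded with a warning rather than
silently retained.

## 3. Regional metabolism

Per region, group differences are tested by ANCOVA: `value ~ group +
age_centred + sex_indicator`, fitted by ordinary least squares. Pairwise
group contrasts are linear functions of the coefficient vector with
standard errors from the model covariance matrix and two-sided t tests on
the residual degrees of freedom; this equals the adjusted-mean contrasts of
`emmeans`, which the test suite uses as an independent oracle rather than
as the implementation. Multiplicity is handled by Bonferroni over 77
regions &times; contrasts. Effect sizes are Cohen's d with the pooled
standard deviation. The similarity of two effect-size topographies (e.g.
DLB with vs without dopamine deficit, each vs controls) is summarised by
an OLS regression across the 77 regional d values (slope, R&sup2;,
parametric p). Single-subject abnormality maps flag regions beyond
`cut` (default 2) control SDs, again with a closed threshold.

## 4. Metabolic connectivity

For each group, the *inter-region correlation* (ICC) matrix is the
77&times;77 Pearson correlation of regional values across the group's
subjects, Fisher-transformed (`z = atanh(r)`) after clipping |r| at
1&nbsp;&minus;&nbsp;1e&minus;7 to keep z finite when two regions are
collinear in small samples. Connectivity *differences* are elementwise
deltas of z matrices. Whether two delta matrices share topography is
tested by regressing one on the other over the 2,926 upper-triangle pairs;
because pairs sharing a region are dependent, the parametric p-value is
anticonservative, so a **region permutation** null is provided: region
labels of one matrix are permuted jointly over rows and columns `n_perm`
times and the permutation p is `(1 + #exceedances) / (1 + n_perm)`. The
test suite verifies that this permutation p is approximately uniform under
independence while the parametric p is not.

## 5. Pattern model (SSM/PCA)

Training data (controls plus dopamine-deficient DLB) are log-transformed
and **double centred** (row means, then column means, removed), so every
subject and region has mean zero and residual covariance drives the
decomposition. Components are eigenvectors of the region-by-region
correlation matrix of the centred data; components with eigenvalue &gt; 1
(Kaiser criterion, guard band 1e&minus;8) are retained, scaled to
loadings, and rotated by Kaiser-normalised Varimax. Factor scores use the
regression method, `W = R^+ L`, where `R^+` is the Moore–Penrose
pseudoinverse — double centering makes `R` exactly singular (the centred
columns sum to zero), so `solve(R)` would fail; the pseudoinverse restricts
the inversion to the non-null subspace. Training scores are standardised
to mean 0, SD 1 per component.

**Weighting factors.** Disease status (control = 0, patient = 1) is
regressed on the standardised factor scores with centred age and a sex
indicator as adjusters. The per-component coefficients &beta; weight the
factor scores into a single raw expression score. The regression intercept
and covariate coefficients are stored but, by default, excluded from the
summed score: within one PCA run the intercept is a constant that cancels
in z-scoring, while *across* leave-one-in re-runs including it would shift
every control's raw score towards zero and make the coefficient of
variation (SD/|mean|) explode for scores near zero — the stability
diagnostic would then measure proximity to an arbitrary offset instead of
run-to-run reproducibility.

**Leave-one-in scoring.** To score a new subject prospectively, the
subject is appended to the training set and the entire extraction
(log/double-centre/PCA/Varimax) is re-run. Each reference component is
re-identified in the new run greedily by maximal absolute Pearson
correlation of loading vectors, with sign alignment; matches below 0.5
raise a warning. The subject's matched factor scores are combined with the
*reference* &beta; weights and z-scored against the control scores of the
same run. Leading components match almost perfectly across runs; trailing
near-degenerate noise components rotate freely, which is why scoring is
approximate by design and why a stability analysis is reported: the CoV of
each control's raw score across all leave-one-in runs, summarised as the
mean over controls.

**ROC.** AUC is computed as the Mann–Whitney probability via mid-ranks
(ties count one half), with an operating-point curve swept over thresholds
with the rule "positive if score &ge; threshold". The test suite checks it
against exhaustive pair counting.

## 6. Synthetic cohort generator

The generator exists so that every claim of the pipeline can be tested by
*parameter recovery* on data whose truth is known.

- Per group `g`, log-SUVr profiles are multivariate normal with mean
  `base_log_mean + delta_g * pattern` and covariance built from a base
  covariance (within-composite correlation 0.45, between 0.15, SD 0.06 on
  the log scale).
- `pattern` is a mean-zero 77-vector with the DLB topography: occipital
  (strongest), parietal and frontal decreases; basal ganglia, limbic,
  cerebellar and insular increases; a sensorimotor (pre/postcentral)
  sparing override; posterior cingulate set to 0 so that, relative to its
  hypometabolic parieto-occipital surroundings, it appears preserved — a
  cingulate-island-like configuration. The magnitude (0.05 in log units
  against noise SD 0.06) gives univariate effects around d &asymp; 0.8 at
  `delta = 1`.
- Default expression multipliers: controls 0, dopamine-deficient DLB 1,
  dopamine-intact DLB 0.6, AD 1 (with an AD-specific temporoparietal
  pattern), PD 0.7 and MSA 1 (each with their own disease patterns), so
  disease controls are *not* trivially separable by global severity.
- DLB groups additionally receive correlation boosts within basal ganglia,
  limbic and frontal blocks and between basal ganglia and limbic regions,
  plus occipital decoupling — the planted connectivity alteration. After
  boosting, the matrix is clipped at |r| &le; 0.99, repaired to positive
  definiteness by eigenvalue flooring, and rescaled.
- Putaminal DaT z-scores are drawn per group (e.g. dopamine-deficient DLB
  at mean &minus;3.7, SD 0.9; dopamine-intact at &minus;1.1, SD 0.7), so
  stratifying the generated data reproduces the intended strata with
  realistic misclassification at the boundary.
- Determinism: each group draws from its own sub-seed
  (`seed %% 2e7 * 100 + group_index`), so enlarging one group never
  changes another group's subjects, and all sub-seeds stay below 2^31.

**Realism and limits.** The generator is a one-factor-per-disease
log-normal model with block covariance. It reproduces the *relationships*
the pipeline is sensitive to (topography, shared covariance alterations,
severity ordering, DaT distributions, site labels without site effects)
but not scanner physics, partial-volume effects, age-dependent atrophy or
heavy-tailed regional noise. Eigen-spectra of real FDG-PET data decay
faster than this generator's beyond the leading components, so the Kaiser
criterion retains more components here (typically 15–20) than on real data
(&asymp; 12); the leading pattern components, which carry the &beta;
weight, behave comparably.

## 7. Numerical choices

- **Pseudoinverse, not `solve`.** See section 5; `MASS::ginv` with the
  default tolerance.
- **Closed thresholds.** Stratification (&le; &minus;2) and abnormality
  (&ge; cut) boundaries are closed so that boundary cases are classified
  deterministically and documented.
- **Clipping before `atanh`.** |r| is clipped at 1 &minus; 1e&minus;7,
  bounding |z| at &asymp; 8.4; a message reports when clipping occurred.
- **Exact symmetry.** Correlation matrices are mirrored from the upper
  triangle after computation so `identical(m, t(m))` holds bitwise.
- **Permutation p-values** use the add-one estimator
  `(1 + #exceed) / (1 + n_perm)`, never exactly zero.
- **Seeds.** Every stochastic step takes an explicit seed derived from the
  master seed; repeated runs of the same configuration are bitwise
  reproducible, verified by the pipeline tests.
- **Serialization.** Matrices are written as TSV with 17 significant
  digits (`%.17g` round-trips doubles exactly); models and reports as JSON
  with unlimited digits.

## 8. Design rationale

The package separates *primitives* (scaling, d, ICC, Fisher z, double
centering, Varimax via `stats::varimax`, OLS via `stats::lm`) from *study
logic* (stratification rules, leave-one-in protocol, similarity
regressions, the pipeline). Standard numerics are delegated to base R and
established packages; everything specific to the metabolic-network
methodology is implemented here and tested against independent oracles
(explicit-loop correlation, normal-equation OLS, a pairwise-sweep Varimax
maximiser, exhaustive-pair AUC) so that no claim rests on a single code
path. The pipeline writes every intermediate table as plain text plus a
manifest (package version, seed, configuration hash) so a run can be
audited and reproduced from its output directory alone.
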