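---
title: "Methods: multiparametric MRI response assessment in glioblastoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiparametric MRI response assessment in glioblastoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliopred)
```

## The clinical problem and the model

A new contrast-enhancing lesion after chemoradiation for glioblastoma can
be viable tumor (true progression, TP) or treatment effect that resolves
on its own (pseudoprogression, PsP). `gliopred` scores each lesion with a
logistic model over three multiparametric MRI features of the
contrast-enhancing region:

$$PP = \frac{1}{1 + \exp\left(-(\beta_0 + \beta_1\,FA + \beta_2\,CL +
\beta_3\,rCBV_{max})\right)}$$

with default coefficients $\beta_0 = -16.17$, $\beta_1 = 194.01$,
$\beta_2 = -285.65$, $\beta_3 = 1.21$, trained previously on a surgical
glioblastoma cohort. FA is the lesion median fractional anisotropy, CL
the median Westin linear-anisotropy coefficient, and rCBV_max the
90th-percentile relative cerebral blood volume. A lesion is called TP
when $PP \ge 0.5$ and PsP otherwise; the boundary is TP by definition of
the rule. The original training study also reported an operating cutoff
of 0.55 (sensitivity 76%, specificity 95%, AUC 0.905); `gliopred` stores
that value as inert metadata on the model object and always classifies at
the 50% rule, because that is how the model is applied prospectively.
Those training-cohort performance figures are metadata too: the package
does not refit the model (the training data are not available) and does
not reproduce its ROC analysis.

The signs are clinically interpretable: higher FA (denser, more organized
cellular tissue) and higher rCBV (angiogenesis) push toward TP, higher CL
pushes toward PsP. The published equation is typeset ambiguously; the
standard logistic reading above is used because it reproduces all six
published case classifications exactly, which we treat as the deciding
evidence.

Two display conventions are worth noting. Reported PP percentages are
rounded to the nearest integer percent, except values below 1% which get
one decimal; whether the source rounded down or to nearest is not
recoverable, and the package asserts classifications and bounds, never
exact printed percentages — with coefficients of magnitude ~200, the
two-decimal rounding of the published feature values moves PP by far more
than a percent. One published case prints PP as 70% in its table and 90%
in a figure caption; recomputation from the printed features gives 79%.
The package does not arbitrate; only the TP call, which all three values
share, is asserted.

## Reference standards

When re-resection tissue is available, the histopathological rule is
applied: more than 25% malignant features is TP, less than 25% is PsP.
Exactly 25% is defined by neither clause, so `label_from_histology()`
returns `"indeterminate"` and leaves the call to the analyst rather than
inventing a boundary convention.

Without tissue, modified RANO criteria decide: tumor burden is the sum of
products of perpendicular diameters (SPD) on post-contrast T1, and a
change only counts once it has persisted at least 4 weeks beyond the
lesion's initial presentation. `classify_modified_rano()` labels a
timeline TP when SPD at the latest confirmation scan (≥ 4 weeks out) has
grown ≥ 25% over the presentation scan — the standard progression
threshold, configurable, since the persistence rule is explicit in the
criteria but the percentage is not restated there — and PsP when the
confirmed course is stable or shrinking. Stability below the progression
threshold is folded into PsP rather than given a fourth label, matching
how imaging-only calls were adjudicated in the motivating case series;
with no scan at least 4 weeks out the result is `"indeterminate"`.
`concordance()` then compares model calls against either reference and
reports overall and per-class agreement.

## Diffusion tensor stage

Tensors are fit per voxel from $S_i = S_0\exp(-b_i\,g_i^T D g_i)$ by
ordinary log-linear least squares over the 7 parameters
($\ln S_0$ and the 6 tensor elements). With 30 well-spread directions at
b = 1000 s/mm² the design is well-conditioned and the unweighted fit is an
appropriate default; signal-squared weighted least squares is available
(`weighted = TRUE`) for lower-SNR protocols. Voxels with any non-positive
signal are invalidated individually; negative eigenvalues are clamped to
zero and flagged rather than discarding the voxel. Eigenvalues are stored
sorted descending; eigenvectors are not exposed (no tractography).

Scalar maps follow the sum-normalized Westin convention:
$MD = \bar\lambda$, $FA = \sqrt{3/2}\,\sqrt{\sum(\lambda_i -
\bar\lambda)^2}/\sqrt{\sum\lambda_i^2}$,
$CL = (\lambda_1-\lambda_2)/\sum\lambda$,
$CP = 2(\lambda_2-\lambda_3)/\sum\lambda$,
$CS = 3\lambda_3/\sum\lambda$. This convention is chosen over the
$\lambda_1$-normalized variant because it gives the algebraic identity
CL + CP + CS = 1 (tested on 10^5 random eigenvalue triples) and produces
the small CL magnitudes (0.03–0.14) seen alongside comparable FA in the
motivating data; the variant remains a documented alternative since the
published maps cite but do not state their formula. Zero tensors take
FA = CL = CP = 0, CS = 1 by convention and are flagged. Inputs are assumed
already corrected for motion and eddy currents upstream; no registration
is estimated anywhere in the package.

## DSC perfusion stage

Signal is converted to relaxation-rate change by
$\Delta R_2^*(t) = -\ln(S(t)/S_0)/TE$ with $S_0$ the baseline mean.
Bolus arrival is detected on the mask-mean curve: the first frame
exceeding baseline mean + k·SD (default k = 3), floored at 5% of the
curve's dynamic range and required to persist for two consecutive frames.
The floor and persistence matter in practice: a short provisional
baseline underestimates the SD of a mean over thousands of voxels, and an
unfloored k·SD rule triggers on pre-bolus fluctuations. The definitive
baseline is every frame before arrival minus one guard frame; fewer than
5 baseline frames degrades the estimate and warns.

The first-pass response is characterized by the gamma-variate
$c(t) = K(t-t_0)^\alpha e^{-(t-t_0)/\beta}$, fit by a grid over $t_0$
with log-linearized initialization and bounded Levenberg–Marquardt
refinement. On noiseless samples all four parameters are recovered to
1e-6 relative. Under realistic noise the amplitude $K$ is *not*
identifiable — it trades off exponentially with $\alpha$ through the
$(t-t_0)^\alpha$ scale — so downstream code and tests rely only on the
identifiable functionals: the fitted curve, its peak time
$t_0 + \alpha\beta$, and its integral
$K\beta^{\alpha+1}\Gamma(\alpha+1)$.

Leakage is corrected with the two-parameter linear model standard in DSC
processing: each voxel curve is regressed on the mean non-enhancing-brain
curve and its running integral,
$\Delta R_2^*(t) \approx K_1\bar c(t) - K_2\int_0^t\bar c$, and the
corrected curve adds $K_2\int\bar c$ back. On leak-free curves the fitted
$K_2$ is below 1e-6 and the correction is the identity. CBV is the
trapezoidal integral of the corrected curve over the first-pass window
(arrival to end of series); integrating the fitted gamma-variate instead
is available (`integration = "gamma"`) since either reading of "numeric
integration of the curve" is defensible. Negative integrals clamp to zero
with a flag. rCBV divides by the mean CBV over a user-supplied
contralateral normal-white-matter mask — never a silently mirrored one —
making the reference-region mean exactly 1.

## Lesion stage

Maps are resliced onto the post-contrast T1 grid by trilinear
interpolation through the composed NIfTI affines (0-based voxel indices;
out-of-field voxels are filled and masked). The enhancing lesion is
segmented on the subtraction image (post − pre) at mean + 3·SD of brain
signal, keeping 6-connected components of at least 10 voxels, optionally
restricted to seeded components; no voxel above threshold yields an empty
mask with a warning, not an error. Features are medians over the mask,
with MD_min the 10th and rCBV_max the 90th percentile. Percentiles use
linear interpolation between order statistics (R's default type 7), which
reproduces the worked order-statistic examples in the test suite exactly;
the alternative "mean of the tail beyond the percentile" reading is
selectable and recorded in the output, since published feature
definitions rarely state their estimator. Non-finite voxels are excluded
and counted.

## The digital phantom

`generate_phantom()` builds a fully synthetic study whose ground truth is
known by construction: a three-regime tensor field (isotropic background
0.75×10⁻³ mm²/s; an enhancing rim whose regime depends on the planted
class; an isotropic high-diffusivity core), forward-simulated DWI with
Rician noise; a DSC series whose per-voxel $\Delta R_2^*$ is the planted
CBV field times a reference gamma-variate minus a planted-K2 leakage
term, converted to signal with Gaussian noise; and a T1 pair with a
deterministic enhancing rim. Defaults mirror the reference acquisition —
1.72 × 1.72 × 3 mm voxels, 30 directions at b = 0/1000 s/mm², 45 frames
at TR/TE = 2000/45 ms — on a 28 × 28 × 10 grid, a size at which the full
pipeline runs in well under a second so that multi-seed end-to-end tests
stay cheap, with baseline SNR 50 (no SNR was published; 50 is a
realistic 3T value).

The planted regimes are placed with margin: TP rims use
λ = (1.50, 1.35, 0.60)×10⁻³ (FA ≈ 0.40 with CL ≈ 0.04 — high anisotropy
that is planar rather than linear, as the model's signs require) and
rCBV scale 4.0; PsP rims are near-isotropic
(λ = (0.95, 0.85, 0.80)×10⁻³, FA ≈ 0.09) with rCBV scale 1.3. Both sit
at least 2 logit units from the PP = 0.5 surface, so fixture noise cannot
flip the class; the generator verifies this invariant at build time and
refuses infeasible specs. The planted CBV field is the regime scale times
a smooth deterministic sinusoidal modulation (±25% in-plane, ±15%
through-plane), renormalized to mean 1 over the reference ROI: real
perfusion varies spatially, and a spatially varying field is what makes
rank-recovery checks (Spearman ρ between planted and recovered rCBV)
meaningful. Generation is seeded and bit-reproducible, and restores the
global RNG state.

What the phantom does *not* emulate — realistic anatomy, partial-volume
and susceptibility effects, motion, bias fields, recirculation, k-space
sampling — bounds what passing tests show: they validate the numerics and
the decision logic of every stage on data whose generative model matches
the processing assumptions, not clinical performance on patient data.

## Numerical and degenerate-input choices

Logistic evaluation goes through `stats::plogis`, which saturates to 0/1
for extreme linear predictors instead of overflowing. Eigenvalue ties are
broken by the stable descending sort of the symmetric eigensolver. A
zero-trace tensor is "spherical" (CS = 1) by convention. An all-zero
leakage reference curve, an empty or non-positive rCBV reference ROI, an
empty feature mask, unordered RANO dates, and out-of-range probabilities
or percentages all raise typed errors (`gliopred_*_error` condition
classes) rather than propagating NaN. Problem sizes in the test suite —
the 28 × 28 × 10 phantom grid, 10 seeds per regime, 10⁵ random eigenvalue
triples, 100 replicate curve fits — were chosen as the smallest sizes at
which each property is convincingly exercised.

## Known limitations

No registration estimation (header affines are trusted); no arterial
input function, CBF or MTT; no DICOM ingestion; single-model scope (the
logistic coefficients are fixed inputs, not refit); RANO here is the
size-plus-persistence core only, without steroid or clinical-status
modifiers. The six-case packaged series is a fixture for verification,
not evidence of generalization.
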