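# asymstroke

Infarct volumetry from non-contrast head CT by **hemispheric asymmetry**, and
the downstream cohort analysis used to study **post-stroke language
deterioration** — group screening, L1-penalized predictor selection with
ROC/decision-curve validation, and partial-correlation / Bayesian / outcome
network inference. A CT phantom generator and a synthetic cohort generator
make every stage testable without patient data.

## Who this is for

Researchers who want a self-contained, auditable R implementation of the
semi-automated CT asymmetry volumetry workflow (the kind usually assembled
from FSL command-line calls) together with the statistical pipeline that
typically follows it in clinical stroke cohorts.

## The core methods

**Volumetry.** An ischemic infarct is hypodense relative to homologous
tissue in the opposite hemisphere. For a scan *I*, the pipeline computes the
rigid transform *T* aligning the left–right flipped image back to *I*
(3-level multi-resolution MSE minimization), forms the absolute difference
map `D = |I ∘ T^{1/2} − flip(I) ∘ T^{−1/2}|` in halfway space, thresholds
`D` at its **98th percentile** over the brain mask, keeps voxels hypodense
relative to their mirror, removes clusters `< 500 mm³` (26-connectivity),
and reports the volume `(#voxels × voxel volume)/1000` in mL. Preprocessing:
RAS+ reorientation, CT skull strip (threshold + morphology + hole fill),
isotropic resampling, HU windowing to [−20, 80].

**Cohort statistics.** For two groups A, B with summaries (m, s, n):

    Welch t  = (m_B − m_A) / sqrt(s_A²/n_A + s_B²/n_B)
    Cohen d  = (m_B − m_A) / s_pooled
    Yates χ² = n·(max(0, |ad − bc| − n/2))² / ((a+b)(c+d)(a+c)(b+d))
    V~       = sqrt(max(0, φ² − (r−1)(c−1)/(n−1)) / (min(r~, c~) − 1))

plus two-sided Fisher exact tests and Benjamini–Hochberg adjustment.
Prediction: coordinate-descent LASSO on `(1/2n)·RSS + λ‖β‖₁`, ROC with the
DeLong AUC interval, decision curves `NB(p) = TP/n − FP/n · p/(1−p)` with a
2000-resample bootstrap band. Networks: GLASSO partial correlations with
refit-EBIC penalty selection and strength/closeness/betweenness/expected-
influence centralities; hill-climbing Gaussian Bayesian networks with
bootstrap arc strengths and a 51% direction rule; network outcome analysis.

## Worked example

```r
library(asymstroke)

# a 20 mL left-hemisphere infarct phantom, 3 HU noise
les  <- lesion_for_volume(20)
spec <- phantom_spec(lesion_center = les$center, lesion_radii = les$radii,
                     noise_sd = 3, seed = 11)
ph   <- make_phantom(spec)
rep  <- quantify_scan(ph$volume, segmentation_config(iso_spacing = 2))
rep
#> <lesion_report> 14.34 mL in 1 cluster(s), laterality left
```

The phantom's true lesion is 19.9 mL; the report recovers 14.3 mL on the
correct side. The under-estimate is intrinsic to the 98th-percentile rule:
the threshold admits at most 2% of brain voxels and the symmetric difference
map spends half of that on the mirror site, capping one-sided recovery at
~1% of the brain volume (~17 mL here). Lesions below the cap recover within
~15% (see the methods vignette, "Known limitations").

```r
# synthetic cohort at the published group sizes, screened by sex
tb  <- simulate_cohort(simulation_params(seed = 3))
cmp <- compare_groups(tb, "gender")
subset(as.data.frame(cmp), variable == "vol",
       select = c(variable, statistic, p_adjusted, effect))
#>   variable statistic   p_adjusted    effect
#> 9      vol -7.411795 1.79247e-10 -1.164498
```

The simulated infarct-volume sex difference reproduces the published effect
(Cohen's d ≈ −1.15, males larger). The same machinery reproduces the printed
test statistics exactly from their printed inputs:

```r
welch_t(69.39, 10.72, 101, 73.51, 9.38, 63)$t   # 2.588  (printed 2.59)
yates_chi_square(32, 13, 69, 50)$chi2           # 1.856  (printed 1.86)
cramers_v_bias_corrected(32, 13, 69, 50)        # 0.092  (printed 0.09)
```

## Command line

```sh
Rscript -e 'asymstroke::run()' phantom --seed 7 --lesion-ml 15 --out out/
Rscript -e 'asymstroke::run()' segment --input out/phantom.nii.gz \
    --iso-spacing 2 --report out/report.json --qc-out out/qc.png
Rscript -e 'asymstroke::run()' cohort  --seed 7 --out out/cohort.csv
Rscript -e 'asymstroke::run()' screen  --cohort out/cohort.csv --group gender --out out/t1.csv
Rscript -e 'asymstroke::run()' predict --cohort out/cohort.csv --seed 7 --out out/model.json
Rscript -e 'asymstroke::run()' network --cohort out/cohort.csv --mode glasso --out out/
```

(an executable launcher is installed at `inst/cli/asymstroke`).

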