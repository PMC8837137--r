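# serialreg

Expert-supervised rigid registration of bone models for serial imaging of
the knee.

When the same knee is imaged more than once — CT twice after repositioning,
or MRI and CT on the same day — quantitative analyses that combine the
acquisitions need the image frames registered. Fully automatic
intensity-based registration is not always trustworthy when protocols are
tuned to particular tissues. `serialreg` implements the expert-supervised
alternative: a triangulated bone model is built from one image set's
segmentation (per-slice closed B-spline contours, lofted into a closed
mesh), a trained operator places a sparse set of *attraction points* on the
bone edges visible in the second image set, and the model is positioned
onto those points automatically.

The algorithmic core is **rigid coherent point drift (CPD)**: the model's
farthest-point surface samples act as centroids of a Gaussian mixture
(shared variance σ², uniform outlier weight *w*) that is rigidly moved by
EM to maximize the likelihood of the attraction points,

&nbsp;&nbsp;p(x) = Σₘ (1−w)/M · N(x; s·R·yₘ + t, σ²I) + w/N,

with the rotation solved in closed form each M-step (SVD of the weighted
cross-covariance, determinant-corrected) and a point-to-surface polish
(exact closest-point ICP) appended so the fit converges to the surface, not
to the sampled centroid cloud. Registrations are evaluated against a
fiducial-marker gold standard (Kabsch/Umeyama corresponding-point fit) and
a whole-model substitution gold standard, using the two standard metrics:
symmetric **mean absolute surface distance** (MAD, mm) and volumetric
**Dice** overlap on a shared voxel grid.

Because clinical imaging data of this kind cannot be shared, the package
ships a synthetic ground-truth generator (bone-like parametric meshes,
simulated operator point placement, interoperator segmentation
perturbation, embedded fiducials) and study harnesses reproducing the
attraction-point-count and method-comparison designs, with Wilcoxon
rank-sum / signed-rank tests and Bonferroni correction.

## Worked example

Simulate one ground-truth case (a femur-like model, a repositioning motion,
a perturbed second-operator reference segmentation, and a 4000-point
operator pool), register the model from 128 randomly chosen attraction
points, and score the result:

```r
library(serialreg)
case <- make_ground_truth_case(kind = "femur", seed = 42)
fit  <- register_model_to_points(case$model,
          subsample_points(case$attraction_candidates, 128, seed = 7),
          seed = 7)
summary(fit)
#> Rigid CPD fit: rotation 12.674 deg, translation 1.499 mm, scale 1.00000
#>   sigma2 = 0.001924 mm^2, loglik = -879.4, 84 iterations (converged)
#>   data-to-nearest-centroid residuals: rms 1.9966 mm, max 6.8949 mm

registered <- predict(fit, case$model)
compare_models(registered, case$reference)
#> MAD 0.2066 mm, Dice 0.9850 (voxel 0.5 mm, 10000 samples/surface)

transform_discrepancy(fit$transform, case$true_transform)
#>   rotation_deg translation_mm
#>      0.2530366      0.1150602
```

The fitted pose is 0.25° / 0.12 mm from the simulated truth; the 0.21 mm
MAD against the reference is dominated by the simulated interoperator
segmentation difference (0.3 mm RMS), not by registration error — exactly
the behavior an interoperator evaluation measures. `plot(fit)` shows the
σ² annealing trace; `coef()`, `residuals()`, `predict()` and `logLik()`
behave as for any fitted model object.

Full study designs:

```r
cfg   <- study_config(master_seed = 1)
cases <- generate_study_cases(cfg)          # 10 femora + 10 tibiae
study <- run_point_count_study(cases, cfg)  # 600 records per bone kind
methods <- run_method_comparison(cases, config = cfg)
```

A thin command-line wrapper over these functions is installed at
`inst/cli/serialreg.R` (subcommands `register-points`, `register-models`,
`register-fiducials`, `metrics`, `simulate`, `loft`, `study`).

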