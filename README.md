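# kneestudy

Tools for studying how radiographic features of knee osteoarthritis (OA)
relate to frequent knee pain — and whether features extracted automatically
from the images can match manual reader grades at that task.

The relation between radiographic OA and knee pain is notoriously weak.
Three of the usual suspects are addressed explicitly in this package's
design: (1) global severity scores may hide the specific features that
matter, so 36 individual ordinal grades (osteophytes, joint space
narrowing, sclerosis, cysts, chondrocalcinosis, attrition, effusion, the
Kellgren–Lawrence grade, …) from two radiographic views (PA and lateral)
are carried separately; (2) some knee pain belongs to a widespread-pain
syndrome rather than to the joint, so a widespread-pain exclusion is built
in; (3) pain is transient, so a *consistent pain* outcome compares people
who answered yes to frequent knee pain on all three baseline instruments
(telephone screen, self-assessed questionnaire, clinic interview) with
people who answered no on all three, discarding inconsistent reporters.

Because the cohorts such studies use are access-restricted, the package
ships a fully synthetic cohort generator with known ground truth, and every
stage of the pipeline is exercised end to end on it:

1. **Synthetic cohort** (`generate_cohort()`) — a latent standard-normal OA
   severity per knee drives (a) joint geometry and texture in rendered
   radiograph-like images (tibiofemoral gap narrowing, marginal
   osteophyte-like bumps, subchondral brightening), (b) the 36 ordinal
   grades with per-feature signal strengths (some at chance by design),
   (c) three repeated binary pain reports observed through symmetric flip
   noise, and (d) age/BMI/sex demographics that also load on pain.
2. **Shape models** (`procrustes_align()`, `build_shape_model()`) — point
   distribution models over the 74-point PA and 102-point lateral landmark
   topologies (patella 21, lateral condyle 24, medial condyle 25, tibia 32).
3. **Appearance models** (`warp_to_reference()`, `build_combined_model()`)
   — textures sampled by piecewise-affine warp into a shape-normalized
   frame; the combined PCA of shape and texture parameters, with the
   variance-balancing weight `W_s = sqrt(sum λ_texture / sum λ_shape)`,
   yields the appearance vector `c` used as the automated feature set.
4. **Automatic landmarking** (`train_detector()`,
   `train_point_regressors()`, `clm_fit()`) — a global joint detector
   (coarse block features, forest regression, residual refinement stage)
   followed by constrained-local-model search: regression-voting response
   maps per landmark, least-squares pose + shape fit, parameters clamped to
   `|b_j| ≤ 3·sqrt(λ_j)`.
5. **Outcomes and feature sets** (`derive_outcome()`,
   `filter_widespread()`, `assemble_features()`) — the four pain outcomes
   (TScreen / SAQ / Clinic / Consistent) and the feature-set grid: single
   grades, all manual grades, manual + sex + BMI, automated
   shape/texture/combined parameters, manual + automated.
6. **Evaluation engine** (`run_repeated_cv()`, `compare_auc()`,
   `table_runner()`) — a random forest with 40 trees under stratified
   5-fold cross-validation repeated 5 times; AUC is the Mann–Whitney
   statistic on pooled out-of-fold scores, reported as mean ± SD over
   repeats; feature sets are compared with a paired DeLong-based χ² test
   whose variance combines the within-repeat DeLong term with the
   between-repeat spread.

## Worked example

Generate a cohort of 800 knees (grades and pain only; add `render = TRUE`
for images and landmarks) and run part of the outcome × feature-set grid:

```r
library(kneestudy)

cfg    <- cohort_config(n_subjects = 800, seed = 42)
cohort <- generate_cohort(cfg, render = FALSE)$table
grid <- data.frame(
  mode = c("CLINIC", "CLINIC", "CONSISTENT", "CONSISTENT", "CONSISTENT"),
  kind = c("MANUAL", "MANUAL_DEMO", "MANUAL", "MANUAL_DEMO", "MANUAL"),
  exclude_widespread = c(FALSE, FALSE, FALSE, FALSE, TRUE))
table_runner(cohort, NULL, grid, cv_config(seed = 42))
```

```
       mode        kind exclude_widespread   n auc_mean auc_sd p_vs_referent
     CLINIC      MANUAL              FALSE 800     53.9    1.4            NA
     CLINIC MANUAL_DEMO              FALSE 800     54.4    1.5        0.8300
 CONSISTENT      MANUAL              FALSE 486     56.0    2.1            NA
 CONSISTENT MANUAL_DEMO              FALSE 486     56.9    1.5        0.6700
 CONSISTENT      MANUAL               TRUE 228     72.4    1.6        0.0006
```

(AUCs in percent; `p_vs_referent` compares each row with the MANUAL row of
the same outcome.) The qualitative pattern of the study design is visible:
the consistent-pain outcome discriminates better than a single clinic
report (56.0 vs 53.9 with the default flip noise of 0.15), demographics add
a little, and removing the widespread-pain subgroup — whose pain is
independent of joint severity by construction — raises the consistent-pain
AUC sharply (72.4 ± 1.6 on the remaining 228 knees in this run).

The fully automatic landmarking pipeline on rendered images:

```r
cfg   <- cohort_config(n_subjects = 1, image_size = 160)
set.seed(7)
train <- lapply(rnorm(30), function(s) render_knee(s, "PA", cfg))
imgs  <- lapply(train, `[[`, "image"); lms <- lapply(train, `[[`, "landmarks")
detector   <- train_detector(imgs, lms, seed = 1)
regressors <- train_point_regressors(imgs, lms, seed = 2)
pdm        <- build_shape_model(procrustes_align(lms), view = "PA")
unseen <- render_knee(1.2, "PA", cfg)
clm_fit(unseen$image, detector, regressors, pdm, truth = unseen$landmarks)
#> <clm_fit> 20 iterations, converged=FALSE, mean error 2.16 px
```

Starting from the detected bounding box alone, the constrained local model
lands about 2 px from the ground-truth outline (the system's accuracy floor
with the default 10-tree patch regressors).

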