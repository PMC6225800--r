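---
title: "Methods: synthetic knee-radiograph cohorts, appearance models, and repeated-CV AUC comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic knee-radiograph cohorts, appearance models, and repeated-CV AUC comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(kneestudy)
```

This vignette documents the models behind `kneestudy`, the choices made
where the design was genuinely open, and what the synthetic experiments do
and do not demonstrate about real radiographs.

## The scientific question

Radiographic osteoarthritis (OA) correlates only weakly with knee pain.
The pipeline in this package operationalizes a study design that probes
three candidate explanations: insensitive global severity scores (so 36
individual ordinal grades from two views are used, plus automated image
features), contamination by widespread-pain syndromes (so a widespread-pain
exclusion is available), and transient pain reporting (so a *consistent
pain* outcome requires the same binary answer at three baseline
instruments: telephone screen, self-assessed questionnaire, clinic
interview). Discrimination is measured as cross-validated AUC of a random
forest, and feature sets are compared by a paired χ² test on the AUC
difference.

## The generative model of the synthetic cohort

Everything observable is driven by a one-dimensional latent OA severity
$s \sim N(0,1)$ per knee. This is deliberately the simplest structure that
reproduces the qualitative orderings the pipeline must detect; it is not a
claim about OA biology.

**Grades.** Feature $k$ with loading $w_k \in [0,1]$ and scale $0..G_k$ is
the ordinal bin of $w_k s + \varepsilon_k$, $\varepsilon_k \sim N(0,
\sigma_g^2)$ with reader-noise SD $\sigma_g = 0.6$. Bin thresholds sit at
fixed quantiles of the marginal distribution (defaults: 80% grade 0 for 0–1
scales; 60/85/95% for 0–3; 35/60/80/93% for the 0–4 global grade),
emulating the sparsity of OARSI-style reading where most knees grade 0.
Default loadings follow the published ordering of single-feature
discriminative power: the global severity grade loads 0.85, osteophytes
0.3–0.6, joint space narrowing and sclerosis 0.2–0.5, and
chondrocalcinosis, cysts, attrition and patellar-tendon ossification load
0 — these are *chance features*, and a classifier given one of them must
sit at AUC 50%.

**Pain.** Persistent pain is Bernoulli with
$\mathrm{logit}\,p = \beta_0 + \beta_1 s + \beta_2 z_{\mathrm{BMI}} +
\beta_3 \mathbb{1}[\text{female}]$, defaults $(-0.85, 1.0, 0.4, 0.3)$,
giving a prevalence near one third. The three instrument reports are the
persistent state flipped independently with probability 0.15 (transient
noise; i.i.d. symmetric flips, no time-ordering, because no per-instrument
error rates are published). A widespread-pain subgroup — fraction 0.5 by
default, matching the halving of the analysis sample when the exclusion is
applied in the study design this emulates — has pain Bernoulli(0.35)
*independent of severity*. Demographics default to age $N(62.3, 8^2)$, BMI
$N(30.7, 5.9^2)$, 60% female. Absolute pain prevalences per instrument are
not published for the source cohort; they are config, not claims.

**Images.** Landmarks are instantiated from a schematic template per view
(74 points PA, 102 lateral). Severity narrows the tibiofemoral gap by a
fixed 0.010 of the unit frame per SD (the whole tibia translates, so the
gap is exactly linear in severity) and displaces marginal landmarks
outward by 0.012 per positive SD (osteophyte analogue); small sinusoidal
fields and similarity jitter provide secondary variation. Rendering splats
Gaussian ridges along the bone outlines over Gaussian background noise and
brightens the subchondral region in proportion to $\mathrm{plogis}(s)$
(sclerosis analogue). The rendering is schematic, not photorealistic: its
purpose is to give patch regressors and texture models real edge structure
with known ground truth.

What passing tests on this cohort do **not** show: robustness to exposure
variation, implants, obesity-related soft-tissue shadows, left/right
differences, reader drift, or any real-world miscalibration between grades
and geometry — in the generator these are all absent or ideal.

## Shape and appearance models

Generalized Procrustes alignment iterates similarity fits (closed-form 2D
Umeyama via the complex formulation) against a running mean that is
re-normalized to centroid zero and unit RMS each round (tolerance 1e-8 on
the mean, cap 100 iterations). Tangent-space projection is omitted: pose
variation in the synthetic data is small, and the omission is the reason
shape parameters are identifiable only up to a small pose–shape gauge
coupling (reconstructions are exact; individual $b_j$ agree to ~1e-3 of a
mode SD). PCA retains the smallest mode count reaching the configured
variance fraction (default 0.95; the source study does not state its mode
counts).

Texture is sampled by piecewise-affine warp into a reference frame scaled
so the mean shape spans 128 px by default (the frame fixes the texture
dimension). The triangulation is Delaunay (Bowyer–Watson, computed once on
the mean shape and frozen into the model) over the convex-hull interior of
the full landmark set — per-bone masks are a possible refinement, left as
config. Texture vectors are normalized to zero mean and unit variance, so
global gain/offset changes of the image cancel exactly. The combined model
concatenates $[W_s b_s; b_g]$ with the classical variance-balancing weight
$W_s = \sqrt{\sum \lambda_{\mathrm{tex}} / \sum \lambda_{\mathrm{shape}}}$
and applies a second PCA (default retention 0.98); its parameter vector
$c$ is the automated appearance feature set, with $b_s$ and $b_g$ exposed
as shape-only and texture-only alternatives.

## Automatic landmark localization

Detection is a two-stage forest regression: block-mean intensity and
gradient features (12×12 grid) vote for the box center and log-width; a
second stage re-extracts features from a window cropped at the coarse
prediction and regresses the residual center offset. The second stage
exists because a single-stage forest on block features plateaus at a
median center error about the size of a feature block. The detector always
returns a box; the spread of per-tree votes is monotonically mapped to a
confidence in (0,1], with a low-confidence flag below 0.5.

The constrained local model then iterates, from the mean shape placed in
the detected box: (1) per-landmark response maps — patches on a 3-px grid
within a 12-px search radius each cast one vote at their forest-predicted
landmark position (votes unweighted); (2) candidate = map argmax, ties
broken at the smallest (row, col), refined to sub-pixel by the vote
centroid in a 5×5 window (pure argmax leaves 1-px quantization jitter that
prevents settling); (3) similarity pose + shape parameters fitted to the
candidates by alternating least squares; (4) parameters clamped to
$|b_j| \le 3\sqrt{\lambda_j}$; until mean movement < 0.5 px or 20
iterations. Patch regressors (one pair of 10-tree forests per landmark,
15×15 mean-centered patches, training offsets uniform within 10 px) are
deliberately small; they give the system an accuracy floor of ~2 px on
rendered images, which is also why a fit initialized at the ground truth
settles near, not at, zero error. Along-contour positions of outline
points are intrinsically ambiguous from local patches; only the shape
constraint resolves them. Search is single-resolution — production systems
add coarse-to-fine pyramids; the synthetic images are clean enough
without.

## Evaluation engine

The classifier is a probability random forest with 40 trees (`ranger`,
other hyperparameters at package defaults, single-threaded for
determinism). Each of 5 repeats draws a fresh stratified 5-fold split
(seeded `seed + repeat`); out-of-fold scores of a repeat are pooled into
one AUC (Mann–Whitney with midrank ties), giving exactly five AUCs whose
mean and SD are reported. A 40-tree forest scores with granularity
$\sim 1/\sqrt{40}$, which costs several AUC points against the optimal
ranking of a single continuous feature — a property of the protocol, not a
bug; it does not affect chance-level calibration.

**AUC comparison.** The χ² test standardizes the mean AUC difference over
repeats by a total variance = mean within-repeat DeLong variance (paired
covariance form) + between-repeat variance of the differences divided by
the repeat count, referred to $\chi^2_1$. Two alternatives were rejected
after simulation: summing per-repeat squared z-values with df = repeats
treats strongly correlated repeats as independent (measured type-I error
~26% at nominal 5%), and the pure DeLong variance misses the model-level
variance that cross-validated scores carry (~11–14%). The adopted
combination is calibrated for the ordinal grade features this package
compares (measured 4–9 rejections per 100 null replicates); for continuous
features prone to heavy forest overfit a residual anti-conservatism from
cross-validation's training-set dependence remains — a known property of
CV inference without refitting. A Venkatraman-style permutation variant
was also evaluated and was no better calibrated here. Comparisons are
paired when both runs share rows and fold seeds, unpaired (summed
variances) otherwise, as when a widespread-exclusion row is compared with
its full-cohort referent.

**Best automated selection.** "Best automated" among shape / texture /
combined parameters is chosen by an inner CV with an independent seed
(`seed + 10000`), so the winner is not picked on the evaluation folds
themselves; a fully nested selection per outer fold would be stricter and
is noted as future work.

## Problem sizes and numerical choices

Unit and acceptance tests run at sizes chosen to make their statistical
margins comfortable on one CPU: chance calibration and the acceptance
script at the study size n = 2756; the consistency-gain property on 20
cohort replicates of n = 1600 (measured median gain ≈ 4 AUC points);
comparison-test calibration on 100 replicates of n = 400; CLM refinement
on 40 training + 50 test images at 160 px. Tolerances: Procrustes 1e-8;
PDM clamp k = 3; degenerate triangles rejected below 1e-9 px²; warp
samples outside the image clamp to the nearest valid pixel; texture
normalization maps constant textures to the zero vector.

## Known limitations

One-dimensional severity cannot express discordant feature patterns
(e.g. isolated patellofemoral disease); the widespread subgroup is a
binary flag rather than a pain-diagram instrument; grades are noisy
monotone functions of the same latent as the geometry, which likely makes
manual and automated features *more* redundant than in real data — so the
finding that automated features do not beat manual grades is expected by
construction here and is a property the synthetic cohort mirrors rather
than evidence about real radiographs. Bilateral correlation, longitudinal
progression, DICOM handling and skyline views are out of scope.
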