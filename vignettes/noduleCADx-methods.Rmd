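---
title: "Methods: texture-based CADx of lung nodules with tuned classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: texture-based CADx of lung nodules with tuned classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem and the pipeline

Classifying a detected lung nodule on chest CT as malignant or benign (CADx)
from a small labelled cohort is a setting where hand-crafted texture features
plus a classical classifier remain competitive: a typical study has fewer than
a hundred nodules, far too few for deep models. `noduleCADx` implements such a
pipeline end to end:

1. **Patch extraction** — the CT volume is resampled to 1 mm isotropic voxels
   by trilinear interpolation and a 64×64×64 patch is cropped around the
   annotated nodule center. Only the center is needed; no segmentation.
2. **Texture features** — rotation-invariant uniform local binary patterns on
   three orthogonal planes (LBP-TOP).
3. **Classification** — either a from-scratch regularized gradient tree
   boosting model (binary logistic objective) or an RBF-kernel soft-margin
   SVM, both emitting malignancy probabilities.
4. **Hyperparameter optimization** — the classifier's and the texture
   operator's parameters θ are tuned by minimizing the leave-one-out
   cross-validation (LOOCV) log loss, with random search or a from-scratch
   Tree Parzen Estimator (TPE).
5. **Evaluation** — ROC AUC and accuracy of the best trial's held-out
   probabilities, averaged over repeated searches.

# Patch extraction

Voxels are treated as cell-centered: input voxel $i$ at spacing $s$ has its
center at $(i + \tfrac12)s$ mm, and output voxel $j$ of the 1 mm grid samples
the input at fractional index $(j+\tfrac12)/s - \tfrac12$, clamped at the
faces. The output shape along each axis is $\mathrm{round}(n_i s_i)$.
Interpolation uses successive linear interpolations in the form
$a + f(b-a)$, which is exact on constant data, and the result is clamped to
the input intensity range so resampling can never manufacture out-of-range
HU values. Crops extending past the volume are padded with −1024 HU (air), a
neutral CT background. Manifest centers are 0-based voxel indices on the
original grid and are converted to mm by multiplying by the original spacing.

# LBP-TOP features

For a pixel $x$ of a 2D slice, the local binary pattern with radius $R$ and
$P$ samples thresholds the circle of neighbors against the center:

$$\mathrm{LBP}(x, R, P) = \sum_{i=0}^{P-1} 2^i\, s\!\big(I(n(x,R,i)) - I(x)\big),
\qquad s(v) = \mathbf{1}[v \ge 0],$$

with neighbor $i$ at angle $2\pi i/P$ counter-clockwise, sampled by bilinear
interpolation (at $P = 40$–$48$ and $R = 7$–$8$ most samples are off-lattice).
The rotation-invariant uniform (riu2) mapping replaces the raw code by its
count of 1-bits when the circular bit string has at most two 0↔1 transitions,
and by a catch-all bin $P+1$ otherwise, giving $P+2$ bins. For a 64³ patch,
riu2 maps are computed on **every** XY, XZ and YZ slice; codes are pooled per
orientation into one histogram, each histogram is L1-normalized, and the
three are concatenated, giving a feature vector of length $3(P+2)$ (126 for
$P=40$, 150 for $P=48$).

Numerical choices that matter:

* The neighbor difference $I(n) - I(x)$ is interpolated directly (bilinear
  weights applied to corner *differences*). The four weights need not sum to
  1 in floating point, so interpolating intensities and subtracting the
  center afterwards can turn an exactly-constant neighborhood into codes
  other than $P$; the difference form keeps $s(0)=1$ exact, and makes codes
  exactly invariant to intensity offsets on integer-valued HU data.
* Circle offsets within $10^{-9}$ of a lattice point are snapped, so
  axis-aligned samples (e.g. $R=1, P=4$) carry no interpolation error.
* A border margin of $\lceil R \rceil$ pixels is excluded rather than padded:
  padding would fabricate texture at patch edges.
* Histograms are L1-normalized per orientation so features do not depend on
  the valid-region size, and whole-volume pooling (all 64 slices per
  orientation rather than the three central planes) uses all texture
  evidence in the patch. Both choices were open in the protocol; they are
  fixed here and recorded with the feature files.

# Gradient tree boosting

The additive model is trained on the second-order expansion of the logistic
loss. With $p_i = \sigma(\hat y_i)$, gradients are $g_i = p_i - y_i$ and
hessians $h_i = p_i(1-p_i)$. A split of a node into children $L, R$ scores

$$\mathrm{gain} = \tfrac12\left[\frac{G_L^2}{H_L+\lambda} +
\frac{G_R^2}{H_R+\lambda} - \frac{(G_L+G_R)^2}{H_L+H_R+\lambda}\right] - \gamma,$$

searched exactly over all features and all midpoints between consecutive
distinct sorted values (with n ≤ 99 instances, histogram approximations buy
nothing). A split is kept only if its gain is positive and both children
carry hessian sum ≥ `min_child_weight`; leaf weights are $-G/(H+\lambda)$;
each round advances the margins by `eta` times the tree output. The base
score is the log-odds of the training prevalence. Ties in the split search
go to the lowest feature index, then the lowest threshold. There is no
row/column subsampling — the four tuned parameters (`eta`, `max_depth`,
`min_child_weight`, `gamma_split`) are exactly the search dimensions, and the
fit is fully deterministic. The number of rounds (50) and the L2 penalty
λ = 1 are held fixed outside the search so trials are comparable; a test
verifies that, at identical hyperparameters, the implementation reproduces
the reference gradient-boosting library's probabilities to ~1e-7.

Tree boosting is invariant to any strictly monotone per-feature transform:
thresholds are midpoints of observed values, so rescaling a feature rescales
the thresholds but leaves every partition — and hence every prediction —
bit-identical. The RBF-SVM, by contrast, is scale sensitive. The test suite
asserts this pair of behaviours explicitly.

# SVM with probability calibration

The soft-margin RBF dual is solved by libsvm (tolerance 1e-3, no feature
scaling — scale sensitivity is part of the model under study). Probabilities
come from a Platt-style sigmoid $p = \sigma(-(Af+B))$ fitted to the
*training* decision values with prior-corrected targets; calibration never
sees validation folds, so the LOOCV loss stays leak-free. Decision values
are sign-normalized so larger always favors the cancer class.

# The LOOCV objective and its optimizers

For a parameter point θ (classifier parameters plus the texture parameters
$R \in \{7,8\}$, $P \in \{40,48\}$), the objective recomputes features at
θ's $(R,P)$, trains on all-but-one sample per fold, and scores the mean
binary log loss of the held-out probabilities, clipped to
$[10^{-15}, 1-10^{-15}]$. Features are memoized per $(R,P)$ — only four
combinations exist. K-fold validation is available, but LOOCV is the
protocol default, and the evaluated AUC uses exactly the best trial's
held-out probabilities (no refit), mirroring the single-loop protocol of the
study design. That protocol shares folds between optimization and
evaluation, which is optimistic; it is reproduced as-is deliberately.

Priors: `C` and `gamma_rbf` are log-uniform over ten decades; `eta` and
`gamma_split` uniform; `max_depth` and `min_child_weight` uniform integers;
$(R,P)$ categorical.

**TPE.** After 10 startup draws from the prior, the history is split into a
good set — the lowest-loss $\min(\lceil 0.25\sqrt{n}\rceil, 25)$ trials —
and the rest. Per dimension, Parzen densities $l(x)$ (good) and $g(x)$
(rest) are mixtures of truncated Gaussians centred at the observed values
(log-uniform dimensions modelled in log space; integers as rounded
continuous; categoricals as add-one-smoothed frequencies), each with one
extra uniform prior component, bandwidths given by the larger adjacent
spacing clipped below at range/100. 24 candidates are drawn from $l$ and the
candidate maximizing $l/g$ is kept, per dimension (the model factorizes, so
per-dimension selection maximizes the joint ratio over the drawn set).

Two of these choices were genuinely open and deserve their rationale:

* *Good-set schedule.* A constant 25 % fraction was measured to trap the
  search in secondary basins on two-basin test objectives (2 of 20 seeds
  never escaped, dragging the mean best loss above random search's); the
  $\sqrt n$ schedule — the convention of the estimator this design follows —
  eliminated those failures (mean best loss on a rescaled Branin after 100
  trials: 0.55 vs 0.97 for random search). The quantile coefficient 0.25,
  24 candidates, 10 startup trials and the bandwidth floor are conventional.
* *Prior mixture component.* Without it the model cannot propose outside the
  observed support and exploration dies with the bandwidths.

# Synthetic phantoms

The generator emulates the *statistical* situation of the nodule cohort —
two classes of 64³ 1 mm patches distinguishable only by 3D micro-texture —
without any anatomical realism. Each phantom is a centered sphere (radius
uniform in 10–20 mm) of contrast +200 HU on a −800 HU lung-like background;
inside the sphere lives a Gaussian-filtered white-noise field, standardized
and scaled by the contrast, whose correlation length is the class label:
1 voxel (benign) vs 4 voxels (cancer) by default. Observation noise is 20 HU
(typical low-dose CT). Intensity means are identical between classes, so
separation is texture-only — LBP's offset invariance would hide a mean shift
anyway. Defaults were fixed once, from domain plausibility, before any
end-to-end measurement.

What passing phantom tests shows: the full chain (disk I/O → resampling →
crop → LBP-TOP → classifier → LOOCV search → AUC) recovers a known
texture-statistical class difference, with chance-level results when the
difference is removed. What it does not show: performance on clinical CT,
where class differences are subtler, confounded, and not purely textural;
absolute AUC values on phantoms say nothing about the nodule cohort's.

# Problem sizes and runtime choices

The shipped tests and the acceptance script use 20 phantoms per class,
searches of 10 trials (the smallest budget in the study protocol) with 3
repeats, and 20-seed/50-trial comparisons for the optimizer benchmarks.
These sizes were chosen so a full run completes in minutes on one core while
every pipeline stage still operates at study-like dimensions (n = 40
patches, 126–150 features, 40-fold LOOCV). At 10 trials TPE is still in its
startup phase and coincides with random search — consistent with the study's
observation that the two are indistinguishable at that budget; the synthetic
objectives benchmark TPE past startup.

# Known limitations

* **Permutation-null AUC under LOOCV.** With labels permuted, the
  loss-minimizing θ is typically one whose regularization forbids all splits;
  the resulting predictor outputs the held-out fold's training prevalence,
  which is *anti*-ranked with the held-out label (19/39 for a held-out
  positive vs 20/39 for a held-out negative), so the null AUC is ≈ 0 rather
  than 0.5. This is the classic LOOCV prevalence artifact, maximal here
  because the base score is the training log-odds and K = n. It indicates
  pessimism, not leakage: the suite verifies separately that no held-out
  sample ever reaches its own fold's training set and that null AUC never
  exceeds chance.
* The shared-fold protocol (optimizing and evaluating on the same LOOCV
  predictions) is optimistic on real data; a nested loop would be needed for
  unbiased estimates.
* Calibration of SVM probabilities is fitted on training decision values of
  each fold; with tiny folds the sigmoid can saturate for extreme (C, γ).
* The TPE model factorizes over dimensions; correlated optima (e.g. C–γ
  ridges) are only captured through the good-set geometry, not jointly.
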