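# noduleCADx

Computer-aided diagnosis (CADx) of lung nodules on chest CT: given a 3D CT
volume and the coordinates of a detected nodule, estimate the probability
that the nodule is malignant. The package targets the small-cohort regime
(tens of nodules) where hand-crafted texture features plus a classical
classifier, carefully tuned, remain the method of choice — no segmentation,
only the nodule center is required.

## What it implements

**Features.** Each volume is resampled to 1 mm isotropic voxels (trilinear)
and a 64×64×64 patch is cropped around the nodule center. Texture is
summarized by rotation-invariant uniform local binary patterns on three
orthogonal planes (LBP-TOP): for every XY/XZ/YZ slice, each pixel gets the
code

    LBP(x, R, P) = Σ_{i=0}^{P−1} 2^i · s(I(n(x,R,i)) − I(x)),   s(v) = 1[v ≥ 0]

with P neighbors bilinearly sampled on the circle of radius R; codes with at
most two circular 0↔1 transitions map to their 1-bit count, the rest to a
catch-all bin (riu2). Pooled per orientation, L1-normalized and
concatenated, this gives a 3(P+2)-dimensional feature vector.

**Classifiers.** A from-scratch regularized gradient tree boosting model
(binary logistic objective, exact greedy splits with second-order gain
½[G_L²/(H_L+λ) + G_R²/(H_R+λ) − G²/(H+λ)] − γ, leaf weights −G/(H+λ)), or an
RBF-kernel soft-margin SVM with Platt-calibrated probabilities.

**Tuning.** Hyperparameters θ — classifier controls plus the texture
parameters R ∈ {7,8}, P ∈ {40,48} — minimize the leave-one-out
cross-validation log loss

    f(θ) = (1/K) Σ_i L(A, θ, D_train_i, D_valid_i),   K = n,

by random search or a from-scratch Tree Parzen Estimator. Performance is the
ROC AUC (Mann–Whitney form) and accuracy of the best trial's held-out
probabilities, averaged over repeated searches.

**Phantoms.** A synthetic generator produces labelled 64³ texture phantoms —
spherical "nodules" on a lung-like background whose only class difference is
the texture correlation length — so the entire pipeline can be exercised and
validated without clinical data.

## Worked example

```r
library(noduleCADx)

spec <- phantom_spec(n_per_class = 20, seed = 7)   # 20 benign + 20 cancer
ds <- generate_dataset(spec)
ds
#> <cadx_dataset> 40 patches (20 cancer / 20 benign)

res <- run_experiment("gtb", ds, n_trials = 10, search = "tpe",
                      n_repeats = 2, base_seed = 1)
res
#> <repeat_summary> gtb + tpe search, 10 trials x 2 repeats
#>   mean validation loss 0.2347, mean AUC 0.9750, mean accuracy 0.9750
summary(res)
#>   algorithm search n_trials validation_loss   auc accuracy
#> 1       gtb    tpe       10       0.2347143 0.975    0.975
```

The searches found hyperparameters whose 40-fold LOOCV held-out
probabilities rank cancer above benign phantoms almost perfectly (mean AUC
0.975): the boosted trees recover the texture-correlation difference between
the classes from the LBP-TOP histograms. The best trial of the first repeat
used θ = (eta 0.54, max_depth 5, min_child_weight 2, gamma_split 0.28,
R 8, P 40).

The same machinery runs from a shell:

```sh
Rscript inst/cli/nodulecadx.R simulate --out_dir data/sim --base_seed 7
Rscript inst/cli/nodulecadx.R features --manifest data/sim/manifest.csv --R 8 --P 48 --out_dir data/feat
Rscript inst/cli/nodulecadx.R optimize --manifest data/sim/manifest.csv \
    --algorithm gtb --search tpe --n_trials 10 --n_repeats 10 --out_dir data/opt
```

Clinical data enter the same way: a CSV manifest `id,path,cx,cy,cz,label`
pointing at NIfTI volumes, with centers as 0-based voxel indices on the
original grid.

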