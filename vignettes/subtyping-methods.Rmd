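---
title: "Deep ensemble clustering of ALFF maps: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep ensemble clustering of ALFF maps: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subtypr)
```

## The problem

Major psychiatric disorders (schizophrenia, bipolar disorder, major
depressive disorder) overlap substantially in their resting-state functional
alterations, and diagnosis-based groupings are often biologically
heterogeneous. `subtypr` implements a trans-diagnostic subtyping workflow
that clusters patients on the amplitude of low-frequency fluctuations (ALFF)
of the resting BOLD signal — a per-voxel scalar map per subject — and scores
how stable the resulting clusters are before calling them subtypes. The
canonical output is a small number of patient subtypes with opposed
frontal-versus-posterior ALFF imbalance patterns relative to controls.

The pipeline has five stages, each usable on its own:

1. **Voxelwise screen.** An ordinary least-squares GLM per mask voxel,
   `ALFF ~ group + sex + age`, with a two-sided test on the group
   coefficient at voxel $p < 0.001$ and cluster-level correction at
   corrected $p < 0.05$. The surviving voxels form the feature matrix.
2. **Embedding.** A fully connected autoencoder compresses the selected
   voxels to $d$ dimensions for every $d \in [2, 10]$ — nine independent
   representations of the same patients.
3. **Ensemble clustering.** Each representation is clustered by
   agglomerative hierarchical clustering (Euclidean distance, complete
   linkage), labels are aligned across representations, and each patient
   receives the plurality label — the consensus partition.
4. **Robustness merging.** The whole embed-and-cluster procedure is rerun
   $J$ times with fresh seeds. For cluster $i$, with matched member sets
   $C_i^j$ across runs, the robustness index is
   $R_i = |\cap_j C_i^j| \,/\, |\cup_j C_i^j|$. While any $R_i \le \delta$,
   the two clusters with the lowest indices are merged and the indices are
   recomputed. What survives is reported as subtypes.
5. **Validation.** Subtype-vs-control contrast maps with voxelwise Cohen's
   $d$, Welch $t$-tests with Benjamini–Hochberg FDR on clinical factor
   scores, and logistic associations of continuous risk scores with
   Nagelkerke pseudo-$R^2$.

## The synthetic cohort generator

Real multi-site ALFF cohorts of this kind are not publicly distributable,
so the package ships a generative model (`sim_config()`,
`generate_cohort()`) that makes every stage testable end to end with known
ground truth.

Each subject is a 3D volume on a small grid (default $16^3$, ellipsoidal
mask covering ~50% of voxels, ~2,000 mask voxels) plus a phenotype row.
The signal model, in units of the voxel noise standard deviation $\sigma$:

* **Controls** carry a constant baseline plus additive covariate effects
  (age, sex; uniform over the mask) plus noise.
* **Patients** additionally receive, in two designated disjoint regions
  ("frontal" and "posterior" spheres along the first axis):
  * a *shared* shift `shared_effect` (default 0.8) in both regions — the
    trans-diagnostic case–control alteration that a patients-vs-controls
    screen can detect;
  * a *subtype-specific* deviation of magnitude `effect_size` (default
    1.0): subtype 1 is frontal $+$ / posterior $-$, subtype 2 the converse.

The shared component is essential: with equal-sized, exactly sign-opposed
subtypes and no shared shift, the patient and control voxel *means* are
identical and a mean-contrast screen has nothing to find. Real cohorts of
this kind show both a common alteration and subtype-dependent directions,
and the generator mirrors that structure.

Noise is i.i.d. Gaussian per voxel, optionally convolved with a Gaussian
kernel (`smoothing_fwhm`, default 2 voxels, circular boundary) and exactly
renormalised to variance $\sigma^2$, so `effect_size` is a per-voxel
Cohen's $d$ regardless of smoothing. Smoothing matters because the random
field theory correction assumes a smooth field; the knob lets the tests
cover both the white-noise and smooth regimes.

Phenotypes include diagnosis labels (cycled SZ/BD/MDD; unused by the
pipeline), a medication indicator, clinical factor scores (patients only;
medicated subtype-1 patients score `factor_effect` = 0.7 sd lower,
emulating a medication-responsive subtype), and continuous risk-score
columns of which only `score_1` is shifted (+0.5 sd) in subtype-1 patients
— emulating a polygenic score that associates with one subtype only.
Ground-truth subtype labels are stored in a separate `truth` table that no
pipeline stage reads.

What the generator does **not** emulate: realistic ALFF spatial covariance
(the smoothing model is a stand-in), site/scanner effects, non-Gaussian
physiological noise, partial-volume effects, and any coupling between
covariates and group. Passing tests therefore demonstrate correctness of
the machinery and calibration under the stated model, not performance on
real scanner data.

## Numerical and statistical choices

**GLM.** Age is mean-centered and sex/group coded 0/1 before fitting;
this leaves the group contrast unchanged and keeps the solve
well-conditioned. The two-sided $p$ comes from the $t$ distribution at
$n - \mathrm{rank}(X)$ degrees of freedom. Rank-deficient designs abort
naming the aliased columns.

**Smoothness.** FWHM per axis is estimated from the variance of spatial
gradients of the unit-normalised residual images
($\hat f = \sqrt{4\ln 2/\hat\lambda}$, with $\hat\lambda$ the mean squared
difference of adjacent mask voxels). White-noise fields give
$\hat f \approx 1.18$ voxels; estimates are clamped at 1 voxel, and
constant residual fields are an error rather than a silent answer.

**GRF cluster correction.** The classic expected-cluster formulation for a
Gaussianised $t$-field: with $u = \Phi^{-1}(1 - p_{\mathrm{vox}}/2)$,
$E[m] = S\,(2\pi)^{-2}\,(4\ln 2)^{3/2}\,u^{2} e^{-u^2/2} / \prod_a f_a$,
$E[N] = S\,\bar\Phi(u)$, cluster-extent tail
$P(n \ge k) = \exp(-\beta k^{2/3})$ with
$\beta = (\Gamma(5/2)/E[n])^{2/3}$, and corrected
$p = 1 - \exp(-2E[m]\,P(n \ge k))$ (the factor 2 accounts for both tails).
Components are extracted at 26-connectivity by default (6/18 available).
The binarised $|t|$ map is used directly, as is conventional for two-sided
screens.

**Permutation correction.** The validation-grade alternative is a
Freedman–Lane permutation of reduced-model residuals: covariate effects are
kept fixed, residuals are permuted, the group $t$-map is refit, and the
maximal suprathreshold cluster extent forms the null; corrected
$p = (1 + \#\{\text{null} \ge k\})/(P+1)$. Extent is integer-valued, so
permutation $p$-values are conservative under heavy ties; the calibration
tests use a smoothed field and a voxel threshold of 0.01 so the null extent
distribution is rich enough to measure the rejection rate.

**Autoencoder.** The encoder follows the halving schedule from the largest
power of two below the input width down to 32, then the bottleneck $d$
(e.g. 2175–2048–1024–512–256–128–64–32–$d$ at full scale; 294–256–128–64–32–$d$
at desk scale). Hidden layers are ReLU; the bottleneck and output are
linear, which suits z-scored inputs of unbounded sign. Features are
z-scored per column before training (otherwise high-variance voxels
dominate the MSE), and the stored transform is re-applied at encode time.
One independent model is trained per $d$ — the schedule ends "–32–$d$",
implying a per-$d$ bottleneck — trained end to end (no greedy layer-wise
pretraining). Training is minibatch Adam (learning rate $10^{-3}$, batch
32) in single precision, the standard arithmetic for neural-network
training, implemented in compiled code with all randomness drawn from R's
RNG so a fixed seed reproduces training bit for bit. Training stops at a
loss plateau: when the full-data MSE has not improved by at least 1%
(relative) for 10 consecutive epochs, capped at `epochs`. The returned
weights are the best checkpoint on record, so the reported final MSE never
exceeds the initial one. `train_autoencoder()` caps at 200 epochs by
default; `pipeline_config()` uses a 60-epoch cap, which at desk scale is
well past the point where the latent geometry that drives the clustering
has stabilised (the planted-recovery tests pass identically at either
cap). A plain-R reference implementation (`engine = "r"`) backs the
compiled path and is checked against numerical gradients in the tests.

**Choice of $k$.** The number of clusters per run is shared across the nine
representations. By default it maximises the mean silhouette width over
$k \in [2, 10]$, averaged across representations, with ties going to the
smaller $k$. This is the largest inferential gap in the procedure — nothing
in the method itself fixes $k$ — so the choice is recorded in the run
manifest and `k` can be set explicitly.

**Label alignment and consensus.** Cluster labels from independent runs are
arbitrary names; before voting, each partition is relabelled by the
maximum-agreement one-to-one matching against a reference partition (the
median-$d$ representation by default), solved exactly by dynamic
programming over column subsets of the contingency table. Unmatched
clusters get fresh labels above the reference's range. The consensus is the
plurality label, ties broken deterministically by the smallest label;
subjects with agreement below 0.5 are flagged, not dropped.

**Robustness merging.** A "run" re-trains all nine autoencoders with fresh
seeds and re-clusters; the feature selection is deterministic given the
cohort and is not repeated. $J$ defaults to 6. Cluster correspondence
across runs uses exact optimal Jaccard matching against the reference
run's consensus. The stopping rule uses the strict inequality
$R_i > \delta$ with $\delta = 0.8$ by default. Merging is applied inside
every run's matched sets too, so the recomputed index refers to the merged
entity — the only self-consistent reading of an iterative merge. An empty
union defines $R = 0$. The loop performs at most $k_0 - 1$ merges; merging
everything yields a single cluster whose index is 1 by construction.

**Validation statistics.** Welch (unequal-variance) $t$-tests are used for
factor scores, since subtype arms are typically unbalanced; the FDR family
is the set of factors within one comparison. Cohen's $d$ uses the pooled,
df-weighted standard deviation. The voxelwise $d$ map is unadjusted (raw
group means), so near-zero voxels can disagree in sign with the
covariate-adjusted $t$; the maps agree wherever the effect is real.
Nagelkerke's
$R^2 = [1 - (L_0/L_1)^{2/n}] / [1 - L_0^{2/n}]$ is computed from the
binomial log-likelihoods; perfect separation is reported with a flag and a
bounded $R^2$, never an error. The default significance threshold for
score associations is $\alpha = 0.004$, a multi-threshold correction level
for families of correlated score columns.

**Seeds.** One master seed drives everything: per-stage seeds (simulation,
the $J \times 9$ autoencoders, permutations) are derived from it by a
counter scheme and recorded in the run manifest, so a pipeline config
reruns bit-identically and any stage can be reproduced from the manifest
alone.

## Problem sizes

The package's default study conditions are desk-scale: cohorts of 200
patients and 100 controls on a $16^3$ grid (~2,100 mask voxels, of which
~300 typically survive the screen), nine embedding dimensions, six runs,
$\delta = 0.8$. The calibration checks use smaller null cohorts (20 + 20
subjects on $10^3$–$12^3$ grids) and 199-permutation corrections, sizes at
which the binomial error of the measured rates is a few percentage points.

## Known limitations

* GRF cluster $p$-values use the classical closed-form field theory; at
  low smoothness (< ~2 voxels FWHM) they are approximate, which is why the
  permutation route exists and is the one whose calibration is asserted.
* The silhouette-based choice of $k$ favours compact, well-separated
  clusters; genuinely nested or chained subtype structure may be
  under-split.
* The autoencoder is trained per run from scratch; there is no
  hyperparameter search, pretraining, denoising or variational variant.
* Validation contrast maps reuse the same cohort that produced the
  subtypes; as in the source workflow, they characterise rather than
  independently confirm the subtypes.
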