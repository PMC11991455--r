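---
title: "Means-field Riemannian classifiers: model, estimation, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Means-field Riemannian classifiers: model, estimation, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfield)
```

## The model

A band-passed EEG trial with $n$ channels is summarized by its $n \times n$
spatial covariance matrix, a symmetric positive-definite (SPD) matrix. The
set of SPD matrices is a curved space, and the natural geometry for
covariance is the affine-invariant Riemannian metric

$$d(A, B) = \lVert \log(A^{-1/2} B A^{-1/2}) \rVert_F,$$

which is invariant under congruence $C \mapsto F C F^\top$ (any linear
re-referencing, re-scaling or mixing of the channels) and under inversion.
All distances in this package are this metric (`airm_distance()`), and all
interpolation is along its geodesics
$A \#_t B = A^{1/2}(A^{-1/2} B A^{-1/2})^t A^{1/2}$ (`geodesic_point()`).

The classical minimum-distance-to-mean (MDM) classifier represents each
class by the geometric (Karcher) mean of its training covariances and
assigns a trial to the class of the nearest mean. The geometric mean is one
point of a one-parameter family: the *power mean* $P_h$, defined for
$h \in (0, 1]$ as the solution of the self-consistency equation

$$P = \sum_k w_k \, (P \#_h C_k),$$

extended to $h \in [-1, 0)$ by the duality
$P_{-h}(\{C_k\}) = [P_h(\{C_k^{-1}\})]^{-1}$, with $h = 1$ the arithmetic
mean, $h = -1$ the harmonic mean, and the geometric mean as the
$h \to 0$ limit. Low-$|h|$ means are robust to heavy-tailed trials, high-$h$
means emphasize high-variance structure; which member of the family
separates classes best depends on the signal-to-noise regime of the
recording, and in practice varies between subjects.

The *means field* is the collection of power means, one per (class, $h$)
pair, sampled on the default grid
$h \in \{\pm 1, \pm 0.75, \pm 0.5, \pm 0.25, \pm 0.1, 0\}$ (11 values,
`default_h_field()`). Three classifiers use it:

* **MDM** (`mdm()`): field restricted to $h = 0$, nearest-mean rule.
* **MDMF** (`mdmf()`): full field, trial assigned to the class owning the
  globally nearest mean.
* **MF** (`mf()`): the vector of *squared* distances from the trial to every
  mean in the field (class-major, $h$ ascending; length
  $\#\text{classes} \times \#h$) is fed to a linear discriminant trained
  together with the means. MF can learn any linear function of all the
  distances, where MDM/MDMF can only use the minimum.

All three are deterministic: there is no randomness anywhere in fitting or
prediction, so repeated runs are bitwise identical. The linear discriminant
is deliberately the closed-form LDA (pooled within-class covariance,
empirical priors) because it has no hyperparameters to tune; the only ridge
is a fixed $10^{-6}\,\mathrm{tr}(\Sigma_w)/p$ inflation applied when the
pooled covariance is singular, e.g. with duplicated features.

## Estimating the means

Power means for $h \neq 0$ are computed by a multiplicative fixed-point
iteration on a square-root factor $X$: with $p = |h|$,

$$H = \sum_k w_k (X C_k X^\top)^p, \qquad X \leftarrow H^{-\varphi} X,
\qquad \varphi = 0.375/p,$$

stopping when $\lVert H - I \rVert_F / \sqrt{n}$ falls below the tolerance;
at convergence $P = (X^\top X)^{-1}$. Negative $h$ runs the same iteration
on the inverted set. The geometric mean has its own fixed point,
$G \leftarrow G^{1/2} \exp(\varepsilon \sum_k w_k \log(G^{-1/2} C_k
G^{-1/2})) G^{1/2}$ with $\varepsilon = 1$ halved on residual increase. All
matrix functions go through the symmetric eigendecomposition — simple,
stable, and exact for symmetric matrices; no series or Schur approximations.

Defaults are a tolerance of $10^{-7}$ and at most 150 iterations. The
tolerance is ample for classification — distances to the means move by far
less than trial-to-trial variability — and the generous iteration cap buys
convergence in low-SNR situations. The fixed-point residual
$\lVert P - \sum_k w_k (P \#_h C_k)\rVert_F / \lVert P \rVert_F$ of every
returned mean is well below $10 \times$ tolerance (verified in the test
suite over random sets).

Because the field samples $h$ densely, the solves are *warm-started*:
positive $h$ in decreasing order from the closed-form arithmetic mean at
$h = 1$, negative $h$ in increasing order from the harmonic mean at
$h = -1$, each solve initialized at the neighbouring solution, and $h = 0$
initialized from the smallest-$|h|$ mean available. Cold starts (when a
mean is requested alone) use the arithmetic mean for $h > 0$, the harmonic
mean for $h < 0$, and their geodesic midpoint for $h = 0$ — closed-form
points inside the convex hull of the data. Uniqueness of the means makes
the warm start a speed-up only: warm- and cold-started fields agree to
within solver tolerance, which is tested.

### Robust estimation

EEG trials are occasionally grossly corrupted. The robust option screens
each class once: estimate the class geometric mean, standardize the
geodesic distances of the trials to it ($z$-scores with sample sd, divisor
$n - 1$), remove trials with $z > z_{th} = 2.5$, and repeat up to $I = 4$
times or until nothing is flagged; the surviving subset then supports the
entire 11-mean field. Guards: if the distances are essentially constant
(sd $< 10^{-12}$) no trial is flagged; a removal that would leave fewer
than `min_retained = 2` trials is skipped entirely rather than applied
partially; weights are renormalized over survivors.

Screening once per class against the geometric mean — rather than
separately for each of the 11 means — was a genuine design choice: it is
11-fold cheaper and keeps a single, internally consistent training subset
per class, at the cost of letting the screen be blind to outliers that are
only extreme relative to high-$|h|$ means. The planted-outlier tests show
the $h = 0$ screen removes dispersion-inflated trials reliably, which is
the failure mode the screen targets.

## Spatial filtering: the two-stage adaptive CSP

Nearest-mean classifiers degrade with many channels, so high-density
montages are first reduced by a spatial filter applied to covariances by
congruence $C \mapsto W C W^\top$. `adcsp_fit()` composes two stages:

1. **Stage 1** (entered when $n \ge 28$, reducing to 28): class means by
   the arithmetic mean; for two classes, the generalized eigenproblem
   $M_1 v = \lambda (M_1 + M_2) v$ with eigenvectors ranked by
   $|\lambda - 1/2|$; for more classes, approximate joint diagonalization
   of the class means. A cheap, Euclidean first cut.
2. **Stage 2** (always after stage 1, entered when the dimension is
   $\ge 10$, reducing to 10): class means by the *geometric* mean of the
   stage-1-filtered covariances, jointly diagonalized by Pham's algorithm,
   components ranked by the between-class dispersion of
   $\log(v_i^\top M_c v_i)$.

Inputs under 10 channels pass through unfiltered. The two thresholds (28,
10) are exposed as arguments with these defaults. Filters are fitted on
training folds only and frozen; test trials only undergo congruence.

Open choices made here (the stage decompositions do not order their
components by themselves): stage 1 keeps the top-28 eigenvectors by
$|\lambda - 1/2|$ overall; stage 2 and the multi-class paths rank
AJD components by the log-variance dispersion score above. Rows are
unit-normalized with the largest-magnitude entry made positive, a pure
sign/scale convention that makes filters reproducible without affecting
distances after congruence (the whitening property of CSP is preserved by
row scaling).

`pham_ajd()` minimizes the log-likelihood diagonality criterion
$\sum_k w_k [\log\det \mathrm{diag}(B C_k B^\top) - \log\det(B C_k
B^\top)]$ by pairwise Newton sweeps; each pair update is damped by step
halving so the criterion never increases, and convergence is declared when
a full sweep decreases it by less than the tolerance.

## Covariance estimation

Trial covariances come from the Oracle Approximating Shrinkage estimator
(`oas_covariance()`): the sample covariance $S$ (divisor $T$; epochs are
assumed zero-mean after band-pass filtering, so no centering option is
exposed) shrunk toward $(\mathrm{tr}(S)/n) I$ with the closed-form
coefficient

$$\rho = \min\left\{1, \frac{(1 - 2/n)\,\mathrm{tr}(S^2) +
\mathrm{tr}^2(S)}{(T + 1 - 2/n)\,(\mathrm{tr}(S^2) -
\mathrm{tr}^2(S)/n)}\right\},$$

with $\rho = 1$ when the denominator is non-positive ($S$ proportional to
the identity). Shrinkage, not eigenvalue clipping, is what guarantees
positive definiteness: $\rho > 0$ whenever $S$ is singular, so even rank-1
epochs yield valid SPD matrices. Elsewhere in the package non-SPD input is
a validation error, never a silent repair.

## Evaluation and comparison statistics

Performance is the AUC-ROC under stratified $k$-fold cross-validation
(default $k = 5$); the fold assignment is a pure function of (labels, $k$,
seed), so every pipeline compared on a dataset sees identical folds.
Continuous scores for the AUC are the signed difference of (minimum)
squared distances for MDM/MDMF and the signed LDA score for MF — the
methods themselves only define decisions, so a score convention had to be
chosen; the signed-distance difference is the natural margin on the
manifold.

Two pipelines are compared per database on per-subject paired AUC
differences: an exact one-sided permutation test enumerating all $2^n$ sign
assignments when $n < 20$ subjects, the one-sided Wilcoxon signed-rank test
(normal approximation, tie-corrected variance, continuity correction)
otherwise. Database p-values are combined by the weighted Liptak function
with weights $\sqrt{n_d}$, and effect sizes by the standardized mean
difference $\mathrm{SMD} = \bar{d}/s_d$ of the paired differences
(a paired Cohen's $d$; no small-sample correction), its 95% CI via
$\mathrm{SMD} \pm 1.96\sqrt{1/n + \mathrm{SMD}^2/(2n)}$, aggregated across
databases with the same $\sqrt{n_d}$ weights.

## What the synthetic generators emulate

No recorded EEG ships with the package; every claim is exercised on
synthetic data with known ground truth.

* `sample_spd_cloud()` / `make_two_class_set()` draw SPD trials as
  $C^{1/2} e^S C^{1/2}$ with $S$ a random symmetric matrix of entry scale
  $\sigma$ — tangent-space (log-normal) sampling, chosen over Wishart
  draws because center and dispersion are then independently controllable
  and the class centers are exactly recoverable. Class centers sit
  $\delta$ apart along a random geodesic; outliers are planted by
  inflating the dispersion (the noisy-trial failure mode the robust screen
  targets), not by translating centers.
* `make_mixed_source_epochs()` builds raw epochs as a random full-rank
  mixture of latent sources in which a designated pair swaps high/low
  variance between classes — an event-related-desynchronization analogue —
  plus white sensor noise at a controlled average per-channel SNR. The
  true mixing matrix is retained so CSP recovery can be checked against
  ground truth.

These generators do *not* emulate realistic EEG spectra (1/f background,
band-limited rhythms), artifact morphology (blinks, EMG bursts),
non-stationarity across a session, or volume-conduction structure from a
head model. Passing tests therefore demonstrate the correctness of the
geometry, the estimators and the statistics under controlled conditions —
not end-to-end performance on recorded BCI data.

Problem sizes used by the test-suite and the acceptance script — 10×10
sets of 10 trials for the mean solvers, 4×4 clouds of 40 trials per class
for robustness (10% outliers at ×10 dispersion), 4-channel heteroscedastic
problems (dispersions 0.2 vs 0.6, separation 0.8) over 20 seeds for the
classifier ordering, 32- and 64-channel mixed-source epochs for the filter
chain — are the package's own desk-scale choices: large enough for the
checked properties to be sharp, small enough to run everywhere.

## Known limitations

* Binary problems are first-class; multi-class MF uses one-versus-rest
  LDA scores with argmax (the nearest-mean rules generalize directly), and
  multi-class cross-validated AUC is not provided.
* The exponent step $\varphi = 0.375/|h|$ makes the power-mean iteration
  slow for $|h| \lesssim 0.01$; such exponents are outside the default
  field and mostly of theoretical interest (use `geometric_mean()` for the
  limit).
* The robust screen assumes outliers are a minority; with
  `outlier_fraction` approaching 0.5 the standardized distances lose
  meaning.
* Epoch containers are plain-text JSON — convenient, diffable and
  dependency-free, but not suited to very large recordings.
* Ties: all argmin/argmax decisions break toward the lower class index,
  documented and tested; scores at exact ties are 0.
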