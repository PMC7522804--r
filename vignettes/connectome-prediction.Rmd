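---
title: "Individualized prediction of sleep quality from functional connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized prediction of sleep quality from functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connpredict)
```

## The analysis

connpredict implements a two-stage individualized prediction analysis for
resting-state functional connectomes. The target is a per-subject
behavioural score on the Pittsburgh Sleep Quality Index (PSQI, an integer
instrument scored 0–21, higher = worse sleep); the predictors are
whole-brain graph features of the subject's functional connectivity matrix.

**Stage 1 (nodal).** For each subject, the region-by-region connectivity
matrix holds the Pearson correlation $r_{ij}$ between the mean BOLD time
series of regions $i$ and $j$ (246 regions in the canonical atlas,
grouped into seven cognitive systems: visual, motor, dorsal attention,
limbic, fronto-parietal, default mode, subcortical). The per-region feature
is the nodal connectivity strength

$$s_i = \sum_{j \ne i} r_{ij},$$

a degree-like centrality with $R - 1 = 245$ signed terms per region: no
absolute value and no Fisher z transform are applied by default, because
global-signal-regressed connectivity has genuinely negative edges and the
summation convention in this literature is the literal signed sum. Both
transforms are available as options (`fisher_z`, `absolute`) for
sensitivity analyses. The 246-dimensional strength vectors are fed to a
relevance vector regression (below) under leave-one-out cross-validation,
and accuracy is summarised by the Pearson correlation $r$, the partial
correlation controlling for age, sex and education, and the mean absolute
error (MAE) between observed and predicted scores. MAE is always computed
on raw scores; residualisation affects only the partial correlation.

**Stage 2 (edge).** A full-sample model is then fit on all subjects, its
sample weights are back-projected to per-region contribution weights, and
the 50 regions with the largest absolute weights are selected. The
connectivity values among those 50 regions ($\binom{50}{2} = 1{,}225$
features) are run through the same cross-validated pipeline, yielding an
edge-level model whose top 50 edges and network-pair weight sums (a 7×7
system-by-system matrix of summed absolute edge weights) describe *which*
connections carry the prediction. Because the stage-2 region set is chosen
on the full sample, its accuracy is interpretive rather than an unbiased
generalisation estimate; a fully nested mode (`nested = TRUE`, region
selection redone inside every training fold) is available when an unbiased
stage-2 estimate is wanted.

## Relevance vector regression

The predictor is linear in a dot-product kernel over training samples:

$$f(x) = \sum_{s=1}^{l} \beta_s \, (x \cdot x_s) + \beta_0,$$

with an explicit zero-mean Gaussian prior on every weight,
$p(\beta \mid \alpha) = \prod_i \mathcal{N}(\beta_i \mid 0, \alpha_i^{-1})$.
The per-sample precisions $\alpha_i$ and the noise variance $\sigma^2$ are
set by type-II maximum likelihood: iterating the classic fixed-point
updates

$$\gamma_i = 1 - \alpha_i \Sigma_{ii}, \qquad
  \alpha_i \leftarrow \gamma_i / \mu_i^2, \qquad
  \sigma^2 \leftarrow \frac{\lVert y - \Phi\mu \rVert^2}{n - \sum_i \gamma_i},$$

where $\mu$ and $\Sigma$ are the posterior mean and covariance of the
weights. Most $\alpha_i$ diverge, pruning their samples; the survivors are
the relevance vectors ($l < n$). The method has no user-tuned
regularisation constant, which is why the cross-validation needs no inner
tuning loop. For the linear kernel the fitted model is equivalent to a
linear predictor $w \cdot x + \beta_0$ with
$w = \sum_s \beta_s x_s$; the absolute entries of $w$ are the feature
contribution weights used for region and edge ranking.

Numerical choices, all recorded in every fitted object:

* deterministic initialisation $\alpha_i = 1/n$, $\sigma^2 = 0.1\,
  \mathrm{var}(y)$ — fits are bit-reproducible, there are no random
  restarts;
* prune threshold $\alpha > 10^9$; convergence when
  $\max_i |\Delta \log \alpha_i| < 10^{-6}$ or after 1,000 iterations;
* $\sigma^2$ floored at $10^{-12}$ so interpolable targets cannot divide by
  zero;
* the bias column is updated like every other weight but never pruned; its
  $\alpha$ is capped at the prune threshold, otherwise it diverges on
  targets that need no intercept and poisons the arithmetic;
* the posterior solve goes through $\Phi^\top\Phi + \sigma^2 A$ (the
  $\sigma^{-2}$ factored out), which stays well-conditioned in the
  small-$\sigma^2$ regime, with a $10^{-10}$ jitter fallback if the
  Cholesky factorisation still fails;
* the log marginal likelihood is evaluated every iteration and returned as
  a trace; the test suite asserts it is non-decreasing.

The inner loop is implemented in C++ (RcppArmadillo) because the
permutation test refits the model hundreds of thousands of times.

## Leakage control

All feature scaling is min–max within the training fold: each feature is
mapped to $[0,1]$ on the training rows and the *same* parameters are
applied to the held-out rows, which may therefore legitimately fall outside
$[0,1]$ and are never clipped. A feature constant in training carries no
information and is mapped to zero in both sets. The test suite includes a
spy harness that replaces held-out rows with `NaN` before the
scaling-and-training path runs and asserts that no prediction changes —
any accidental use of test rows upstream of prediction would surface as
`NaN` contamination.

The permutation test for significance re-runs the *entire* pipeline —
per-fold scaling, model fitting, prediction — against scores shuffled
without replacement (1,000 permutations canonically). $p$ for the
correlation is the proportion of permutations with a null correlation at
least as high as observed; $p$ for MAE the proportion at least as low.
Covariates are never permuted. The literal proportion can be exactly zero;
an add-one smoothed estimate $(b+1)/(B+1)$ is available behind the
`smoothed` flag because the literal rule understates uncertainty at the
boundary. Since shuffling the scores leaves the feature side untouched,
per-fold scaled kernels are computed once and re-used across permutations;
every permutation still refits every per-fold model. For repeated k-fold
schemes each permutation reruns the full repeat-averaged statistic with the
same partitions as the observed run.

For repeated 10-fold cross-validation (20 repeats canonically) the
partition of $n$ subjects uses near-equal folds (the first $n \bmod k$
folds take the extra subject), each repeat seeded by a (seed, repeat)
sub-seed, and the reported accuracy is the *mean of per-repeat metrics*,
not the metric of pooled predictions.

## The synthetic cohort generator

No patient data ship with the package; every test and the acceptance
script run on synthetic cohorts with known ground truth. The generator
emulates the study conditions of a chronic-insomnia-like cohort:

* **score**: $y_i \sim \mathcal{N}(18.4, 2.3^2)$, rounded and clamped to
  the 0–21 instrument range (the continuous latent value is kept in the
  truth record); the acute-like alternative (mean 16.6, SD 3.2) is one
  argument away;
* **base connectome**: a block-structured correlation matrix shared by all
  subjects — within-system $r = 0.3$, between-system $r = 0.05$ over seven
  contiguous system blocks — so network-level aggregation has realistic
  structure;
* **subject variability**: independent Gaussian edge noise
  (`noise_sd`, default 0.05) on every edge. Noise on all edges (not only
  signal edges) is what makes null cohorts non-degenerate: with
  `effect_size = 0` every feature still varies across subjects while being
  independent of the score;
* **planted signal**: edges incident to the planted regions are shifted by
  `effect_size * signal_scale * z(y_i)`, where $z$ is the cohort z-score of
  the subject's score. `signal_scale` (default 0.05 correlation units per
  z-unit) is the connectivity-scale amplitude of the coupling and
  `effect_size` the dimensionless signal-to-noise knob. Keeping the shift
  on the correlation scale of a few hundredths matters: shifts of order
  ±0.5 saturate the $[-1,1]$ edge bound, and after bound-clipping, PSD
  repair and per-fold min–max scaling *every* region becomes equally
  correlated with the score, which makes contribution-weight ranking
  unidentifiable. Planting on incident edges (rather than on strengths
  directly) gives the nodal stage and the edge stage distinct known
  targets;
* **validity repair**: the perturbed matrix is clipped to $[-1, 1]$ and
  projected back to a valid correlation matrix by a single spectral
  projection — eigenvalues clamped at $10^{-8}$, then rescaled to unit
  diagonal. One eigendecomposition per subject keeps cohort generation fast
  enough for the simulation-heavy test suite; an iterated
  alternating-projection repair would be closer to the mathematical
  nearest-correlation matrix but costs an order of magnitude more and the
  residual difference is far below the edge noise;
* **covariates**: age, sex, education, daytime sleepiness (ESS) and head
  motion are drawn independently of the score, matching cohorts in which
  the score is essentially uncorrelated with age and motion; defaults
  follow the chronic-like demographics (age 38.1 ± 10.3, education
  10.2 ± 3.8, 66% female, ESS 9.0 ± 6.2);
* optional **time series**: multivariate-normal draws whose population
  correlation equals the subject's connectome (default 230 time points,
  i.e. 240 volumes minus 10 discarded), so the feature-extraction stage can
  be tested end-to-end against Fisher-z sampling theory.

What the generator does *not* emulate: autocorrelated BOLD noise, scanner
or site effects, preprocessing artefacts, motion-connectivity coupling, or
any nonlinearity in the connectome–behaviour relationship. Passing tests
therefore demonstrate that the pipeline is correct and calibrated under a
linear generative model with exchangeable subjects — not that comparable
accuracy is attainable on real cohorts.

## Design decisions on open points

* **Signed strengths** are the default; the summation is over raw
  $r_{ij}$, with Fisher-z and absolute-value variants behind flags.
* **Stage-2 region selection** uses the full-sample model (the
  two-stage convention), with `nested = TRUE` as the honest alternative.
* **Network aggregation** sums *absolute* edge weights (signed sums are
  attached as an attribute): mixed-sign sums can cancel to zero and
  misrepresent a strongly contributing system pair.
* **Ranking ties** (possible when pruning zeroes many weights) break by
  atlas order, so rankings are deterministic.
* **Permutation granularity**: one global score shuffle per permutation,
  applied consistently across all folds — equivalent to per-training-set
  shuffling under leave-one-out, and well-defined for k-fold.
* **FDR level** for the region-wise covariate screens defaults to
  $q = 0.05$.
* **MAE** is reported on raw scores even when the headline correlation is
  partial; mixing residualised correlations with raw-scale MAE mirrors the
  reporting convention of this literature.

## Problem sizes used in the checks

The simulation-based checks run at sizes chosen to make their statistical
assertions sharp while keeping the whole suite interactive: planted-signal
recovery uses 20 cohorts of n = 100 subjects × 246 regions (10 planted
regions, `effect_size` 0.5, `noise_sd` 0.05), and permutation calibration
uses 50 null cohorts of n = 30 with 200 permutations each, testing the
p-value distribution against Uniform(0,1). The acceptance script runs the
prediction stage on a 44-subject, 246-region cohort (the chronic-cohort
scale) with 200 permutations and a 20×10-fold validation, and the
interpretive stage (top-50 recovery, edge-level model, network
aggregation) on the 100-subject recovery condition.

## Known limitations

* The evidence updates are the classic full fixed-point scheme; the fast
  sequential (basis-addition) variant would scale better past a few
  thousand samples but is unnecessary at cohort sizes of tens of subjects.
* Exact scale equivariance of fits under $y \to c\,y$ holds at the
  evidence optimum but not along the iteration path, because the
  initialisation and prune threshold are fixed constants; in practice
  fits agree to ~$10^{-6}$ relative.
* The permutation p-value of the partial correlation shuffles raw scores
  and recomputes the partial statistic per permutation; shuffling
  residualised scores is a defensible alternative the package does not
  implement.
* `run_full_study()` labels stage-2 cross-validation metrics as
  interpretive unless `nested = TRUE`; treat the default stage-2 $r$ as a
  description of the selected subnetwork, not an accuracy claim.
* Contribution-weight ranking needs more subjects than prediction does.
  With ~250 strongly collinear strength features, kernel solutions shrink
  the shared signal direction, so at n ≈ 40 the back-projected weights can
  rank planted and unplanted regions almost interchangeably even when
  out-of-sample r exceeds 0.95; at the default signal strength, reliable
  top-50 recovery sets in around n = 100. Prediction accuracy and
  interpretability are distinct statistical problems, and cohort sizes
  adequate for one need not be adequate for the other.
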