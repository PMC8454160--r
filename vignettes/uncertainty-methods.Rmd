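---
title: "Hybrid uncertainty quantification for molecular property regression"
author: "molUQ"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid uncertainty quantification for molecular property regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molUQ)
```

## The problem and the error model

QSAR-style regression predicts a real-valued property (typically a pIC50)
from a molecular structure. For deployment it is not enough to predict well
on average: each prediction needs an uncertainty, both to *rank* predictions
by expected absolute error (so unreliable ones can be excluded) and to
*calibrate* intervals around them. molUQ treats the residual of each test
prediction as a zero-mean Gaussian with a sample-specific variance
$\sigma^2(x)$, and an uncertainty method as an estimator — relative or
absolute — of that variance.

Four individual estimators are provided, all computed from a *deep
ensemble* of $K$ independently initialised mean–variance regressors:

* **MVE** — the aleatoric (label-noise) variance $v(\theta, x)$ predicted by
  the variance head, trained with the Gaussian negative log-likelihood
  $\frac 1N \sum_i \left[ \frac{(y_i-\mu_i)^2}{2 v_i} + \frac 12 \ln v_i
  \right]$, averaged over the $K$ members.
* **ENS** — the epistemic estimate: the population variance (divisor $K$)
  of the member means around the ensemble mean.
* **FDIST** — the Tanimoto distance to the nearest training molecule in
  fingerprint space (MinHash signatures over circular substructures, or
  exact Jaccard on binary fingerprints / thresholded feature vectors).
  Model-independent, so it is computed once per split.
* **LDIST** — the cosine distance to the nearest training sample in each
  member's penultimate-layer latent space, averaged over members.

**BYS**, the additive baseline $Q_A + Q_E$, approximates the posterior
predictive variance: the expectation of the noise variance plus the
variance of the predicted mean.

## Consensus strategies

The distance estimators carry information the Bayesian pair lacks (they
notice out-of-domain inputs even when the model is confidently wrong), but
they are unitless. Two linear consensus forms bridge this:

* **Weighted averaging** (ranking-oriented):
  $U_* = w_0 + \sum_i w_i\, \mathbb{H}(U_i)$ with $\mathbb{H}$ a per-vector
  normalization (`zscore` with population SD, `minmax`, or average-tie
  `rank` divided by $n$). Unweighted averaging uses $w_0 = 0,\ w_i = 1$;
  weighted averaging sets $w_i$ to the validation-set Spearman correlation
  of method $i$ with the absolute errors, clipped at zero, falling back to
  the arithmetic mean if every correlation is nonpositive. The bias is
  added once: a constant repeated inside the sum is not identifiable from a
  single intercept.
* **NLL calibration** (calibration-oriented): on the validation residuals
  $e_i$, minimise $\sum_i [\ln Q_i + e_i^2 / Q_i]$ over
  $Q_i = w_0 + \sum_j w_j U_{ij}$ with $w_j \ge 0$, inputs entering
  *unnormalized*, so the output is on the variance scale of the labels.
  Stationarity in a constant $Q$ gives $Q = \mathrm{mean}(e^2)$, which is
  the package's cheapest self-check.

Normalization statistics for weighted averaging are computed on the vector
being scored (test-set internal): ranking is evaluated within a test set
and ranks are only defined within a set. This was a genuinely open choice;
fitting $\mathbb{H}$ on the validation set instead would make scores
transferable across sets at the cost of extrapolating normalization
statistics under shift.

## Evaluation metrics

* **SCC** — Spearman correlation (average-tie) between uncertainties and
  absolute test errors.
* **Confidence curve** — remove the most uncertain sample one at a time
  (ties broken by stable input order) and track the MAE of the remainder;
  the trapezoidal AUC over the removed-fraction axis compares estimators
  (smaller is better). Per-sample removal is the finest deterministic
  granularity.
* **ENCE** — sort by predicted variance into 20-sample bins (the last bin
  absorbs the remainder rather than dropping samples) and average
  $|\sqrt{\mathrm{mVAR}} - \sqrt{\mathrm{MSE}}| / \sqrt{\mathrm{mVAR}}$.
  Note an intrinsic floor: with $b$-sample bins the ratio
  $\mathrm{MSE}/\mathrm{mVAR}$ is $\chi^2_b/b$-distributed even for a
  perfectly calibrated estimator, giving an expected per-bin term
  $\mathbb{E}\,|1 - \sqrt{\chi^2_{20}/20}| \approx 0.126$. ENCE values
  around 0.13 at bin size 20 therefore mean "as calibrated as finite bins
  can show", and the oracle-uncertainty tests assert a 0.15 noise band
  rather than zero.
* **ECE** — over nominal levels $i/100$, the empirical coverage of the
  two-sided symmetric zero-mean Gaussian interval
  $|e| \le z_{(1+i/100)/2} \sqrt{Q}$, averaged as
  $\frac 1{100}\sum_i |\mathrm{acc}(i\%) - i/100|$. Sidedness was not
  dictated by the error model; the symmetric two-sided interval is the
  convention used throughout.

ECE and ENCE are only reported for variance-scale estimates (MVE, ENS,
BYS, calibrated consensus); raw distances get `NA` in the pipeline tables.

## Splitting regimes

All regimes are fivefold with a 60/20/20 train/validation/test ratio:

* **IVIT** — plain random folds.
* **IVOT / OVOT** — built from single-linkage clusters of the Tanimoto
  distance matrix (binarized circular fingerprints, radius 2; cutoff 0.3).
  Cutting the single-linkage dendrogram at the cutoff equals taking
  connected components of the thresholded distance graph, so the minimum
  distance between any two clusters — and hence between any two folds —
  exceeds the cutoff. Clusters are united into five folds greedily,
  largest cluster into the currently smallest fold (ties shuffled by
  seed): the exact uniting rule was unspecified, and greedy balancing is
  the simplest policy that never splits a cluster. OVOT holds out whole
  folds for validation and test; IVOT holds out a fold for test and
  randomly re-splits the pooled remainder 60:20, so the validation set
  shares the training domain.

## Conformal comparator

Inductive conformal prediction with the ensemble-standard-deviation
nonconformity $\alpha_i = |y_i - \hat y_i| / \exp(\sqrt{Q_E(x_i)})$,
calibrated on the validation set. The interval quantile is the
$\lceil (n+1)\,c \rceil$-th smallest calibration score (the standard
inductive rule; an overflowing quantile yields an explicitly flagged
infinite interval), and each test interval is
$\hat y \pm \alpha^* e^{\sqrt{Q_E}}$. *Validity* is the coverage fraction
(a predictor is conventionally valid at $c = 0.9$ when it lands in
$[0.85, 0.95]$); *efficiency* is the mean interval range
($2 \times$ half-width).

## The reference regressor

No graph network is bundled: the trainable-model contract is any object
that returns (mean, aleatoric variance, latent vector) per sample, and the
reference implementation is a small fully connected tanh network on
fixed-length feature vectors with a linear mean head and a log-variance
head ($v = e^s + \text{floor}$, floor $10^{-6}$ in standardised-label
variance units, keeping the NLL finite and the variance positive —
how positivity is guaranteed was an open implementation choice). Training
is full-batch Adam (rate 0.01 after a 10-epoch linear warm-up — a simple
monotone stand-in for cyclical schedules, recorded in the config), with
inputs and labels standardised on the training set. The first 50 epochs
train the mean on squared error with the variance head frozen, which
prevents the classic early collapse of heteroskedastic NLL training; the
early-stopping counter (patience 50, checkpoint with the best validation
loss retained) starts after that phase. tanh was chosen over ReLU so
latent vectors are almost surely nonzero, keeping the cosine distance
well-defined. The latent vector defaults to the post-activation
penultimate layer; the pre-activation alternative is exposed because the
"final layer" convention is ambiguous. Ensembles train members on
identical data with seeds `seed + 0 … seed + K − 1`; $K = 10$ is the
standard practice, smaller $K$ is used in tests for speed.

## The synthetic generator

`generateSynthetic()` emulates the statistical structure the framework
assumes, without chemistry: cluster prototypes are random bit vectors
(Bernoulli 0.5 over 128 bits), samples flip prototype bits at rate 0.05,
and labels are a linear function of the bits plus Gaussian noise with
$\sigma^2(x) = a + b\,g(x)$, where $g$ is tied to cluster identity
(equally spaced on $[0,1]$; defaults $a = 0.05$, $b = 0.95$, eight
clusters of 2000 samples). Cluster-tied noise gives the aleatoric head
learnable structure, mimicking the heteroskedasticity of bioactivity
data; the label weights are scaled ($\mathrm{sd} = 2/\sqrt{d}$) so the
signal variance is about 1 on the label scale, comparable to the noise. A
draw is rejected and regenerated (bounded retries) if any two clusters
come closer than the declared Jaccard margin (0.4), so domain-shift
constructions are guaranteed by construction, and the exact
$f(x)$, $\sigma^2(x)$, $g(x)$ and cluster ids are stored with the data.

What the generator does **not** emulate: real assay-noise magnitudes or
label distributions, activity cliffs, scaffold-continuous chemical space,
or correlated fingerprint bits. Two consequences matter for interpreting
the tests. First, because the labels really are Gaussian with a
feature-predictable variance, a trained mean–variance head can be almost
perfectly calibrated out of the box — real models are usually far more
miscalibrated, which is precisely where post-hoc calibration earns its
keep. Second, clusters separated by a hard margin make out-of-domain
distances jump far outside their in-domain range, which stresses
distance-weighted consensus calibration under shift more severely than
continuous chemical space does; the package's own domain-shift
consensus check reflects this (the ranking clause holds, the ECE clause
is stricter than the fixture can support).

## Problem sizes and numerical choices

The bundled tests train networks at $n \le 2000$, $d = 128$, hidden
width 48, $K \le 5$, which keeps the whole suite in the minutes range on
one CPU; the same code scales to larger ensembles unchanged. The NLL
calibration fit is a deterministic multi-start L-BFGS-B (constant-only
start, one moment-matched start per method, one equal-share start) with
$w_j \ge 0$ bound constraints and the combined variance floored at
$10^{-6}$ inside the objective; ties in rank normalization use average
ranks; Tanimoto distances between two empty bit sets are defined as 0
(identical). Single-linkage clustering delegates to `hclust`/`cutree`,
and its equivalence to thresholded connected components is asserted
against a brute-force union-find in the tests.

## A worked example

```{r example, eval = FALSE}
ms <- generateSynthetic(syntheticSpec(nSamples = 800, seed = 3))
cfg <- runConfig(regime = "IVIT", K = 3, seed = 2,
                 regressor = regressorConfig(maxEpochs = 300))
res <- runPipeline(ms, cfg)
res$summary
```

On this fixture the calibrated consensus (`NLLCAL`) attains the lowest
ECE of all variance-scale methods while matching the best ranking SCC,
and the conformal comparator's validity stays inside $[0.85, 0.95]$ —
the qualitative pattern the framework is designed to produce. Exact
numbers for one run are shown in the README; they are recomputed, not
stored.

## Known limitations

* The reference regressor is deliberately small; it fills the model
  contract but is not a competitive molecular property predictor.
* SMILES featurization requires the optional OpenBabel bridge
  (`ChemmineOB`); without it the package runs chemistry-free on feature
  vectors.
* MinHash signatures use a universal-hash family over circular
  substructure shingles; estimated Jaccard distances converge to the
  exact set Jaccard as permutations grow (the tests bound the deviation
  at 2048 permutations) but individual estimates are stochastic in the
  hash-family seed.
* Consensus forms are linear by design; no stacking or nonlinear
  combiners are provided.
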