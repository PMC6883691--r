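---
title: "Latent region states and platform effects: the methylcomp model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent region states and platform effects: the methylcomp model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylcomp)
```

## Why region-level latent states

Reference-based deconvolution of bulk DNA methylation regresses each
sample's CpG-level beta values on measured cell-type-specific profiles.
Those profiles are platform-bound twice over: the measured methylation
*levels* carry a technology-specific bias (microarrays attenuate values away
from 0 and 1, bisulfite sequencing concentrates them near the extremes), and
each technology interrogates a different CpG set, so profiles measured on an
array are largely unobservable on a sequencing platform.

`methylcomp` sidesteps both problems by changing the unit of analysis from
the CpG to the *region*. In regions where every cell type is clearly
methylated or clearly unmethylated, the binary state is a property of the
biology: any platform that measures any CpGs inside the region can estimate
the region's methylation level, and the level it reports differs from other
platforms only through a systematic, platform-wide shift and spread. That
motivates the model

$$
\mathbf{Y}_i \;=\; \sum_{k=1}^{K} \pi_{ik}
  \left\{ (1-\mathbf{Z}_k)\,\boldsymbol\delta_0 +
          \mathbf{Z}_k\,\boldsymbol\delta_1 \right\}
  + \boldsymbol\varepsilon_i ,
\qquad \sum_k \pi_{ik} = 1,\; \pi_{ik} \ge 0 ,
$$

where $\mathbf{Y}_i$ holds sample $i$'s methylation level in $R$ regions,
$Z_{rk}\in\{0,1\}$ says whether region $r$ is methylated in cell type $k$,
$\boldsymbol\delta_0 \sim N(\alpha_0\mathbf 1, \sigma_0^2 I)$ and
$\boldsymbol\delta_1 \sim N(\alpha_1\mathbf 1, \sigma_1^2 I)$ are
platform-dependent random effects shared by all samples, and
$\boldsymbol\varepsilon_i \sim N(0, \tau^2 I)$ is measurement error. The
binary matrix $\mathbf Z$ is estimated once per tissue from sorted-cell
data and must have full column rank for the proportions to be identifiable;
the constructor rejects rank-deficient matrices and names the dependent
columns.

## Estimation

**Initialization.** Rows of $\mathbf Z$ that are all-zero (the $R^0$ set)
have expectation $\alpha_0$ whatever the mixing proportions, so
$\hat\alpha_0^{(0)}$ is the average over samples of each sample's mean over
$R^0$ rows, and $(\hat\sigma_0^2)^{(0)}$ the average per-sample variance
across those rows (denominator $R^0-1$). By a Jensen argument this variance
upper-bounds $\sigma_0^2 + \tau^2$; we use it as a plain estimate, accepting
that it over-states $\sigma_0^2$ by up to $\tau^2$ (which the EM then
corrects; the bound is tight when $\tau^2 = 0$). All-one rows give the
methylated state symmetrically. Proportions start from the
simplex-constrained fit to the binarized design
$(1-\mathbf Z)\hat\alpha_0 + \mathbf Z\hat\alpha_1$, and $\hat\tau^2$ from
its mean squared residual. If $\mathbf Z$ lacks all-zero or all-one rows —
possible when users supply externally built region sets — the rows with the
most extreme state sums stand in, with a warning; the package's own region
builder avoids this by including consensus regions (below).

**E-step.** Conditional on all observed samples, the posterior of
$\delta_{0,r}$ (and $\delta_{1,r}$) is normal. Because region effects and
noise are independent across regions, the $(RN+R)$-dimensional joint normal
factorizes into per-region blocks of dimension $N$: with mixture weights
$w_{0ri} = \sum_k \pi_{ik}(1-Z_{rk})$, $w_{1ri} = \sum_k \pi_{ik} Z_{rk}$
(note $w_0 + w_1 = 1$ on the simplex), the block covariance is the rank-2
perturbation $C_r = \tau^2 I + \sigma_0^2 w_{0r} w_{0r}^{\!\top} +
\sigma_1^2 w_{1r} w_{1r}^{\!\top}$, inverted with the Woodbury identity in
$O(N)$ per region. A dense-conditioning oracle in the test suite certifies
the equivalence to $10^{-8}$ on fifty random instances. Regions missing in
some samples restrict their block to the observed samples; fully missing
regions fall back to the prior moments and contribute nothing to the
likelihood.

**M-step.** The complete-data MLEs are linear in the posterior sums
$T_1 = \sum_r E[\delta_{0,r}|\mathbf Y]$,
$T_3 = \sum_r E[\delta_{0,r}^2|\mathbf Y]$ (and $T_2, T_4$ for the
methylated state): $\hat\alpha_0 = T_1/R$,
$\hat\sigma_0^2 = T_3/R - \hat\alpha_0^2$, symmetrically for state 1. The
working design $X^{(t)}_{rk} = (1-Z_{rk})E[\delta_{0,r}|\mathbf Y] +
Z_{rk}E[\delta_{1,r}|\mathbf Y]$ feeds one simplex-constrained quadratic
program per sample ($Q = X^\top X$, $a = -X^\top Y_i$, solved by
`quadprog::solve.QP`; a relative ridge of $10^{-10}\,\mathrm{tr}(Q)/K$ is
added only if the solver rejects a numerically singular $Q$), and
$\hat\tau^2$ is the mean squared residual over observed entries.

**Convergence and monotonicity.** Iteration stops when the maximum relative
change across the five model parameters and the maximum absolute change
across all proportions fall below `tol` (default $10^{-4}$; `max_iter`
default 100). Non-convergence is reported in the returned object, not
thrown. One caveat is intrinsic to the algorithm: the proportion update
plugs posterior *means* of the state effects into a least-squares criterion
and drops the posterior covariance terms of the expected complete-data
log-likelihood, so the observed log-likelihood is not guaranteed to ascend
monotonically. In practice we observe small decreases (order $10^{-3}$ per
iteration) near convergence; the fit records the full likelihood trace and
emits one summarizing warning rather than asserting monotonicity.

**Numerical floors.** $\sigma_0^2, \sigma_1^2, \tau^2$ are floored at
$10^{-12}$ so every $C_r$ stays positive definite; on noiseless input
$\hat\tau^2$ hits the floor with a warning and the fit reproduces the exact
proportions (verified to $10^{-6}$ in the tests, typically at machine
precision).

## The reference-based baseline

`houseman_estimate()` implements the classical constrained-least-squares
estimator at CpG level: intersect each sample's CpGs with the reference
profile (at least $K$ shared CpGs are required; the error reports the count,
since CpG loss is exactly how cross-platform application degrades), then
solve the non-negative least-squares problem. By default the sum-to-one
constraint is *off*, so unaccounted cell types can manifest as row sums
below 1; the model-internal QP always keeps the simplex constraint, as the
EM derivation requires. Both behaviors are flags. When a mismatched
reference is used, the direction of the bias follows the spread of the
reference relative to the data: a reference with wider state separation than
the data shrinks the estimated totals below 1, a narrower one inflates them
(tested on constructed designs).

## Building Z from sorted-cell data

`build_z_matrix()` is a deliberately deterministic stand-in for
smoothing-and-permutation DMR hunters: for every cell type and both
directions it computes per-CpG one-vs-rest mean differences (for a two-group
design the least-squares slope *is* the difference of group means; the
effect sign convention is target minus rest), calls maximal runs of
consecutive CpGs with $|\hat\beta_1| \ge$ `effect_cutoff`, a common sign and
inter-CpG gaps $\le$ `max_gap`, ranks candidates by CpG count then mean
absolute effect, and greedily selects non-overlapping regions round-robin
across contrasts. Single-CpG candidates are admitted only when a contrast
yields nothing longer (or on request), mirroring the preference for
multi-CpG regions. Region states are assigned by thresholding each cell
type's mean reference beta at 0.5 (`methylated_threshold`). Consensus
regions — uniformly unmethylated (all states 0) or methylated (all 1) across
cell types — are added by default so the resulting $\mathbf Z$ supports the
moment initialization directly.

Defaults (`effect_cutoff` 0.3, `max_gap` 500 bp, 20 regions per contrast)
were chosen once as values a practitioner would consider reasonable for
fully separated cell-type states on a CpG grid with ~100 bp spacing; all are
exposed in `dmr_criteria()`. Everything here is deterministic: identical
input and criteria give bit-identical output. There is no multiple-testing
inference — downstream estimation only needs a valid full-rank $\mathbf Z$,
not calibrated DMR p-values, and permutation inference is out of scope.

## What the simulation emulates — and what it does not

`simulate_mixtures()` implements the two-platform generative design: one set
of true proportions $\pi_i \sim \mathrm{Dirichlet}(\boldsymbol 2)$ and one
measurement-error draw per replicate, shared across platforms (a flag
redraws noise per platform), with each platform contributing its own state
random effects $\delta^*_l \sim N(\alpha^*_l, (\sigma^2_l)^*)$ and profile
matrix $X^* = (1-\mathbf Z)\delta^*_0 + \mathbf Z\delta^*_1$. Study
conditions default to $N = 200$ samples, $K = 6$ whole-blood cell types,
$R = 210$ regions, $\tau = 0.03$, 100 replicates, an array-like platform
with states at $0.15/0.85$ and a sequencing-like platform at $0.05/0.95$,
both with state variance $0.0025$ — values chosen to mimic the attenuated
vs edge-hugging level distributions of the two technology families. The
acceptance checks run the same design scaled to $N = 50$ and 20 replicates,
which keeps the full suite under a minute of EM time while leaving Monte
Carlo error well below the decision margins.

Draws are clipped to $[0,1]$ and clip events counted. At the defaults
clipping is negligible on the array-like platform (&lt; 0.1%) but affects a
few percent of sequencing-like values, whose states sit near the boundary by
design; this slightly truncates the sequencing noise distribution and is the
main reason fitted state means on that platform carry a small (&lt; 0.01)
truncation bias.

Two honest limitations. First, with equal platform *parameters* the two
platforms still realize independent random effects, so handing the
reference-based estimator the other platform's realized profiles costs a
small errors-in-variables penalty (~0.01 mean RMSE at $\sigma^* = 0.05$)
even without any mean shift; only with the state variances at zero are the
matched and crossed scenarios literally the same problem. Second, the
generator emulates region-level levels directly: it does not model read
depth, CpG-level coverage variation within regions, array probe chemistry,
or batch structure, so passing tests demonstrate correctness of the
estimation machinery under the stated model, not robustness to everything
real data can do.

## Data handling conventions

Coordinates are 0-based half-open throughout (BED convention); Bismark
coverage input (1-based) is converted on read, and a CpG at `pos == end` of
a region is excluded while `pos == start` is included. Strand is ignored;
CpG measurements are assumed collapsed to one strand upstream. Region
summaries are the unweighted mean of CpG levels for array input and the
read-weighted ratio $\sum \mathrm{meth} / \sum (\mathrm{meth} +
\mathrm{unmeth})$ for sequencing input (`weighting = "auto"`; the two
coincide when all CpGs in a region share one total coverage). Regions a
sample does not cover are missing, excluded listwise from that sample's
likelihood blocks and QPs; samples covering fewer than 80% of regions are
rejected by default (`min_sample_coverage`), and a minimum of one CpG per
region per sample is accepted — coverage-starved regions are flagged, not
silently averaged away.

## Known limitations

* The normal random-effects and error model is an approximation; count-based
  (e.g. negative-binomial) likelihoods for sequencing data are out of scope.
* No standard errors or inference on the estimated proportions.
* The region builder assumes clean state separation in the reference; noisy
  or partially methylated references need relaxed criteria and may yield
  regions whose binary states are poor summaries.
* The EM's proportion update is a generalized (not exact) M-step; likelihood
  ascent is typical but not guaranteed, as discussed above.
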