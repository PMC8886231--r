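---
title: "Methods: phylogenetic comparative analysis of climatic-niche evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic comparative analysis of climatic-niche evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyniche)
```

phyniche implements a comparative-methods pipeline for asking how the
climatic niches of the tips of a time-scaled phylogeny have evolved: do
related lineages occupy similar climates (phylogenetic signal), was niche
disparity concentrated early or late in the clade's history (disparity
through time), which simple stochastic process best describes each climate
variable (model fitting), and how fast has each lineage's niche actually
moved (absolute rates)? Every analysis runs on a maximum clade credibility
(MCC) tree and, optionally, on a sample of posterior trees, so that all
reported quantities carry the topological and temporal uncertainty of the
dating analysis.

This vignette documents the statistical machinery, the default parameter
choices and their rationale, what the synthetic-data generator does and
does not emulate, and the numerical decisions that affect results at the
margins.

## Data model

The unit of observation is an *accession*: a georeferenced record assigned
to an operational taxonomic unit (OTU), with values for 19 bioclim-style
variables (`bio1`–`bio19`; annual means, extremes and seasonality of
temperature and humidity). OTUs are the tips of the chronogram. Branch
lengths are read as durations in Myr everywhere, so diffusion rates come
out in trait-units²/Myr and tip rates in trait-units/Myr.

Analyses use per-OTU means, but accession counts are wildly uneven — many
OTUs have a single record — so a per-OTU sample variance is unavailable
for much of the data. `pooled_se()` therefore pools the within-OTU
variance across all OTUs with at least two accessions,

$$ s_p^2 = \frac{\sum_i (n_i - 1)\, s_i^2}{\sum_i (n_i - 1)}, $$

and assigns each OTU the sampling error $se_i = s_p / \sqrt{n_i}$. The
phrase "pooled variance divided by the square root of the sample size" is
sometimes used loosely for this construction; taken literally
($s_p^2/\sqrt{n_i}$) it is dimensionally inconsistent for a standard
error, so the dimensionally correct pooled-SD form is the default and the
literal form is available as `se_formula = "var_over_sqrt_n"` for
reproducing analyses that used it. Pooling is per variable, since bioclim
variables differ in scale by orders of magnitude, and missing values are
dropped per variable rather than per OTU.

## Phylogenetic signal: Blomberg's K with sampling error

`blomberg_k()` computes the K statistic: the ratio of the observed
mean-squared error of tip values around the phylogenetic (GLS) mean,
relative to the phylogenetically corrected MSE, scaled by that ratio's
expectation under Brownian motion (BM) on the same tree. K = 1 is the BM
expectation; K near 0 means trait values are exchangeable across the tree.

Sampling error enters through a two-step procedure: the BM rate σ² is
first estimated by maximizing the likelihood of the tip means under
covariance σ²C + diag(se²) (C the phylogenetic covariance), and K is then
evaluated on the inflated structure matrix C̃ = C + diag(se²)/σ̂². With
all se = 0 this collapses exactly to the classical statistic — a property
the test suite checks against an independent dense-matrix implementation
to 1e-10. When every tip has positive error the computation runs through a
generalized eigendecomposition of diag(se)⁻¹ C diag(se)⁻¹, which makes
each σ² evaluation O(n) and is algebraically identical to the direct
Cholesky route (also tested).

Significance is a tip randomization: trait values are permuted across tips
jointly with their standard errors (so the error structure follows the
data), the default 1,000 times, and the p-value is the plain proportion of
permutations with K at least the observed value (an add-one smoothed
version is available). By default σ² is re-estimated for every
permutation; reusing the observed estimate is a flag. Re-estimation is the
self-consistent choice — each permuted dataset is treated exactly like an
observed one — at a modest computational cost.

## Disparity through time and the MDI

`dtt_curve()` traces mean relative subclade disparity from root to
present. Disparity is the average squared difference over unordered pairs
of values; at each internal-node time the lineages crossing that moment
contribute the disparity of their descendant tips divided by the
whole-clade disparity, and the curve records the mean over lineages. The
root point is 1 by construction, and the grid ends at the present with
value 0 (every lineage is then a single tip). No truncation before the
most recent divergences is applied by default; the comparison runs over
the full relative-time axis.

`dtt_test()` simulates the default 1,000 BM datasets on the same tree
(rate fit by ML to the observed data — disparity ratios are
location- and scale-free, so only the tree shape matters for the null
curve, and the fitted rate is retained for bookkeeping), builds the
pointwise median reference and 95% envelope, and computes the MDI — the
signed area between observed and reference curves, by a left-endpoint
rectangle rule (trapezoid optional) — for the observed curve and for every
simulation. The reported p is the proportion of simulations whose MDI the
observed value equals or exceeds: the tail probability of an MDI as
*negative* as observed (the adaptive-radiation direction), with 1 − p the
relevant tail for positive MDI. The per-simulation MDI distribution is kept
in the result for audit. Measurement error is deliberately *not* injected
into the DTT null — the error model belongs to the signal and model-fitting
analyses — though the machinery accepts it upstream if per-OTU minima or
maxima are analyzed instead of means.

## Trait-evolution models

Three Gaussian models are fit per variable and tree by maximum likelihood,
each with the pooled sampling errors as a fixed, known diagonal added to
the model covariance:

* **BM** — covariance σ²C; parameters z0 (root state) and σ²; k = 2.
* **OU** — non-stationary Ornstein–Uhlenbeck started at z0 with zero
  variance at the root:
  $V_{ij} = \frac{\sigma^2}{2\alpha} e^{-2\alpha (T - s_{ij})}
  (1 - e^{-2\alpha s_{ij}})$ with $s_{ij}$ the shared time and T the tree
  depth; k = 3. The stationary variant (root drawn from the equilibrium
  distribution) is not fit; on ultrametric trees without fossils the
  non-stationary form is the identifiable one and matches the default of
  the standard fitting frameworks.
* **EB** — early burst, BM on a tree whose branch spanning times
  $t_1 \to t_2$ is stretched to $(e^{a t_2} - e^{a t_1})/a$ with a ≤ 0;
  k = 3.

z0 is profiled by GLS at every likelihood evaluation and σ² profiled
analytically (error-free case) or by a bounded 1-D search. The shape
parameters are optimized by multi-start bounded searches: α over
[1e-8, 50/T] in log space and a over [ln(1e-5)/T, 0], each split into five
subintervals with a Brent search per subinterval, convergence tolerance
1e-8 in log-likelihood. For EB the boundary a = 0 (exact BM) is always
evaluated as a candidate. The bounds are this package's choices — wide
enough that optima are interior for any signal the data can support at
these tree depths — and are stated here rather than inferred from any
particular dataset.

On an ultrametric tree the non-stationary OU model is identical to an
*accelerating*-rates model (EB with a = 2α > 0 and rate σ²e^{−2αT}), so an
OU preference cannot be distinguished from exponentially increasing rates.
`fit_model(..., ac_mode = TRUE)` opens the EB exponent to positive values
and the test suite confirms the two parameterizations reach the same
maximized likelihood; ac_mode's upper bound mirrors the lower one, so the
equivalence is representable whenever α̂ ≤ |ln(1e-5)|/(2T).

Model support is summarized with AICc weights,
$w_i \propto e^{-\Delta_i/2}$ with $\Delta_i$ the AICc difference to the
best model and the small-sample correction 2k(k+1)/(n−k−1). Ties in
best-model selection break toward the simpler model (then alphabetically),
and the choice is recorded per (variable, tree) for the rates stage.

## Ancestral states and absolute rates

`ancestral_states()` reconstructs internal-node states as conditional
means of the fitted Gaussian process: with z0 estimated by GLS,
$\hat{x}_v = \hat{z}_0 + \mathrm{Cov}(v, \text{tips})\, V^{-1}
(x - \hat{z}_0 \mathbf{1})$. The node–tip covariances come from the fitted
model (for OU, $\mathrm{Cov}(u, w) = \frac{\sigma^2}{2\alpha}
e^{-\alpha(t_u + t_w - 2s)}(1 - e^{-2\alpha s})$), which is how
"reconstruction on the model-transformed tree" is realized: the OU
covariance is not exactly representable as a tree for all α, so the
transform lives in covariance space, exact rather than cosmetic. For BM
this reduces to the familiar GLS reconstruction and matches both a dense
conditional-normal oracle and an independent implementation in the test
suite. Sampling error, when the best fit used it, is carried into the tip
covariance of the reconstruction by default.

`absolute_tip_rates()` then reports, per tip, |tip value − reconstructed
state of its immediate parent node| divided by the tip's branch duration
*on the original chronogram*. Using the original-time denominator is
deliberate: dividing by EB- or OU-rescaled "lengths" would destroy the
per-Myr unit that makes rates comparable to projected climate change; a
`denominator = "transformed"` flag exists for the alternative reading
(BM/EB only). The same procedure is rerun with per-OTU minimum and maximum
values (model re-fit per basis) to bracket the niche-edge rates.
Zero-length terminal branches yield missing rates with a warning rather
than infinities.

Ensemble summaries use `hpd_interval()`: the shortest contiguous interval
containing ⌈0.95 N⌉ of the per-tree values, leftmost on ties. Diffusion
rate contrasts (`compare_sigma2()`) pair per-tree best-fit σ² values for
two variables (warm vs cold extremes, humid vs dry quarters) and report
the MCC values, both HPDs, the fraction of trees ordering the pair, and
the overlap of the two HPDs as a fraction of the narrower one — the
"largely segregated distributions" judgment as a number rather than a
verdict.

## Synthetic data: what it emulates, and what it does not

The generator exists so the whole pipeline is testable end to end without
any external download, at the scale the analyses target:

* **Tree**: a birth–death chronogram conditioned on 81 tips, rescaled to a
  100 Myr crown age — the size and depth of a genus-level OTU phylogeny
  with tens of OTUs and a Mesozoic crown.
* **Pseudo-posterior**: node ages jittered by mean-one lognormal factors
  (sdlog 0.05), children capped just below their parents in a preorder
  pass so every tree stays ultrametric and the ensemble root age is
  unbiased; topology fixed by default, random NNI moves optional. This
  emulates the *spread* of a dating posterior, not its correlation
  structure: real posterior node ages covary along the tree and with the
  topology, so ensemble HPDs here quantify sensitivity to branch-time
  noise, nothing more.
* **Traits**: 19 variables built as one latent factor per variable group
  plus an idiosyncratic component of the same process class (a sum of two
  independent BM or same-α OU processes remains BM/OU), giving the
  within-group correlation that real bioclim layers show. Groups 1–3
  (means and extremes) evolve under BM (σ² = 0.05 units²/Myr, ≈ 2.2-unit
  tip SD over 100 Myr — a realistic spread for °C-scale variables);
  Groups 4–6 (seasonality, isothermality) under OU with α = 0.05/Myr
  (αT = 5, strong pull). These are the two regimes the analyses must
  separate: K ≈ 1 / MDI ≈ 0 / BM-best versus lower K / positive MDI /
  OU-best.
* **Accessions**: counts per OTU from a rounded lognormal (meanlog 2.52,
  sdlog 1.3, clipped to [1, 454]), giving a heavy-tailed mean near 29
  accessions/OTU; values scatter around the tip mean with SD 2. The exact
  count law is this package's choice; only its min/mean/max shape is
  anchored to real accession tables.

Passing tests on these data show the *estimators* are calibrated (K
centered on 1 under BM, nominal DTT type-I error, unbiased σ², correct
model selection). They do not show that real niche data meet the model
assumptions — no spatial autocorrelation of sampling, no niche truncation,
no raster error structure is simulated.

## Numerical choices and degenerate inputs

* Ultrametricity: relative tolerance 1e-6 of tree depth, configurable;
  violations above it error (or warn), below it pass silently — dating
  software writes rounding noise at this level.
* Newick serialization: 10 significant digits; internal labels, quoted
  labels and comments tolerated on input; root edge ignored.
* Likelihoods: Cholesky factorizations throughout; non-PD covariances
  error with the offending eigenvalue; a 1e-12 ridge (logged) rescues
  numerically singular GLS systems.
* Constant traits: zero trait variance is an error for K and DTT (both
  statistics are undefined ratios there), not a silent zero.
* p-values: plain proportions by default, so 0 is a possible value;
  smoothed (count+1)/(n+1) variants are flags.
* Seeds: every stochastic routine requires one; the pipeline derives
  per-stage/per-variable/per-tree seeds from the run seed by a
  deterministic hash (`derive_seed()`), so partial reruns reproduce
  identical numbers and per-tree results are order-independent.
* Pipeline failures: each (variable, tree) analysis is quarantined; a
  single optimizer corner case is logged into the result's `errors`
  attribute and the run continues, erroring only if everything fails.

## Problem sizes

Default study sizes in the bundled analysis scripts are 81 tips, a
20-tree pseudo-posterior, 19 variables, 1,000 randomizations and 1,000 DTT
simulations. The test suite and the acceptance script use the same tree
scale with 100–500 replicate datasets and 100–200 simulations per test —
sizes at which the Monte-Carlo error of each calibration quantity is well
inside the asserted bands.

## Known limitations

* Single-optimum OU only; no rate shifts, no λ/κ/δ transforms, no
  multivariate fits — each variable is analyzed separately, matching the
  per-variable reporting the pipeline targets.
* The OU transform being covariance-space means "transformed branch
  lengths" are not available for OU (rates use the original-time
  denominator there, which is the default everywhere).
* Sampling error is a fixed known diagonal, not an estimated nuisance
  variance.
* The pseudo-posterior is a sensitivity device, not a statistically
  faithful posterior sample; HPDs over it understate correlated dating
  uncertainty.
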