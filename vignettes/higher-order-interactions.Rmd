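---
title: "Quantifying synergy and redundancy in neuronal parameter ensembles"
author: "hoinfo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying synergy and redundancy in neuronal parameter ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Neurons of a single electrical type realize their phenotype through many
distinct combinations of ion-channel conductances, and single-cell
transcriptomes show structured covariation among ion-channel genes. Pairwise
correlation cannot distinguish two very different statistical organizations
of such ensembles:

* **synergy** — information about the ensemble (or about a target feature
  such as resting membrane potential) is carried only by *joint*
  configurations of several variables, as happens when parameters trade off
  against each other along a degenerate solution manifold;
* **redundancy** — several variables carry overlapping copies of the same
  information, as happens under latent-factor coexpression or when a sample
  mixes tight, well-separated subpopulations.

`hoinfo` quantifies this balance with two higher-order information measures
computed in closed form under a multivariate Gaussian assumption, wraps them
in the scanning, resampling, and selection machinery needed to analyze real
sample-by-variable matrices, and ships seeded generators that reproduce each
statistical structure so every claim in the package is testable without any
external data.

## Measures

For a variable subset $X = (X_1,\dots,X_k)$ with covariance $\Sigma$,
marginal variances $\sigma_i^2$ and leave-one-out minors $\Sigma_{-i}$, all
in nats:

* total correlation $TC = \tfrac12\ln\!\big(\prod_i \sigma_i^2 /
  |\Sigma|\big)$;
* dual total correlation $DTC = \tfrac12\ln\!\big(\prod_i |\Sigma_{-i}| /
  |\Sigma|^{k-1}\big)$;
* O-information
  $$O(X) = TC - DTC = \tfrac12 \ln \frac{|\Sigma|^{\,k-2}\prod_i
  \sigma_i^2}{\prod_i |\Sigma_{-i}|},$$
  positive when redundancy dominates, negative when synergy dominates;
* redundancy-synergy index for predictors $S$ and target $Y$
  $$\mathrm{RSI}(S;Y) = \tfrac12 \ln \frac{|\Sigma_S| \prod_{i}
  \sigma^2_{X_i|Y}}{|\Sigma_{S|Y}| \prod_i \sigma^2_{X_i}}
  = I(S;Y) - \sum_{X_i \in S} I(X_i;Y),$$
  with $\Sigma_{S|Y}$ the Schur complement.

The Gaussian assumption means every quantity is a function of the covariance
matrix alone; the measures should be read as *covariance-structure*
statistics, exact for Gaussian ensembles and interpretable as second-order
approximations otherwise. Empirical, model-free dependence screening is
provided separately (histogram mutual information with permutation nulls),
precisely so the pairwise maps do not inherit the Gaussian assumption.

### The RSI sign conventions

The fraction above is *positive* for the canonical synergistic construction
$Y = X_1 + X_2 + \varepsilon$ (independent unit-variance predictors, unit
noise), where it equals $\ln 2 - \tfrac12\ln 3 \approx 0.144$ nats. Yet
trajectory-level interpretation throughout this field reads *negative*
values as synergy, matching O-information's sign language. These two usages
are genuinely inconsistent, and the package does not paper over that: both
are implemented (`convention = "printed"` for the raw fraction,
`"results"` for its negation), the default is `"results"` because that is
the convention under which reported trajectory values (e.g. an RSI of
$-0.35$ for a resting-membrane-potential module) are negative for synergy,
and the two are exact negations of each other, which the test suite asserts
identically.

### Units

Natural logarithms (nats) throughout. Published magnitudes in this area
rarely state nats versus bits; we take nats, consistent with the $\ln$ in
the closed forms. A bits presentation is a division by $\ln 2$ left to the
caller.

## Scanning tuples

`scan()` evaluates O-information (or RSI against a target) over all variable
tuples per order when $\binom{N}{k}$ fits the per-order budget (default
20\,000), and otherwise draws distinct tuples uniformly without replacement
under a seed derived from the scan seed and the order. The exhaustive flag
is reported per order because sampled extrema are biased toward zero
relative to exhaustive extrema; curves mixing the two regimes should be
compared only like-for-like. Tuples whose covariance submatrix is singular
(collinear variables) are skipped and tallied rather than erroring, since a
single duplicated variable would otherwise poison every order.

Derived objects:

* **frequency maps** (`top_fraction_frequency`): the per-order top 5% most
  extreme tuples (ceiling, at least one tuple) are selected and each
  variable's appearance frequency among them is normalized by the number of
  selected tuples, so a column sums to its order;
* **minimal synergistic sets** (`minimal_synergistic_set`): the smallest
  order whose per-order extremum comes within a tolerance (default 1% of
  the global extremum's magnitude — a plateau criterion, since "the curve
  stops improving" needs a quantitative cutoff) of the global extremum,
  with lexicographic tie-breaking for determinism;
* **stabilization points** (`detect_stabilization`): the position with the
  minimum discrete second difference, ties to the first interior position.
  Taken literally, this rule is geometrically ambiguous for decay-to-plateau
  curves (their interior second differences are nonnegative, so the minimum
  lands where curvature first vanishes — the plateau onset); an alternative
  maximum-$|d_2|$ knee detector is available but non-default, and we make no
  claim about which variant produced any published stabilization order.
  Positions are 1-based indices into the series.

## Inference

* **Bootstrap bands** (`bootstrap_band`): 50 repetitions by default, each
  drawing a fixed number of rows *without replacement* (1,000 by default,
  mirroring common practice for large model ensembles; use ~60% of cells
  for small expression datasets), re-estimating the covariance, and
  re-evaluating the *same* tuple list drawn once up front. Fixing the tuple
  list makes the band width reflect row-sampling uncertainty only, which is
  what a confidence band around a trajectory should depict; re-drawing
  tuples per replicate would conflate two sources of noise. Percentile 95%
  intervals, since nothing here justifies a parametric band.
* **Shuffle surrogates** (`shuffle_surrogates`): 100 surrogates by default,
  each permuting every column independently — destroying all cross-variable
  dependence while preserving marginals exactly — and recording per-order
  extrema. An observed trajectory escaping this band indicates structure
  beyond what marginals plus finite-sample noise produce.
* **Trajectory AUC** (`oinfo_auc`): trapezoidal area across orders, split
  exactly at zero crossings; by default synergy AUC comes from the
  per-order minima and redundancy AUC from the per-order maxima, both
  reported as absolute areas. Groups of AUCs are compared with a two-sided
  Mann-Whitney U test.
* **Dataset guard** (`dataset_guard`): resampling is refused below 100
  samples or when labeled classes are strongly imbalanced (smallest class
  below 10% by default — the threshold is a package choice, configurable,
  as no standard number exists).

## Empirical mutual-information maps

Pairwise dependence screening uses plug-in MI on 10 equal-width bins per
variable (configurable; bin counts in this range trade bias against
variance and the permutation null absorbs the plug-in bias, which is why no
Miller–Madow-style correction is applied), a 1,000-permutation null
shuffling the second variable with an add-one p-value, Benjamini–Hochberg
FDR at $\alpha = 0.05$ via `stats::p.adjust`, and an additional minimum
effect size of 0.1 nats for a pair to be called significant. The map also
reports how many variables participate in at least one significant pair.
Permutations run on a dedicated deterministic RNG, so identical seeds give
bit-identical p-value matrices on any platform.

## High-covariance subset selection

`select_high_covariance` fits a PCA (variables z-scored first by default —
conductances, calcium time constants and expression levels do not share a
scale, and unstandardized PCA would let the widest-variance variable define
the subspace), reconstructs each sample from the top 5 components, and
keeps the 1,000 samples with the smallest residual L2 error, computed in
the standardized space for consistency with the fitted model. Samples near
the leading subspace are exactly the ones whose variables covary most, so
this selection raises redundancy by construction.

A geometric point worth making explicit: with $r$ retained components among
$p$ variables, near-subspace selection pushes O-information by roughly
$(2r - p)$ times half the log of the per-direction trailing-variance
shrinkage. At $p = 10, r = 5$ the effect is neutral and *no* selection can
flip the balance; the redundancy shift emerges for $p$ comfortably above
$2r$, which is why the packaged demonstration uses 20 variables with 5
components — the geometry of the ensembles this method is used on (about 20
conductance parameters, 5 components).

## Gene-panel clustering and the ARI null

Expression matrices are preprocessed by $\log(1+x)$ then gene-wise
z-scoring (zero-variance genes dropped with a warning; re-processing an
already processed matrix errors rather than silently double-transforming).
Cells are clustered from a gene panel by PCA (50 components, capped by the
data), a k-nearest-neighbor graph ($k = 15$, Euclidean in PC space), and
Leiden community detection under the modularity objective at resolution 1.0
via `igraph`; these hyperparameters are package defaults in line with
standard single-cell toolchains, all exposed in the API. Agreement with
ground-truth types uses the adjusted Rand index, with the degenerate case
of two single-block partitions defined as 1 for determinism. The kNN graph
is built from a full distance matrix, which is adequate for the
thousands-of-cells scale this package targets but quadratic in cells.

`ari_null` draws many random panels of matched size (500 by default — the
number attached to reported null ARI distributions; a 1,000-draw setting is
one argument away) from the full gene pool or from a restricted pool such
as differentially expressed genes, clusters each identically, and places
the focal panel's ARI as a percentile (midrank convention for ties) of the
null. DEGs are identified by one-vs-rest Wilcoxon rank-sum per gene per
class with BH correction — a deliberately standard stand-in, since DEG
pipelines vary; the ranking, not the exact test, is what the null pool
needs.

## What the generators emulate — and what they do not

Every generator takes a mandatory seed, is bit-reproducible, and returns
its full configuration plus ground truth alongside the data.

* `gen_independent` — the null ensemble; O-information fluctuates inside
  the surrogate band at every order.
* `gen_redundant` — latent-factor coexpression $X = LZ^\top + E$;
  population covariance $LL^\top + \sigma^2 I$. One unit-loading factor with
  unit noise gives every triple $O = \tfrac12\ln(32/27) \approx +0.085$
  nats, a closed form the tests pin.
* `gen_synergistic` — sampling conditioned exactly (conditional Gaussian,
  not accept-reject, so the target distribution is exact and no draws are
  wasted) on a soft linear phenotype constraint $w^\top X = y_0 + \eta$,
  $\eta \sim N(0,\tau^2)$: the degeneracy structure of model populations
  fit to one phenotype. The population covariance is
  $(I - ww^\top/\|w\|^2) + ww^\top\tau^2/\|w\|^4$. Note $\tau = \|w\|$
  makes the constraint exactly vacuous (population covariance $I$); an
  infinitely loose $\tau$ does *not* recover independence under exact
  conditioning — it over-disperses the constrained direction — so tests of
  the vacuous limit use the variance-matched $\tau$.
  `constraint_tau_for_correlation` maps a target equicorrelation to its
  $\tau$, connecting simulations to the equicorrelated closed form.
* `gen_cluster_mixture` — tight Gaussian clusters whose centers themselves
  follow a constraint-conditioned distribution by default (one draw per
  cluster then reproduces a synergy-rich ensemble, emulating diverse
  model repositories), with an oversampled mode drawing many samples from
  few clusters (the cluster-identity axis becomes a shared factor, driving
  redundancy — the sampling-strategy effect). Within-cluster offsets can
  themselves be constraint-structured for studying pooled nearly-coincident
  clusters.
* `gen_feature_map` — target features as a weighted sum of 2 variables (a
  resting-membrane-potential-like module) or a sum of pairwise products
  over ~10 mean-shifted variables (an interspike-interval-like broad mix;
  the mean shift keeps products linearly correlated with their factors,
  without which a Gaussian analysis would be blind to the map).
* `gen_counts` — zero-inflated rounded log-normal counts with a planted
  subtype-informative panel and an optional shared latent factor on the
  panel. This emulates the *structure* single-cell inputs present to the
  pipeline (dropout, skewed positive counts, subtype shifts, coexpression);
  it is not a calibrated fit to any sequencing protocol, makes no claim
  about real library-size or dispersion distributions, and a
  negative-binomial alternative was deliberately left out of scope as the
  analysis only consumes the log-standardized matrix.

Passing tests on these generators show the pipeline detects each planted
structure at realistic sizes; they do not show that real parameter
ensembles are Gaussian, that real expression is log-normal, or that the
Gaussian O-information of heavy-tailed data equals its "true"
information-theoretic value.

## Numerical choices

* All determinants go through Cholesky with an explicit positivity check;
  pivots below a $10^{-12}$ relative tolerance count as singular (exactly
  collinear columns can otherwise pass floating-point Cholesky with a tiny
  positive pivot). Singularities are errors (or skipped-and-tallied tuples
  inside scans), never silent `NaN`s, because a singular minor usually
  means duplicated variables — something the analyst must know.
* Covariance uses the unbiased $n-1$ estimator; the optional ridge adds
  `ridge * trace/p` to the diagonal and defaults to 0 — explicit
  regularization over silent smoothing.
* Permutation p-values use the add-one form $(1 + \#\{\ge\})/(1 + B)$.
* Tuple sampling, bootstrap, surrogates and panel draws derive child seeds
  from the caller's seed, so independent stages do not share RNG streams.

## Problem sizes

The packaged tests and the acceptance script run at desk scale, chosen to
finish comfortably on one CPU while keeping every effect far from its
decision boundary: ensembles of 400–8,000 samples over 8–20 variables,
50-seed replications for the surrogate-band and FDR properties, 500
random-panel draws at 300 cells × 2,000 genes for the ARI null, and 100
surrogates / 50 bootstrap repetitions matching the method defaults.

## Limitations

* The closed-form measures are Gaussian; heavy tails, nonlinear manifolds
  and zero inflation are seen only through their covariance footprint.
  The histogram-MI module is the model-free cross-check at the pairwise
  level; no non-Gaussian higher-order estimator is provided.
* Sampled (non-exhaustive) scans estimate per-order extrema conservatively;
  frequencies from sampled orders are estimates, not enumerations.
* The kNN graph construction is $O(n^2)$ in cells.
* `identify_degs` is a generic rank-sum ranking, not a replacement for a
  dedicated differential-expression pipeline.
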