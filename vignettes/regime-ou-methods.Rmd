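---
title: "Multi-regime OU models of genome size evolution: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-regime OU models of genome size evolution: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ouregimes)
```

## The scientific problem

Salamander genome sizes span an enormous range, and life history is a prime
candidate driver: metamorphosis plausibly constrains genome (and hence cell)
size, while paedomorphic lineages freed from metamorphic remodeling may
drift or be pushed toward larger genomes. `ouregimes` asks this question
the way modern phylogenetic comparative methods do: model natural-log genome
size (ln pg) as a stochastic process evolving along an ultrametric
phylogeny whose branches are painted with *life-history regimes*, fit
alternative regime groupings by maximum likelihood, and compare them with
AICc and parametric-bootstrap model selection.

Four life-history codes are distinguished — abrupt metamorphosis, gradual
metamorphosis, direct development, and paedomorphosis — and five nested
regime hypotheses grouping them (from "one regime, pure drift" up to "all
four distinct"; see `build_hypotheses()`).

## The model

Trait evolution within a regime follows an Ornstein–Uhlenbeck (OU) process

$$dX(t) = \alpha\,(\theta(t) - X(t))\,dt + \sigma(t)\, dB(t),$$

where $\theta(t)$ and $\sigma(t)$ take regime-specific values along each
branch, $\alpha \ge 0$ is the pull toward the equilibrium, and $B$ is
standard Brownian motion.  We deliberately read $\theta$ as a
*deterministic equilibrium* — the balance point of mutation pressure and
constraint — rather than a "selective optimum": nothing in the mathematics
requires the pull to be adaptive.  Setting $\alpha = 0$ gives Brownian
motion (BM).  The model classes are:

| class | free parameters | count (r regimes) |
|-------|-----------------|-------------------|
| BM1   | $\sigma$, root state $x_0$ | 2 |
| BMS   | $\sigma_i$, $x_0$ | r + 1 |
| OUM   | $\alpha$, $\sigma$, $\theta_i$ | r + 2 |
| OUMV  | $\alpha$, $\sigma_i$, $\theta_i$ | 2r + 1 |

Multi-$\alpha$ classes (OUMA, OUMVA) are enumerated for completeness but
not fitted; in our experience, as in the wider literature, they are prone
to fitting pathologies on data of this size, and `model_spec()` marks them
enumeration-only.  Crossing the classes with the five hypotheses gives 21
candidate models, 13 of them fit-able.

Because shifts are painted at nodes (each edge takes the regime of its
child node), every root-to-tip path decomposes into timed regime segments,
and the tip vector is exactly multivariate normal.  With time running from
0 at the root to $T_i$ at tip $i$, and the root trait fixed at the root
regime's equilibrium:

* mean: $E[x_i] = e^{-\alpha T_i}\theta_{\mathrm{root}} + \sum_{[a,b],\rho}
  (e^{-\alpha(T_i-b)} - e^{-\alpha(T_i-a)})\,\theta_\rho$ — a convex
  combination `W %*% theta` whose weights sum to one;
* covariance: $V_{ij} = e^{-\alpha(T_i+T_j)} \sum_{[a,b]\subset[0,t_s],\rho}
  \sigma_\rho^2\,(e^{2\alpha b}-e^{2\alpha a})/(2\alpha)$, summing over the
  shared root-to-MRCA path ($t_s$ = MRCA depth);
* BM replaces these with $x_0$ and the $\sigma^2$-weighted shared path
  length.

**Root convention.** Fixing the root at the root regime's equilibrium (and
giving the $e^{-\alpha T_i}$ weight to that regime's column of `W`) is the
convention under which the parameter counts above hold — e.g. $k = 9$ for
the four-regime OUMV ($\alpha$ + 4$\sigma$ + 4$\theta$) and $k = 2$ for BM1.
A stationary-root variant would add root variance
$\sigma^2_{\mathrm{root}}/(2\alpha)\,e^{-\alpha(T_i+T_j)}$ to every pair;
we keep it out of scope so that likelihoods and counts match the fixed-root
convention exactly.

## Fitting

`fit_model()` profiles everything it can and searches over the rest:

* the mean coefficients ($\theta_i$, or $x_0$) are profiled out by
  generalized least squares at every likelihood evaluation,
  $\hat\theta = (W^\top V^{-1} W)^{-1} W^\top V^{-1} x$, computed through a
  Cholesky factorization of $V$ (never an explicit inverse; a
  non-positive-definite $V$ is an error, not a silent regularization);
* the overall noise scale is profiled analytically
  ($\hat\sigma_1^2 = r^\top \tilde V^{-1} r / n$);
* what remains — $\log\alpha$ and the log noise-variance ratios — is
  maximized by bounded quasi-Newton (`optim` L-BFGS-B) from a four-point
  multi-start grid of $\alpha$ values whose half-lives $\log 2/\alpha$ span
  $[T/50,\,2T]$; $\alpha T$ is bounded in $[10^{-3}, 50]$ and the log
  ratios in $[-12, 12]$.  BM1 needs no search at all.

Log-scale parameterization keeps the scale parameters off the boundary;
the optimizer tolerance (`factr = 1e7`, about $10^{-9}$ relative on the
log-likelihood) is far below anything the data can distinguish.  AICc ties
would be broken toward fewer parameters.  Replicate fits inside bootstrap
procedures are warm-started at the observed-data MLEs, which is standard
practice and materially cheaper.

Identifiability deserves a caveat: on a single draw of 118 tips, $\alpha$
and the $\theta_i$ of regimes far from the root are only weakly identified
(the likelihood in $\alpha$ is shallow), so point estimates wander even
when orderings are stable.  This is why the package leans on bootstrap
intervals and model selection rather than point estimates.

## Model comparison

`aicc()` implements $-2\log L + 2k + 2k(k+1)/(n-k-1)$, and
`build_model_table()` ranks converged fits, flagging the conventional
$\Delta\mathrm{AICc} \le 4$ support set.  Because AICc can favor complex
models, `pmc_compare()` implements the phylogenetic Monte Carlo
(parametric bootstrap) comparison of a simpler against a richer model:

1. fit both to the data, $\delta_{\mathrm{obs}} = -2(\log L_0 - \log L_1)$;
2. simulate `n_sims` datasets under the simpler model at its MLEs, refit
   both, collect the null $\delta$ distribution; the p-value is the
   fraction of null $\delta \ge \delta_{\mathrm{obs}}$ (a zero fraction is
   printed as `< 1/n_sims`; the stored value stays 0);
3. simulate under the richer model's MLEs likewise; power is the fraction
   of those $\delta$ above the null distribution's 95th percentile.

The two arms use independent RNG streams derived from the master seed, so
resizing one arm never perturbs the other.  Replicate fits that fail are
dropped and counted; more than 50% failures in an arm aborts the
comparison.  The six standard comparisons (drift vs metamorphosis;
refining "other"; refining "metamorphosis"; each three-regime model vs the
four-regime one; single vs multiple $\sigma$ within the four-regime model)
are plain (simple, complex) pairs in `run_pmc_suite()` with no
special-case code.

One subtlety: with a deterministic fitter, a *literal* self-comparison
(identical model against itself) yields $\delta \equiv 0$ in both arms, a
point mass for which "power" degenerates to 0.  The textbook statement
that self-comparison power sits at the 5% tail mass presumes a continuous
$\delta$; the property that actually holds — and that the test suite
checks — is that the power estimator applied to two *independent* samples
from one continuous $\delta$ distribution returns $\approx 0.05$.

## Stationary distributions

For $\alpha > 0$ each regime has stationary law
$N(\theta_i, \sigma_i^2/(2\alpha))$ (`stationary_distribution()`).
`regime_summary()` tabulates observed per-regime tip means and variances
against these predictions on the ln-pg scale — the numerical content of a
histogram-overlay figure; `fd_breaks()` supplies Freedman–Diaconis bins
(the binning is a display choice, nothing downstream depends on it).
Display in pg is a convenience transform only; all modeling is in ln pg.

## The synthetic study

Because the original data bundle is not redistributed here, the package
carries a generator (`study_mimic_fixture()`) whose defaults *are* the
study conditions: 118 tips on a unit-height pure-birth tree; clade-
structured regimes with tip shares of roughly 40% direct development (the
background regime, which also holds the root), 30% gradual metamorphosis,
15% abrupt metamorphosis, 15% paedomorphosis (shares estimated from the
clade structure of the group; every regime is guaranteed at least 5 tips);
and traits simulated under the four-regime OUMV model at $\alpha = 1.3$,
$\theta = (2.7, 3.7, 3.7, 4.3)$, $\sigma = (0.4, 0.6, 0.8, 0.4)$ for
(abrupt, gradual, dd, paed) — rounded magnitudes of published estimates
for this system, documented as approximations rather than claims.  On a
unit-height tree $\alpha = 1.3$ means a phylogenetic half-life of about
0.53 tree depths.

What the generator emulates: the clade structure of regimes, realistic
effect sizes and noise, exact ultrametricity, reproducibility from one
seed (tree draws are retried if no clade arrangement can satisfy the
minimum regime sizes — a property of the generator, not of any particular
seed).  What it does not emulate: regime evolution as a process on the
tree (paintings are drawn, not evolved), measurement error and
multi-study heterogeneity in the trait values, extinction (pure-birth
trees only), and topological uncertainty.  Passing tests on this fixture
therefore validate the *machinery* — likelihoods, optimization,
calibration of the Monte Carlo — not the biological conclusions, which
require the real data.

## Data preparation rules

`prepare_traits()` applies the study's rules for building one trait value
per species from a multi-study table: drop excluded studies, average the
remaining picogram estimates with equal weight (the source states only
"mean", so no inverse-variance weighting), exclude miniaturized species
(mean SVL below 35 mm — miniaturization shrinks genomes independently of
life history), intersect with the tree's tips, and take natural logs.
Every exclusion is logged with its rule; a tree tip left with no record is
a hard error.  Species names are matched after whitespace/underscore
normalization, the Newick convention.  `mean_edge_consensus()` distills a
sample of same-topology dated trees into one analysis tree by averaging
matched edge lengths; topology conflicts are reported by naming the first
conflicting split rather than silently resolved, since edge averaging
across topologies is not well defined.  Consensus trees are near- but not
exactly ultrametric, hence the relative tolerance (default $10^{-6}$) in
`check_ultrametric()`.

Ancestral regime states are reconstructed by a Fitch-style parsimony pass
with ties broken toward the parent's state — a deliberately simple
stand-in that is always overridable by explicit node assignments
(`internal_overrides`), because the scientifically contested node in this
system is handled by comparing both assignments, not by trusting any
reconstruction.  Borderline taxa (facultative paedomorphs and similar) are
not special-cased: they are whatever the input table codes them as.

## Problem sizes and numerical choices

The shipped analysis and test suite run at sizes chosen to make a full
replication cheap on a laptop: 13-model tables on the 118-tip fixture,
bootstrap intervals at 99–199 replicates, Monte Carlo comparisons at
99–199 simulations per arm, calibration checks on 24–32-tip trees where
the BM1/BMS pair makes each replicate fit nearly free.  Full-scale runs
(500 replicates, as in the original design) are a flag away
(`n_reps`, `n_sims`) and change nothing but wall-clock time and Monte
Carlo error.  Exponential path integrals are computed as
$e^{2\alpha a}\,\mathrm{expm1}(2\alpha(b-a))$ to stay accurate at small
$\alpha$; the OU covariance reduces to the BM one as $\alpha \to 0$ to
within $10^{-6}$ at $\alpha = 10^{-8}$, and likelihoods agree there to
$10^{-4}$.

## Known limitations

* Non-ultrametric trees are not supported (the formulas generalize, but
  behavior is only guaranteed on ultrametric inputs).
* No measurement-error variance on tips.
* Multi-$\alpha$ models are enumeration-only by design.
* The bootstrap uses plain percentile intervals; the percentile convention
  is stated rather than hidden, and bias-corrected variants are not
  implemented.
* `mean_edge_consensus()` handles the same-topology case only.
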