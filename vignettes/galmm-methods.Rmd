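---
title: "Mixed linear models with genetic-algorithm variable selection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed linear models with genetic-algorithm variable selection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(galmm)
```

## The problem

`galmm` models a clustered binary outcome — developed around
intimate-partner-femicide (IPF) risk: did a case of intimate partner
violence end in the woman's death? — as a function of coded risk
indicators, while letting part of the model differ between strata of the
victim's coping strategy: a *disengagement* cluster (G1: negation,
silence, conflict avoidance) and an *engagement* cluster (G2:
help-seeking, denouncing, leaving). The scientific question the model
structure serves is which risk indicators are shared across coping
styles and which are specific to one of them.

## The model

For cluster $G_i$ ($i = 1, \dots, m$, here $m = 2$) with $n_i$ cases:

$$y_i = P_i \beta + Z_i b_i + \epsilon_i,
  \qquad \epsilon_i \sim N(0, \sigma^2 I_{n_i}),
  \qquad b_i \sim N(0, \sigma^2 D),$$

where $P_i$ ($n_i \times p$) holds the fixed-effects features shared by
all clusters, $Z_i$ ($n_i \times z_i$) the cluster-specific
random-effects features (optionally including a cluster intercept
column), and $D$ is a symmetric nonnegative-definite scale matrix for
the random effects. The binary outcome is handled by *0–1 regression*:
the model is fitted as a continuous regression on the 0/1 labels and a
case is classified positive when its fitted score exceeds 0.5 (strictly;
ties go to the negative class).

### Estimation

Estimation alternates closed-form least-squares steps:

1. initialise $\hat\beta = (P^\top P)^{-1} P^\top y$ (OLS);
2. per cluster, $\hat b_i = (Z_i^\top Z_i)^{-1} Z_i^\top (y_i - P_i \hat\beta)$
   and $\hat\epsilon_i = (y_i - P_i\hat\beta) - Z_i \hat b_i$;
3. $\hat\sigma^2 = \sum_i \hat\epsilon_i^\top \hat\epsilon_i / (N - \sum_i z_i)$;
4. $\hat D = \sum_i \hat b_i \hat b_i^\top / (m \hat\sigma^2)
   - \sum_i (Z_i^\top Z_i)^{-1} / m$, symmetrised and eigenvalue-clipped
   at zero (the moment formula can leave the PSD cone);
5. re-estimate $\hat\beta = (P^\top W P)^{-1} P^\top W y$ with
   $W = \mathrm{blockdiag}\{(Z_i \hat D Z_i^\top + I_{n_i})^{-1}\}$,
   computed block-by-block (the $N \times N$ weight matrix is never
   assembled);
6. repeat 2–5 until the largest change in $(\beta, \sigma^2)$, relative
   to $\max(|\text{old}|, 1)$, drops below `tol` (default $10^{-6}$,
   cap 100 iterations; the convergence flag reports what actually
   happened).

Numerical choices: singular normal equations are solved with the
Moore–Penrose pseudoinverse (variable selection can propose collinear
interaction sets, and the fit must not crash mid-search); $\hat\sigma^2$
is floored away from zero before it divides the $D$ formula; a model
with no random columns anywhere collapses to a single OLS solve.

Two open points in the formulation were resolved as follows.
*Shared vs per-cluster $D$*: the pooled moment formula requires one
dimension $q$ for all clusters, but the two clusters' selected random
sets generally differ. `lmm_fit()` pools $D$ when the dimensions agree
and otherwise estimates a per-cluster $D$ (the $m = 1$ case of the same
formula), which is the block-diagonal reading of the model.
*Standard errors*: the estimation scheme defines no SEs; the reported
ones use the WLS covariance $\hat\sigma^2 (P^\top W P)^{-1}$ for fixed
effects and $\hat\sigma^2 (Z_i^\top Z_i)^{-1}$ for random effects — a
reporting convention, stated as such.

## Preprocessing

Three steps, applied in this order by `preprocess()`:

1. **0–1 scaling** per column: $(x - \min)/(\max - \min)$ over observed
   entries; constant columns map to all zeros rather than erroring
   (they carry no information and are simply never selected).
2. **Moving-window median imputation** (`window_length = 100`): each
   missing entry takes the median of observed values within
   $\lfloor w/2 \rfloor$ positions on each side, in dataset row order,
   truncated at the edges; an all-missing window falls back to the
   whole-column median. Whether the original procedure centred or
   trailed its window, and whether it imputed before or after scaling,
   is not determinable; this package scales first and centres the
   window, and records both choices here and in provenance.
3. **Interaction expansion**: the $K$ originals are followed by all
   $\binom{K}{2}$ unordered pairwise products in lexicographic index
   order, named `a:b` — 780 features for the default 39-predictor
   schema. Products of unit-interval values stay in the unit interval.

For held-out data the scaling min/max and imputation medians are learned
on the training part and replayed on the test part (test values are
clipped to $[0,1]$; test gaps take the training column median). This is
standard leakage hygiene; `preprocess_mode = "pooled"` in
`holdout_experiment()` reproduces whole-dataset preprocessing for
fidelity comparisons with analyses that preprocessed before splitting.

## Variable selection

A binary genetic algorithm (`run_ga()`) searches subsets of the expanded
features, minimising the BIC-style fitness

$$f(s) = l \ln(e_s^2) + \lambda\, h \ln(l),$$

with $l$ the run's sample size, $h$ the number of selected features,
$e_s^2$ the residual variance ($\mathrm{SSE}/l$) of the least-squares
fit of the run's target on the selected columns, and $\lambda = 4$.
Two guards keep the fitness well behaved: $e_s^2$ is floored at
$10^{-12}$ so a perfectly explained target stays finite, and subsets
with $h \ge l$ score $+\infty$ — an interpolating fit of $n$ cases by
$\ge n$ columns says nothing about the target, and admitting such
subsets would make interpolation the global optimum of the fitness
(the floored $l\ln e_s^2$ term overwhelms any complexity penalty) while
also proposing random-effects sets larger than their clusters.
Defaults: population 60, 150 generations, 2% per-gene mutation,
single-point crossover with uniformly random pairing. The pieces the
scheme leaves open were fixed as: crossover probability 0.9 per pair;
$(\mu + \lambda)$-style survivor selection (parents and offspring
pooled, best 60 kept), which makes the best-so-far trace monotone;
initial gene density Bernoulli(0.5) by default, with a sparse
alternative (`init_density = 0.02`) recommended — and used by the
hold-out harness — when the candidate pool (780) is wider than the
sample, where half-dense chromosomes give saturated, uninformative
fits.

`select_model()` orchestrates $m + 1$ GA runs: run 1 selects the
fixed-effects set over all $N$ cases with the outcome as target; runs
2..$m{+}1$ select each cluster's random set with that cluster's OLS
residual $y_i - P_i \hat\beta$ as target and an intercept column added
to the candidates (cluster intercepts are eligible only here). The
residual target mirrors the estimation order of the model itself
($\beta$ first, then $b_i$ from the residual). Inside the GA each
candidate is scored by a plain OLS refit rather than the full iterative
mixed fit — refitting the mixed model for every one of the
$\approx 60 \times 150 \times 3$ evaluations would be prohibitive, and
the residual-based orchestration makes OLS the natural surrogate. This
is the package's most consequential design choice and is worth knowing
when comparing selected structures across implementations.

## Evaluation

`holdout_experiment()` repeats (default 30 times): draw a random
unstratified training split of $\lfloor 0.66 N \rfloor$ cases (redrawn
if a class or cluster is absent from training), preprocess, select,
fit, score both parts, and record the confusion matrix, global and
per-class correct-classification rates (CCR), RMSE and $R^2$. Metrics
are aggregated as mean ± SD over repeats, and the best repeat (highest
test CCR, ties broken by test CCR of the positive class — the class the
application cares most about) is kept in full with its coefficient
tables. `report_render()` writes the whole report as JSON plus a
Markdown digest.

## The synthetic generator

The study's case table (491 Spanish penal-sentence cases, 330 non-IPF /
161 IPF, two coping clusters) is not publicly deposited, so
`generate_cases()` emulates its shape: 39 predictors with the study's
codings, per-variable missingness at the reported rates (completely at
random — the simplest mechanism consistent with what is reported), a
latent continuous score computed from a planted coefficient set
(default: the published best-model coefficients, `reference_model()`)
plus Gaussian noise, and a binary outcome obtained by rank-thresholding
the latent score so the positive count is hit exactly (guaranteeing the
study's class balance and making parameter recovery well-posed; an
absolute 0.5-threshold rule is available instead). Ties at the rank
boundary are an explicit error, never silently broken.

Defaults chosen once and documented here: noise SD 0.3 on the latent
scale (commensurate with the reported residual RMSE of the study's
model blocks, 0.25–0.32); equal cluster proportions (no cluster sizes
are reported, and the published socio-demographic margins are too
inconsistent to imply a split); binary prevalences 0.3 (0.5 for the
urban/rural indicator); ordinal levels uniform; sentence durations
zero-inflated exponential (60% zero, mean 12 months). Cluster
assignment is independent of the predictors.

What the generator does *not* emulate: the joint dependence structure
of real case files (predictors are drawn independently), informative
missingness, cluster-dependent predictor distributions, or any
dependence of coping strategy on covariates. Passing tests on this
synthetic data therefore demonstrate that the machinery recovers what
it plants and classifies better than the majority rule under the
study's shape — not that the published real-data performance is
reproduced, which is impossible without the original case files.

The generated latent score is kept as `attr(tab, "latent")`. Parameter
recovery is assessed against it: the rank-thresholded 0/1 outcome is a
censored transform of the score, so fitting the binary label cannot
return the planted coefficients on their original scale, whereas the
latent response makes recovery a well-posed linear problem.

## Problem sizes used by the test suite

The suite fits recovery at $n = 5000$ (noise SD 0.2), where the
worst-case Monte-Carlo coefficient error was pre-verified to sit well
inside the asserted ±0.1 band; GA correctness is checked against
exhaustive enumeration on 5- and 10-candidate instances (31 and 1023
subsets); and the end-to-end hold-out runs 5 repeats with population 30
and 40 generations on a 491-case table, asserting only the property
that mean test CCR beats the majority-class rate (330/491 ≈ 0.672).

## Known limitations

- The GA fitness refits OLS, not the mixed model (see above); selected
  structures can differ from a scheme that scores candidates with the
  full iterative fit.
- The 0–1 regression device produces scores outside $[0, 1]$; they are
  thresholded, not calibrated probabilities.
- Per-cluster $D$ estimation (unequal random-set sizes) departs from
  the strictly shared-$D$ formulation, which is not representable when
  the clusters select different regressors.
- Reported SEs are a convention (WLS/LS covariances at convergence),
  not derived from the scheme's sampling distribution.
- The generator's independence assumptions make its tables easier than
  real case files in some respects (no confounded predictors) and
  harder in others (no redundant signal across correlated indicators).
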