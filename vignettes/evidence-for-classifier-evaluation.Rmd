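---
title: "Evidence, not accuracy: a Bayesian independence test for confusion matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence, not accuracy: a Bayesian independence test for confusion matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfindep)
```

## The problem

In computer-aided diagnosis a trained classifier is judged on a test set by
its confusion matrix: rows are the true diagnostic groups, columns the
predicted ones. Summary metrics — prediction accuracy, MCC, F1, Cohen's
$\kappa$, Youden's $J$ — are functions of the four cell *proportions* only.
Two consequences follow. On unbalanced test sets (many controls, few
patients, the typical situation in diagnosis) a classifier that always
predicts the majority class can score high accuracy while discriminating
nothing. And no standard metric changes when every cell is multiplied by the
same constant, although five times the data plainly constitutes five times
more ground for a claim.

`bfindep` recasts the evaluation as a hypothesis test: are the predicted
labels statistically **dependent** on the true labels ($H_1$), or
independent ($H_0$)? The answer is a Bayes factor, which by construction
scales with the amount of data and does not care about class imbalance.

## Sampling model and priors

The row margins $n_1, n_2$ (examples per true class) are known constants of
the test design — the *one margin fixed* assumption — so each row of the
matrix is a binomial draw $z_i \sim \mathrm{Bin}(n_i, p_i)$, with $z_i$ the
count in a designated reference column (the result is invariant to which
column, a property the test suite asserts).

Under $H_0$ both rows share one probability with a uniform prior,
$p_1 = p_2 = p \sim U(0,1)$. Under $H_1$ the pair $(p_1, p_2)$ gets the
*intrinsic prior*

$$\pi(p_1,p_2 \mid t_1,t_2) = \sum_{i=0}^{t_1}\sum_{j=0}^{t_2}
\binom{t_1}{i}\binom{t_2}{j}
\frac{\Gamma(i{+}j{+}1)\,\Gamma(t_1{+}t_2{-}i{-}j{+}1)}{\Gamma(t_1{+}t_2{+}2)}
\,\mathrm{Beta}(p_1 \mid i{+}1, t_1{-}i{+}1)\,
\mathrm{Beta}(p_2 \mid j{+}1, t_2{-}j{+}1),$$

a proper mixture of Beta products whose mass concentrates around the
diagonal $p_1 = p_2$ as the non-negative integer concentrations $t_1, t_2$
grow. This concentration is what makes the test able to separate $H_0$ from
*close* alternatives instead of wasting prior mass on absurd ones; at
$t_1 = t_2 = 0$ it degenerates to the uniform product. The Bayes factor
$B_{10}(z_1,z_2,t_1,t_2)$ — the ratio of the two marginal likelihoods — has
the closed form shown in `?log_bayes_factor`.

## The conservative minimum and its grid

$B_{10}$ depends on $(t_1, t_2)$, and inference is only trustworthy where it
is reasonably stable across them. The package takes the conservative route:
report $\min B_{10}$ over the admissible grid, so dependence is claimed only
if **every** admissible prior concentration supports it.

The admissible grid is $t_1 \in \{0..n_1\}$, $t_2 \in \{0..n_2\}$: the
intrinsic prior for row $i$ is generated by an imaginary training sample of
$t_i$ observations from that row's binomial, so concentrations beyond the
row's own sample size are not meaningful — and, numerically, letting
$t_i > n_i$ makes the surface keep falling and the minimum mean something
else entirely. This per-row cap is a deliberate design choice of this
package; the reference evidence values below are reproduced only under it.
A `t_max` argument (default the test-set size $m$, so inactive) can cap the
grid further for very large matrices; results then carry a
`truncated_grid` flag because the minimum is over a subset.

Ties in the arg-min are broken lexicographically, smallest $(t_1, t_2)$
first, for determinism. As a stability diagnostic the result records the
grid min, max and spread, with a warning flag when the spread exceeds 2
natural-log units (one evidence-band width); the flag never alters the
reported minimum.

$\log B_{10}$ is natural log throughout — the reference values are only
consistent with base $e$ — and is read off the usual scale: negative
($<0$), bare mention ($[0,1)$), positive ($[1,3)$), strong ($[3,5)$),
decisive ($[5,\infty)$). The printed scale leaves the boundaries'
inclusivity open; bands here are left-closed/right-open so that exactly 5 is
decisive. Posterior odds are `prior_odds * exp(log_b10)` with prior odds
defaulting to 1.

```{r}
cm <- confusion_matrix(matrix(c(80, 10, 0, 10), 2, byrow = TRUE))
min_log_bayes_factor(cm)
```

## Standard metrics and undefined values

All comparison metrics are implemented from the same matrix: PA, TPR / FPR /
specificity, MCC, F1, $\kappa = (PA - rPA)/(1 - rPA)$ with $rPA$ the chance
agreement, and $J = TPR + SPC - 1$. A metric whose defining ratio has a zero
denominator is **undefined**: it is returned as `NA` and serialized as
`null`, never silently zero and never an error, because undefinedness is
itself informative (the always-majority matrix `[[90,0],[10,0]]` has
undefined MCC). One documented edge: for that same matrix Youden's $J$
is sometimes described as undefined, but both rate denominators are nonzero
and the definition evaluates to $J = 0$; the implementation follows the
definition.

TP/TN/FP/FN mapping needs a positive class; the default is row 2 (the
patient class under the conventional control/patient row ordering),
configurable via `positive`. PA, $\kappa$, MCC, $J$ and the Bayes factor do
not depend on the choice; the rates swap and F1 changes.

## The oracle: verifying, not trusting, the closed form

`oracle_log_m0()` / `oracle_log_m1()` recompute both marginal likelihoods by
an independent route — beta-binomial identities: under $H_0$ a single
$\int \mathrm{Bin}(z_1|n_1,p)\mathrm{Bin}(z_2|n_2,p)\,dp$, under $H_1$ the
mixture of per-row $\int \mathrm{Bin}(z|n,p)\mathrm{Beta}(p|a,b)\,dp$
integrals — and `oracle_quad_log_m0()` / `oracle_quad_log_m1()` add a third
route by adaptive numerical quadrature (absolute tolerance $10^{-10}$) of
the raw integrands, so an algebra slip shared by the closed form and the
oracle would still be caught. The acceptance suite checks closed form
against oracle to $10^{-8}$ in log over every case with $n_i \le 6$ and
$t_i \le 4$, and the prior's normalization to $10^{-6}$ for $t_i \le 3$. The
oracle ships in the package so any reported value can be audited at small
scale; its cost is $O((t_1{+}1)(t_2{+}1))$ per point and the quadrature
versions are for small counts only.

## Numerical choices

Binomial coefficients at these sizes (e.g. $\binom{200}{100}$) overflow
doubles, so nothing is ever computed on the natural scale: all factors are
assembled from `lchoose` / `lgamma` / `lbeta`, and the all-positive double
sums are accumulated by log-sum-exp. Arithmetic stays finite for $m$ up to
at least 10,000 (asserted in the suite). Grid minimization is an exact
exhaustive scan — the surface need not be convex in $(t_1,t_2)$, so no
descent shortcut is taken.

## What the simulator emulates

`simulation_scenario()` / `sample_matrix()` draw matrices from exactly the
model the test assumes: fixed margins, independent row binomials, with
$p_1 = p_2$ for null scenarios. The stream is counter-based — each replicate
is seeded by a hash of (seed, scenario index, replicate index) — so
replicates are reproducible independent of execution order.
`run_comparison()` records every metric plus the evidence per replicate and
summarises per scenario; fixed-matrix scenarios let deterministic textbook
cases flow through the same path. Scenario defaults in the bundled
`fig1_cases.json` are the four canonical matrices on 90 controls + 10
patients.

What a green simulation test does **not** establish: real confusion matrices
come from cross-validated classifiers whose folds share training data, so
cells are not exactly independent binomials; the simulator makes no attempt
to model classifier correlation structure, feature data, or fold
aggregation. The Monte-Carlo false-claim rate asserted for a null scenario
(fraction of replicates reaching at least "positive" evidence $\le 0.10$ at
$n_1{=}90, n_2{=}10, p{=}0.8$, 200 replicates, fixed seed) is a frozen
regression value under this idealised model, not a universal guarantee.

## Known limitations

* Binary classification only; the multi-class extension of the Bayes factor
  is not implemented.
* One-margin-fixed sampling only; designs with both margins or only the
  total fixed need a different marginal likelihood.
* Only the uniform prior for $H_0$ is supported.
* Single-point ROC: Youden's $J$ at the classifier's operating point, no
  threshold sweeps.
* The conservative minimum is deliberately pessimistic; when the grid spread
  is large (flagged), no single number summarises the surface well and the
  full grid (returned in the result) deserves a look.
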