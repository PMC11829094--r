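---
title: "Cosine-series logistic regression: model, estimation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cosine-series logistic regression: model, estimation and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fslogit)
```

## The model and its assumptions

`fslogit` models a binary response $Y_i \sim B(1, \pi(x_i))$ whose logit is
an additive, possibly *repeating* function of $p$ continuous predictors:

$$
\operatorname{logit} \pi(x_i)
 = \tfrac{1}{2} a_0
 + \sum_{j=1}^p \Big( b_j x_{ji} + \sum_{k=1}^{K_j} a_{kj} \cos(k x_{ji}) \Big).
$$

Each predictor contributes a linear trend plus $K_j$ cosine harmonics; the
*oscillation parameter* $K_j$ is the per-predictor smoothing/complexity
knob. The assumptions are those of any additive binary GLM — independent
Bernoulli observations, no interactions, complete data, predictors not
collinear — plus the structural assumption that departures from a linear
logit are well described by low-order cosine terms, i.e. the pattern
repeats along the predictor with period commensurate with its scale.

Two parameterization notes:

* **Single half-intercept.** An additive form with a per-predictor
  intercept $\tfrac{1}{2} a_{0j}$ puts $p$ copies of the same constant
  column in the design, which is rank-deficient; the package collapses them
  to one constant-$\tfrac12$ column. The $\tfrac12$ scaling (rather than a
  plain 1) is kept so that the reported $a_0$ matches the conventional
  write-up of this estimator, and the $\tfrac12$/$\tfrac14$ factors appear
  naturally in the intercept rows of the score and Hessian.
* **Raw-scale cosines by default.** `cos(k * x)` is applied to the
  predictor in its native units. For wide-range predictors (percentages,
  currency), `cos(k x)` then oscillates many times across the data; an
  optional `rescale = TRUE` maps each predictor affinely to $[0, \pi]$
  *inside the cosine only* (the linear trend stays raw). The default is
  raw, which is the published form; whether application work rescaled first
  is not documented, so the flag makes both conventions available.

## Estimation

With design matrix $Z$ ($m = 1 + p + \sum_j K_j$ columns), the Bernoulli
log-likelihood is computed in the overflow-safe form
$L(\beta) = \sum_i \{ y_i \eta_i - \ln(1 + e^{\eta_i}) \}$, with score
$g = Z^\top (y - \pi)$ and Hessian $H = -Z^\top W Z$,
$W = \mathrm{diag}(\pi_i(1 - \pi_i))$. $H$ is negative semidefinite
everywhere (canonical link), so Newton–Raphson

$$\beta^{(t+1)} = \beta^{(t)} - H^{-1} g$$

is well behaved near the optimum. Numerical choices, each of which matters
with oscillatory bases:

* **Initialisation** $\beta^{(0)} = 0$: deterministic, inside the concave
  region, and the null model is a sensible starting point for any data.
* **Step-halving** (up to 30 halvings): a full Newton step can overshoot
  when cosine columns make the likelihood surface locally narrow; the
  accepted step is the largest halving that does not decrease $L$, so the
  likelihood trace is monotone by construction (and asserted in tests).
* **Convergence**: elementwise max-norm coefficient change below
  $\varepsilon = 10^{-6}$ (the published threshold), with `max_iter = 100`;
  hitting `max_iter` yields `converged = FALSE`, not an error.
* **Singular Hessian**: one ridge rescue of $10^{-8} I$ is allowed for
  transient ill-conditioning; if the system is singular again the fit
  aborts with an error naming the rank-deficient columns. A silent
  pseudo-inverse would hide collinear cosine columns (e.g. a predictor
  with too few distinct values for its $K_j$).
* **Separation**: if any coefficient exceeds $10^3$ in magnitude, or
  fitted probabilities saturate to within $10^{-10}$ of 0/1 while the
  gradient norm has stopped decreasing, the fit warns about (quasi-)
  complete separation and returns `converged = FALSE`. A single-class
  response is an error up front.
* **Deviance**: data are ungrouped Bernoulli, so the saturated
  log-likelihood is 0 and deviance $= -2 \log L$; $AIC = deviance + 2m$.
  This identity is what ties published deviance and AIC tables together
  and is exposed as `fs_aic()` / `fs_n_params()`.

The binary-logistic baseline (`fs_fit_logistic`) is the same engine on an
intercept-1-plus-linear design; a cosine model with all $K_j = 0$
reproduces it exactly under $a_0 = 2\beta_0$.

## Selecting the oscillation parameters

`fs_select` fits every combination in $\{k_{\min},\dots,k_{\max}\}^p$
(default $1\dots4$; published work caps $k$ at 4) and takes the global
minimum AIC, with ties broken by smaller $\sum_j K_j$ then lexicographic
order — the literature is silent on both the search strategy and
tie-breaking, so the package makes them deterministic and documents them.
Per *level* $K$ the table also reports the cumulative minimum over
combinations with $\max_j K_j \le K$; because the search spaces are nested
this sequence is non-increasing, and a repeated row means the extra
harmonics of that level never help. A greedy mode (one $K_j$ incremented
per step) is available for large $p$ where $k_{\max}^p$ refits are
infeasible; it is a labelled heuristic and can miss the global minimum.
During selection $k_{\min} = 1$ (no predictor reduced to purely linear),
matching how the estimator is used in practice; $K_j = 0$ designs remain
constructible directly.

**A caution on AIC recovery rates.** AIC does not select consistently: a
spurious harmonic improves the deviance by an asymptotic $\chi^2_1$ draw
and is adopted whenever that draw exceeds 2, i.e. with probability
$\approx 0.157$ *per spurious direction, regardless of sample size or
signal strength*. In a $p = 2$, $k_{\max} = 4$ grid around a true $(2,1)$
model there are five spurious directions (chained into eleven competing
supersets), and the product of the corresponding survival probabilities
puts the chance that the exact true combination wins at only roughly 0.6.
The acceptance experiment that demands majority recovery over 20
replicates is therefore genuinely marginal by design: it holds in
expectation but fails for an appreciable fraction of seed sets, and a red
outcome there reflects this property of AIC itself, not an estimation
defect — every miss observed in that experiment selects a *superset* of
the true combination. The accompanying acceptance script reports the
realized recovery count so the behaviour is measurable rather than
asserted.

## Evaluation conventions

* **Cutoff** 0.5 by default. Published confusion tables are consistent
  with a single fixed cutoff.
* **Orientation**: application write-ups are inconsistent about which
  class is "positive", so `fs_classify` reports sensitivity/specificity
  under *both* labelings (`sensitivity`/`specificity` treat class 1 as
  positive; `sensitivity0`/`specificity0` swap). A class absent from the
  data gives `NA` rates, not an error.
* **AUC** is the Mann–Whitney rank form — the probability a random
  positive outranks a random negative, ties counted $\tfrac12$ — which
  equals the trapezoidal area under the empirical ROC (both routes are
  asserted against each other in tests).
* **Press's Q** $= (n - k\,n_{correct})^2 / (n(k-1))$ with $k = 2$ groups,
  referred to $\chi^2_{1}$ at $\alpha = 0.05$ (threshold 3.8415; published
  tables print the truncated 3.8414). `reject_h0` is exactly
  `press_q > chi2_crit`.

## What the synthetic generator does and does not emulate

`fs_simulate` draws predictors independently uniform over per-predictor
ranges (default $[0, 2\pi]$, over which the harmonics complete whole
cycles and the cosine columns are nearly orthogonal — the cleanest regime
for studying the estimator; percentage-like ranges can be configured), and
samples $y_i$ from the exact model above. It is seeded per dataset and
restores the caller's RNG state.

It does **not** emulate correlated or spatially structured predictors,
non-uniform marginals, measurement error, or missingness — so a green
recovery/selection test establishes correctness of the estimator under its
own generative model, not robustness on observational data. The canonical
simulation truth used across tests ($p = 2$, $K = (2,1)$, $a_0 = 0.5$,
$b = (0.6, -0.4)$, amplitudes $1.5, -1.0$ and $1.2$) was chosen once:
amplitudes of order 1 move the success probability across most of (0, 1)
(strong signal relative to Bernoulli noise) while keeping fitted
probabilities off the boundary.

## Known limitations

* Exhaustive selection costs $(k_{\max} - k_{\min} + 1)^p$ refits; for the
  six-predictor case at $k_{\max} = 4$ that is 4096 fits. The greedy mode
  trades optimality for linear cost.
* No standard errors, Wald tables or penalized (Firth) fits; separation is
  detected and reported, not remedied.
* Cosine-only basis (no sine terms or interactions) and grouped-binomial
  responses are out of scope.
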