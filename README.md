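# fslogit

Nonparametric logistic regression with a Fourier (cosine) series basis, for
binary outcomes whose probability rises and falls with a **repeating
pattern** along one or more continuous predictors — e.g. disease status
against age or anthropometric measures, or a development indicator against
district-level percentages. A straight-line logit misses such patterns;
splines need knot placement; a cosine series captures them with a single
complexity knob per predictor.

## The model

For a Bernoulli response \(Y_i \sim B(1, \pi(x_i))\) with \(p\) continuous
predictors, the logit is modelled additively as a linear trend plus \(K_j\)
cosine harmonics per predictor:

$$
\ln\frac{\pi(x_i)}{1-\pi(x_i)}
  = \frac{1}{2}a_0
  + \sum_{j=1}^{p}\Big( b_j x_{ji} + \sum_{k=1}^{K_j} a_{kj}\cos(k x_{ji}) \Big)
$$

The oscillation parameter \(K_j\) controls smoothness: \(K_j = 0\) is plain
logistic regression in \(x_j\); larger \(K_j\) allows faster repeating
structure. Coefficients are estimated by maximum likelihood with analytic
score \(g(\beta) = Z^\top(y - \pi)\) and Hessian
\(H(\beta) = -Z^\top W Z\), \(W = \mathrm{diag}(\pi_i(1-\pi_i))\), iterated
by Newton–Raphson \(\beta^{(t+1)} = \beta^{(t)} - H^{-1}g\) with
step-halving, to a max-norm coefficient change below \(10^{-6}\). The
\((K_1,\dots,K_p)\) combination is chosen by exhaustive minimum-AIC search
(\(AIC = -2\log L + 2m\), \(m = 1 + p + \sum_j K_j\)). Model quality is
compared against a plain binary-logistic baseline by deviance
(\(-2\log L\)), confusion metrics, Mann–Whitney AUC, and Press's Q
\(= (n - 2\,n_{correct})^2/n\) against the \(\chi^2_{1,0.95}\) threshold.

## Worked example

The application data the method was designed for are not publicly
deposited, so the example uses the package's own seeded generator: 800
observations, two predictors uniform on \([0, 2\pi]\), true logit
\(\tfrac12(0.5) + 0.6x_1 + 1.5\cos x_1 - \cos 2x_1 - 0.4x_2 + 1.2\cos x_2\)
(true combination \(K = (2,1)\)).

```r
library(fslogit)
beta <- fs_coef(a0 = 0.5, b = c(0.6, -0.4), a = list(c(1.5, -1.0), 1.2))
d   <- fs_simulate(800, beta, seed = 42)
sel <- fs_select(d$x, d$y, k_max = 3)   # 9 combinations fitted
sel
#> Oscillation-parameter selection (grid search, K in 1..3)
#> Per-level cumulative minimum AIC:
#>  level combo      aic
#>      1   1,1 741.8128
#>      2   2,1 720.3255
#>      3   2,1 720.3255
#> Best combination: (2,1)  AIC = 720.32555
```

The per-level rows give the best AIC among combinations whose largest
\(K_j\) is at most that level; the repeated row at level 3 means the third
harmonic never helps. The winner is the true combination, and its
coefficients sit near the truth:

```r
sel$best_fit
#> Fourier-series logit fit (K = 2,1)
#>   n = 800, parameters = 6, iterations = 6, converged: TRUE
#>   logLik = -354.1628, deviance = 708.3255, AIC = 720.3255
#>        a0        x1 cos(1*x1) cos(2*x1)        x2 cos(1*x2)
#>  1.295772  0.540517  1.526349 -0.653747 -0.503468  1.089348

fs_compare(list(fourier = sel$best_fit,
                logistic = fs_fit_logistic(d$x, d$y)), d$y)
#>     model m deviance      aic accuracy sensitivity specificity    auc press_q
#>   fourier 6 708.3255 720.3255   77.75%      81.33%      72.33% 86.62%  246.42
#>  logistic 3 931.0881 937.0881   70.75%      82.57%      52.83% 74.75%  137.78
#>  reject_h0 converged
#>       TRUE      TRUE
#>       TRUE      TRUE
#> smallest deviance: fourier
#> largest AUC: fourier
```

The cosine model halves the deviance gap to the saturated model and lifts
the AUC from 74.8% to 86.6%: the repeating component of the signal is real
and the linear-logit baseline cannot represent it. Both Press's Q values
exceed the 3.8415 chi-square threshold, so both classifiers beat chance;
sensitivity/specificity are reported for class 1 as "positive" (the
opposite orientation is in the `fs_classify` report as
`sensitivity0`/`specificity0`).

A command-line interface wraps the same workflow
(`exec/fslogit fit|select|evaluate|simulate`, see `?fs_cli`), and
`fs_pipeline()` writes the full selection/comparison report as JSON.

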