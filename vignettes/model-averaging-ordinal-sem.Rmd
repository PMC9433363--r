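---
title: "Frequentist model averaging for ordinal-indicator SEMs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequentist model averaging for ordinal-indicator SEMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Applied structural equation modelling rarely starts from a single model.
A researcher entertains a family of nested candidates — a restrictive
("narrow") model, a rich ("full") model, and models in between — picks one
by a fit index, and then reports confidence intervals as if the winning
model had been fixed in advance.  Because the selection step is random,
those intervals are too short, sometimes drastically so: in our simulation
engine, post-selection coverage of a structural coefficient with nominal
level 95% can fall below 30% when the data drift away from the narrow
model.

`semfma` implements the frequentist alternative: estimate every candidate,
estimate mean-squared-error-optimal weights on the unit simplex, and
average.  The machinery is built for *ordinal* indicators — Likert-type
items analysed through polychoric correlations and least-squares fitting —
where the textbook continuous-data averaging theory is not quite right and
needs corrections that this package supplies.

## Model and estimation pipeline

The latent-response model is the LISREL system

$$x^* = \Lambda_x \xi + \delta_x,\qquad
  y^* = \Lambda_y \eta + \delta_y,\qquad
  \eta = B\eta + \Gamma\xi + \varepsilon,$$

with jointly normal latent responses.  Only discretized versions $x, y$
of $x^*, y^*$ are observed, cut at per-variable thresholds.  Because the
scale of each latent response is lost, its variance is fixed at 1 and the
model-implied covariance $\Sigma(\beta)$ is a *correlation* matrix;
indicator error variances are not free parameters but are derived as one
minus the communality (`model_implied_correlation()` flags a Heywood case
when that quantity goes negative).

Estimation is the standard multi-step procedure:

1. **Thresholds** per variable, as normal quantiles of cumulative category
   proportions (`estimate_thresholds()`).
2. **Polychoric correlations** pairwise, maximizing the contingency-table
   likelihood at fixed thresholds (`fit_polychoric_pair()`), and the
   asymptotic covariance $\hat\Upsilon$ of
   $\sqrt n(\hat\rho - \sigma)$ (`estimate_upsilon()`).
3. **Least-squares fitting** of each candidate model,
   $F_{LS}(\beta) = n(\hat\rho-\sigma(\beta))^\top \hat V
   (\hat\rho-\sigma(\beta))$, with $\hat V$ the identity (ULS), the
   inverse diagonal of $\hat\Upsilon$ (DWLS, the default), or
   $\hat\Upsilon^{-1}$ (WLS).
4. **Weight estimation, averaging, inference, fit assessment**
   (`fma_sem()` runs the whole pipeline).

### Why ordinal data changes the averaging theory

Write $\beta = (\theta, \gamma)$, where $\gamma$ collects the parameters
that candidate models may pin at a null value $\gamma_0$, and let the true
$\gamma$ drift as $\gamma_0 + \delta/\sqrt n$ (the local-misspecification
frame, which keeps the bias and variance of averaged estimators on the
same footing).  The limiting score pieces $M$ (protected directions) and
$N$ (drift directions) have covariance

$$H = D_\sigma^\top V\,\Upsilon\,V D_\sigma,
  \qquad D_\sigma = \partial\sigma/\partial\beta^\top,$$

while the information is $J = D_\sigma^\top V D_\sigma$.  With continuous
data fitted by ML — or with WLS weighting, where $V = \Upsilon^{-1}$ makes
$H = J$ — the limit $M$ is independent of the local-parameter error $D$,
and the classical weight criterion and interval apply.  Under ULS or DWLS,
$H \neq J$ and $\mathrm{cov}(M, D^\top) \neq 0$; `semfma` therefore:

* corrects the risk criterion $Q(c)$ through modified $\Delta_1, \Delta_2$
  built from the $H$-blocks (`build_Q(..., variant = "ordinal")`);
* corrects the bias of $\hat\delta\hat\delta^\top$ by $G H G^\top$ rather
  than $K$ (`estimate_delta_outer()`);
* computes the interval scale $\kappa$ from the full covariance of
  $(\partial\mu_0/\partial\theta^\top)J_{\theta\theta}^{-1}M - WD$,
  including the $\mathrm{cov}(M,D^\top)$ cross terms
  (`kappa_covariance()`).

The uncorrected versions remain available as the `"continuous"` variant —
the comparator called FMAordcont in the simulation engine — precisely so
that the cost of ignoring the correction can be measured: in our cells its
interval coverage runs around 0.83–0.86 instead of 0.92–0.95.

Every population quantity ($J$, $H$, $K$, $K^{(s)}$, $W$, $G$, $\kappa$)
is estimated by plugging in the full-model solution; the full model is the
only candidate that estimates everything consistently under the drift.

### Weights, intervals, fit statistics

The criterion $Q(c)$ is a convex quadratic on the unit simplex; it is
minimized exactly by `quadprog` after symmetrizing and flooring the
eigenvalues of the quadratic part at zero (a projected-gradient fallback
covers solver failure; ties between equally risky weight vectors are
left to the solver).  The averaged estimate, the shrunken local parameter
$\tilde\delta = \sum_s \hat c_s \hat K^{(s)} \hat K^{-1}\hat\delta$, and
the de-shrinking adjustment $\hat u = \hat W(\hat\delta - \tilde\delta)$
feed the interval
$[\bar\mu_i - \hat u_i/\sqrt n \pm z_{1-\alpha/2}\hat\kappa_i/\sqrt n]$,
which is asymptotically equivalent to the full-model interval — a
property the test suite checks by verifying that $\sqrt n$ times the
centre gap stays bounded as $n$ grows.

Global fit of the averaged solution is assessed (for focus $\mu = \beta$)
by a residual quadratic form in
$\sqrt n(\hat\rho - \bar\sigma) + D_\sigma \hat u$, calibrated by
Satorra–Bentler moment corrections: the mean-scaled statistic referred to
$\chi^2_r$ with $r$ = number of unique correlations minus number of
parameters, and the mean-and-variance adjusted statistic with fractional
degrees of freedom $[\mathrm{tr}\,\Xi]^2/\mathrm{tr}\,\Xi^2$.  The
scaling matrix is implemented as a matrix
$\Xi = (I - D_\sigma L V)^\top V (I - D_\sigma L V)\,\hat\Upsilon$ (a
trace would not support $\mathrm{tr}\,\Xi^2$); when the focus is all of
$\beta$, $L = J_{full}^{-1}D_\sigma^\top$ and $\Xi$ coincides with the
classical single-model scaling matrix, which is why the averaged and
full-model scaled statistics behave almost identically.

The model-selection comparator uses a sample-corrected robust RMSEA,
$\hat\varepsilon = \sqrt{\max(0, (T - \mathrm{tr}\,\Xi_s)/(n r_s))}$ with
each candidate's own scaling matrix, walking the family from narrow to
full and keeping the first candidate with
$\hat\varepsilon \le 0.05$ — the conventional close-fit bar.

## Numerical choices

* **Bivariate normal cells.**  Rectangle probabilities are computed in
  C++ by composite Gauss–Legendre quadrature over row strips (10 nodes
  per panel, panels no wider than 1.0, narrowed as $|\rho| \to 1$);
  agreement with an independent CDF implementation is ~1e-16 in the
  tested range and frozen oracle values are asserted in the tests.  Cell
  probabilities below 1e-30 are floored inside log-likelihoods, which is
  what keeps extreme-asymmetry thresholds (top category probability
  0.03) numerically safe.
* **Pairwise optimizer.**  The correlation solves the profile-score
  equation by a safeguarded Illinois method, bracketed from the Pearson
  correlation of the raw codes and expanded only on demand (tolerance
  1e-9; estimates at |rho| > 0.999 are flagged as boundary cases).
* **$\hat\Upsilon$.**  Influence-function (sandwich) estimator of the
  two-step pseudo-ML: the correlation score of each pair is corrected for
  threshold estimation error through the chain
  $\hat\tau_k = \Phi^{-1}(\hat F_k)$, and $\hat\Upsilon$ is the sample
  covariance of the stacked per-observation contributions.  Among the
  estimators in circulation this one is fast (one pass over the data),
  automatically positive semidefinite, and valid under the drift — the
  property the package's Monte Carlo contract tests verify directly.
* **Candidate fitting.**  Levenberg–Marquardt on the weighted residual
  with the analytic Jacobian of $\sigma(\beta)$ (exact for this model
  class: the derived error variances are diagonal, so the unit-diagonal
  constraint does not leak into off-diagonal derivatives), followed by
  damped Gauss–Newton polishing until the gradient norm of $F_{LS}/n$
  falls below 1e-6; candidates are fitted narrow to full, each warm
  started from the previous solution.  Solutions are *admissible* when
  converged with positive semidefinite latent covariances and
  nonnegative derived error variances; fits are unconstrained, so
  Heywood cases can and do occur and are screened exactly like
  non-convergences.
* **Degenerate categories.**  A category empty in a given sample is
  collapsed into its lower neighbour for that dataset and flagged; the
  replication remains admissible.

## The synthetic-data generator

`simulation_model()` and `population_parameters()` encode the four-factor
study population used throughout the tests: three indicators per factor
with loadings (1, 0.95, 0.9); exogenous covariance matrix with variances
0.7 and covariance 0.3; protected structural effects 0.5 and 0.45; and a
drift block $\gamma = (g_{12}, g_{21}, b_{21})$ moving as
$\delta/\sqrt n \cdot (1, 0.75, 0.5)$ with $\delta = \sqrt{150}\,\zeta$
(the "standard" framework instead fixes $\gamma$ at
$\zeta\cdot(1, 0.75, 0.5)$; the two coincide at $n = 150$).  Structural
residual variances solve a reliability constraint — endogenous factor
variances are held at their narrow-truth values 0.625 and 0.64175, giving
residual variances (0.45, 0.5) at $\zeta = 0$ — so that discretization
thresholds keep the same meaning across effect sizes.  Two threshold
regimes are built in: moderate asymmetry (category probabilities 0.24,
0.41, 0.22, 0.10, 0.03) and extreme asymmetry (0.52, 0.15, 0.13, 0.11,
0.09), with exact normal-quantile cut points.

What the generator deliberately does *not* emulate: non-normal latent
responses, missing data, unequal category counts across variables, and
multi-group structure.  A green simulation suite therefore says the
machinery is internally correct under the latent-normality assumption
that also underlies polychoric estimation — not that real Likert data
satisfy that assumption.

## Problem sizes in the shipped tests and script

The test suite reproduces the reference coverage and rejection cells with
1000 replications at $n = 150$ and 500 replications at $n = 600$
(tolerances ±0.025 and ±0.035, about three binomial standard errors), the
unbiasedness contracts at 2000 replications, and the large-sample
equivalence checks at $n$ up to 20000.  `scripts/acceptance.R` recomputes
the headline quantities at 600/400 replications per cell, sizes chosen so
a full run stays within a coffee break on a single core; Monte Carlo
standard errors at those sizes are ~0.01–0.02 and are reported alongside
every rate by `summarize_simulation()`.

## Known limitations

* The averaged-model fit statistic requires the focus parameter to be the
  whole of $\beta$; for a narrower focus the averaged estimate and
  intervals are still valid but `t_fma()` refuses to compute.
* $\hat\Upsilon$ grows as the fourth power of the number of indicators in
  memory terms (stacked pairs squared); the implementation is comfortable
  for the tens-of-indicators range typical of applications, not for
  hundreds.
* Thresholds are estimated but never structured (no threshold equality
  constraints across variables), error covariances between x- and y-side
  indicators are representable but exercised only by structural-zero
  checks, and ordinal-as-continuous analysis (Pearson correlations with
  ML machinery) is out of scope by design.
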