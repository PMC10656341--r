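---
title: "Two-step estimation of multilevel latent class models with covariates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step estimation of multilevel latent class models with covariates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlcastep)
```

## The model

`mlcastep` fits latent class models for hierarchical binary data:
individuals $i = 1, \dots, n_j$ nested in groups $j = 1, \dots, J$, each
individual answering $H$ binary items $Y_{ijh}$. A low-level latent class
$X_{ij} \in \{1, \dots, T\}$ explains the associations among an
individual's items through class-conditional response probabilities
$\phi_{h|t} = P(Y_{ijh} = 1 \mid X_{ij} = t)$ (the $H \times T$ matrix
$\Phi$), with items conditionally independent given the class. A
high-level latent class $W_j \in \{1, \dots, M\}$ with probabilities
$\omega_m$ acts as a categorical random effect: the $X_{ij}$ of a group
are conditionally independent given $W_j$, with probabilities
$\pi_{t|m} = P(X_{ij} = t \mid W_j = m)$ (the $M \times T$ matrix $\Pi$).
The group-level likelihood contribution of the unconditional
(measurement) model is

$$P(\mathbf{Y}_j) \;=\; \sum_{m=1}^{M} \omega_m \prod_{i=1}^{n_j}
  \sum_{t=1}^{T} \pi_{t|m} \prod_{h=1}^{H}
  \phi_{h|t}^{\,Y_{ijh}} (1 - \phi_{h|t})^{1 - Y_{ijh}}.$$

Covariates $\mathbf{Z}_{ij}$ (with a leading 1) enter a multinomial
logistic structural model for the low-level class, with coefficients
specific to the high-level class:

$$P(X_{ij} = t \mid W_j = m, \mathbf{Z}_{ij}) \;=\;
  \frac{\exp(\gamma_{tm}' \mathbf{Z}_{ij})}
       {\sum_{s=1}^{T} \exp(\gamma_{sm}' \mathbf{Z}_{ij})},
  \qquad \gamma_{1m} \equiv 0,$$

so class 1 is the reference category. The structural parameter vector is
$\theta_2 = (\mathrm{vec}(\Gamma)', \omega')'$; the measurement parameters
are $\theta_1 = \mathrm{vec}(\Phi)$. No covariates are modelled for $W_j$
itself: the high-level class plays the role of a random effect accounting
for within-group dependence, and its free parameters are the $M - 1$
log-odds $\log(\omega_m / \omega_1)$.

The model is generically identified when each item separates all
low-level classes, $\Pi$ has full row rank $M$, $M \le T$, and every group
has at least three members; `check_identification()` reports on these
(sufficient, not necessary) conditions without ever blocking a fit.

## The two-step estimator

The simultaneous (one-step) maximum likelihood estimator maximizes the
full-model likelihood over $(\theta_1, \theta_2)$ jointly. It is the
statistical benchmark but is computationally heavy and must be rerun
whenever covariates change. The two-step estimator instead:

1. **Step 1** fits the unconditional multilevel model by EM, yielding
   $(\hat\omega, \hat\Pi, \hat\Phi)$; only $\hat\theta_1 = \hat\Phi$ is
   carried forward.
2. **Step 2** maximizes the pseudo log-likelihood of the covariate model
   over $\theta_2$ with $\Phi$ frozen at $\hat\Phi$.

Both steps use an upward–downward E-step: the group posteriors
$\hat u_{jm} = P(W_j = m \mid \mathbf{Y}_j)$ are computed first, then the
unit-level conditionals
$\hat q_{ijt|m} = P(X_{ij} = t \mid W_j = m, \mathbf{Y}_{ij})$, and the
joint posteriors are $\hat v_{ijtm} = \hat u_{jm}\hat q_{ijt|m}$. The
cost is linear in $\sum_j n_j$; a naive E-step over all $M T^{n_j}$
latent configurations would be infeasible for realistic group sizes. The
M-step of step 1 is closed-form (posterior-weighted relative
frequencies). In step 2 the $\Gamma$ update solves weighted
multinomial-logit score equations; because the weights
$\hat u_{jm}\hat q_{ijt|m}$ factor by high-level class, this is $M$
independent weighted multinomial logistic regressions, each solved by
Newton–Raphson with step halving (at most 50 inner iterations, gradient
sup-norm below $10^{-6}$ at the solution, coefficients capped at $\pm 20$
on the logit scale to guard against quasi-separation).

Label switching between the steps is prevented by construction: step 2
starts from $\omega = \hat\omega$, intercepts
$\gamma_{0tm} = \log(\hat\pi_{t|m} / \hat\pi_{1|m})$ and zero slopes, so
its EM begins exactly at the step-1 optimum of the equivalent
intercept-only model, and a single start suffices.

The package also implements the older **two-stage** estimator for
comparison (single-level fit for an initial $\Phi$; multilevel EM with
$\Phi$ fixed for $(\omega, \Pi)$; multilevel EM with $(\omega, \Pi)$
fixed for the final $\Phi$; then the same structural step). Its
multi-sub-step conditioning makes a corrected covariance impractical, so
only naive standard errors are reported for it.

## Corrected standard errors

Treating $\hat\Phi$ as known in step 2 understates the variability of
$\hat\theta_2$. Pseudo-maximum-likelihood theory gives

$$\sqrt{N}(\hat\theta_2 - \theta_2) \;\xrightarrow{d}\;
  N(0, V), \qquad
  V \;=\; \underbrace{\mathcal{I}_{22}^{-1}}_{V_2}
  \;+\; \underbrace{\mathcal{I}_{22}^{-1}\,\mathcal{I}_{21}\,
  \Sigma_{11}\,\mathcal{I}_{21}'\,\mathcal{I}_{22}^{-1}}_{V_1},$$

where $\mathcal{I}_{22}$ and $\mathcal{I}_{21}$ are blocks of the Fisher
information at $(\hat\theta_1, \hat\theta_2)$ and $\Sigma_{11}$ is the
asymptotic covariance of $\sqrt{N}(\hat\theta_1 - \theta_1)$. $V_1$ is
positive semidefinite, so corrected standard errors
$\sqrt{\mathrm{diag}(V)/N}$ always dominate the naive
$\sqrt{\mathrm{diag}(V_2)/N}$ coordinate-wise.

All blocks are estimated by outer products of analytic score
contributions obtained through the Oakes identity: the derivative of the
observed log-likelihood equals the derivative of the expected
complete-data log-likelihood at fixed posteriors, so every score is a
simple posterior-weighted residual available from the EM output
($\hat v_{ijtm} - \hat u_{jm} p_{ijt|m}$ times the covariate for
$\Gamma$; $\hat u_{jm} - \omega_m$ for the $\omega$ log-odds;
$\bar v_{ijt}(Y_{ijh} - \phi_{h|t}) / \{\phi_{h|t}(1-\phi_{h|t})\}$ for
$\Phi$). $\Sigma_{11}$ is the $\Phi$-block of the inverse outer-product
information of the full step-1 parameter vector (free coordinates of
$\omega$ and of each row of $\Pi$ on the log-ratio scale, plus
$\mathrm{vec}(\Phi)$), so that the matrix is full rank. The test suite
verifies every analytic score against central finite differences of the
per-group log-likelihood contributions.

**Score aggregation.** The outer products can be formed from per-unit
score rows, from rows summed within groups, or block-wise
(`score_aggregate`). Groups are the independent replicates, so the group
form is always theoretically valid; but inverting an outer product of
$d$ parameters built from $J$ rows carries an inverse-Wishart-type
small-sample bias of order $J/(J - d - 1)$, which is severe for
$\Sigma_{11}$ (a step-1 parameter vector of dimension
$M-1 + M(T-1) + HT$, e.g. 35 for the simulation design here, against
$J = 100$ groups or fewer); in calibration runs it inflated corrected
standard errors 25–40% above Monte Carlo standard deviations. Pure
per-unit rows avoid that bias and are accurate for the unit-level
parameter blocks ($\Gamma$, $\Phi$), whose within-group score
correlations are weak — but they destroy the information of the purely
group-level $\omega$ log-odds, whose per-unit score fragments are
perfectly correlated within a group. The default (`"hybrid"`) therefore
assembles $\mathcal{I}_{22}$ and $\mathcal{I}_{21}$ block-wise at the
finest valid level: unit rows for $\Gamma \times \Gamma$,
$\Gamma \times \Phi$ and $\Phi \times \Phi$, group rows for every
block involving $\omega$. $\Sigma_{11}$ always uses unit rows: mixing
levels inside the large step-1 information is not a Gram construction
and can go indefinite at small $J$, whereas the unit-row Gram matrix is
always positive semidefinite. In 60-replicate calibration runs of the
most favorable design cell this puts the corrected standard error of
every slope and intercept within about 12% of its Monte Carlo standard
deviation, and that of the high-class log-odds within about 18%.

## Initialization and numerical choices

EM for mixture models finds local optima, so starting values matter,
especially for a stepwise estimator whose later steps condition on the
first. Step 1 uses a hierarchical K-modes initialization:

1. K-modes clustering (Huang-style: seeded starts from distinct observed
   rows, best of `kmodes_n_init = 10` runs by total Hamming cost, mode
   ties broken toward 0) with $K = M$; each group receives its
   within-group majority label, giving $\tilde W_j$ and, after sorting
   classes by decreasing size, $\omega^{(0)}$.
2. A pooled single-level $T$-class latent class fit (itself K-modes
   initialized) gives $\Phi^{(0)}$; cross-tabulating its MAP assignments
   against $\tilde W_j$ and row-normalizing (adding 0.5 to every cell
   when any cell is empty) gives $\Pi^{(0)}$.

`mlca()` adds four seeded logit-scale perturbations of this start by
default (`n_starts = 5`) and keeps the best solution by log-likelihood.
Low-level classes are then put in canonical order by decreasing mean
response probability $\bar\phi_{\cdot|t}$ — the arithmetic mean is used
rather than the probability of scoring 1 on *all* items, which can
underflow and become noise-dominated with many or rare items — and
high-level classes by decreasing $\hat\omega_m$.

Other numerical choices: all mixture sums are computed in the log domain
with max subtraction (a literal product over $n_j \ge 50$ units
underflows); probabilities are clipped to $[10^{-10}, 1 - 10^{-10}]$
before logs and simplex constraints re-normalized after clipping; EM
stops when $|\ell_k - \ell_{k-1}| / (|\ell_{k-1}| + 1) < 10^{-8}$
(`tol`), with `max_iter = 1000`; an empty class in an M-step is clipped
to the boundary tolerance with a warning rather than triggering a
restart, keeping runs deterministic. Per-unit item log-densities are
cached once per E-step and reused in both the group posterior and the
unit-level conditional.

## Class enumeration

`mlca_select()` chooses $(T, M)$ for the unconditional model, either
over the full grid or hierarchically: single-level fits choose $T$; with
$T$ fixed, multilevel fits choose $M$; with $M$ fixed, $T$ is
re-checked. Fits are compared by AIC, BIC ($-2\ell + k \log N$) or the
group-level BIC ($-2\ell + k \log J$), where the parameter count is
$k = HT + M(T-1) + (M-1)$ without covariates. By default the group-level
BIC is used when comparing values of $M$ (information about group-level
structure accrues with $J$, not $N$) and the standard BIC for $T$;
passing a single `criterion` overrides both. Class separation is
summarized by the entropy-based $R^2$,
$1 - \overline{H(\text{posterior})} / H(\text{marginal})$, at the unit
level for $X$ and the group level for $W$; it is 1 exactly when
posteriors are degenerate and is defined as 1 when the marginal puts all
mass on one class.

## The simulation engine

`mlca_sim_design()` encodes the crossed Monte Carlo design used to
evaluate the estimators: $T = 3$, $M = 2$, $H = 10$; group sizes
$n_j \in \{100, 500\}$; numbers of groups $J \in \{30, 50, 100\}$;
low-level separation through response probabilities
$\phi \in \{0.7, 0.8, 0.9\}$ for the most likely response (class 1
scores 1 on all items, class 2 on the last five only, class 3 on none);
high-level separation through structural intercepts
$(-0.85, -1.38 \mid 0.85, 1.38)$ (moderate) or
$(-1.38, -2.07 \mid 1.38, 2.07)$ (large); one standard-normal covariate
with slopes $(-0.25, -0.25)$ in high-level class 1 and $(0.25, 0.25)$ in
class 2. The high-level class probabilities are set to $(0.5, 0.5)$ and
the covariate is redrawn independently in every replicate; both choices
are recorded in the generator's `truth` output. The generator's item
marginals and class proportions are verified in the tests against
Gauss–Hermite integration of the logit over the covariate.

`mlca_sim_study()` runs replicates, fits the requested estimators, and
aggregates per-coefficient bias, Monte Carlo SD, relative SD with
respect to the one-step estimator, and 95% confidence-interval coverage
(estimate $\pm 1.96 \cdot$ SE; corrected SEs for the two-step estimator,
full-information SEs for one-step, naive for two-stage). Because the
generating high-level classes are equally sized, the fitted high-level
labels are aligned to the truth by matching structural intercepts over
the $M!$ permutations before metrics are computed; low-level labels are
already canonical. The study driver's default control uses the single
hierarchical initialization without extra perturbed starts: the
initialization is designed to make one start sufficient, and the driver
fits thousands of models.

What the generator emulates — and what it does not: it produces exactly
conditionally independent binary items, a single normal covariate with
homogeneous within-class effects, equally sized high-level classes and
balanced groups. Real data bring measurement non-invariance, local
dependence, missing values and informative group sizes, none of which
are represented; passing tests therefore demonstrate correctness of the
estimators under the model, not robustness to its violations.

## Problem sizes used in the checks

The packaged checks run the study at desk scale, chosen to keep the full
suite fast while leaving Monte Carlo error well below the tolerances
asserted: parameter recovery and coverage use the most favorable design
cell ($\phi = 0.9$, large high-level separation, $n_j = 500$, $J = 100$)
with 100 replicates; standard-error calibration uses 200 replicates of
the same cell; class enumeration uses 20 replicates at $n_j = 100$,
$J = 50$. With 100 replicates the Monte Carlo standard error of a
coverage estimate near 95% is about 2.2 percentage points, and the
relative error of a Monte Carlo SD is about 7%.

## Known limitations

- Items must be strictly binary with no missing values; polytomous items
  and NA handling are out of scope.
- No covariates for the high-level class $W_j$ (it is a pure random
  effect here), and no sampling weights or complex-survey variance.
- Standard errors are outer-product (expected-information) estimates;
  Hessian- and sandwich-based alternatives are not implemented.
- The classical three-step procedure (assign-then-regress) is
  deliberately absent; it is known to be biased.

## A worked example

```{r example, eval = FALSE}
design <- mlca_sim_design(36)      # phi = 0.9, large separation
sim <- mlca_sim_data(design, n_j = 100, J = 50, seed = 1)
fit <- mlca(cbind(y1, y2, y3, y4, y5, y6, y7, y8, y9, y10) ~ z,
            data = sim$data, group = "group",
            nclass = 3, nclass_high = 2, method = "twostep")
summary(fit)           # coefficients with naive and corrected SEs
plot(fit)              # class-conditional response profiles
predict(fit, "high")   # group posteriors
```
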