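---
title: "Methods: a multilevel probit choice model with a latent living-conditions covariate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a multilevel probit choice model with a latent living-conditions covariate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlcprobit)
```

## The model

`hlcprobit` estimates, in a single step, a binary choice model in which one
covariate is not observed directly but measured by a battery of binary
indicators. The motivating application is household survey analysis: a
woman's contraceptive adoption (or any binary outcome) is modelled as a
function of observed covariates and of her household's material living
conditions — a latent "wealth" construct indicated by asset ownership and
dwelling characteristics. Estimating measurement and regression jointly
avoids the bias that two-step score-then-regress workflows introduce.

The model has three blocks, for person $i$ in cluster (primary sampling
unit) $j$:

**Structural (choice) block.** A latent response
$$Y^*_{ij} = \mathbf{x}_{ij}'\boldsymbol\beta + \gamma_1 z_{ij} + \gamma_2 z_{ij}^2 + u_j + \varepsilon_{ij},
\qquad \varepsilon_{ij} \sim N(0, 1),$$
with $Y_{ij} = 1$ exactly when $Y^*_{ij} > \tau$. The threshold $\tau$
replaces the intercept, the residual variance is fixed at 1 (probit
identification), and $u_j \sim N(0, \sigma_u^2)$ is a cluster random
intercept capturing place-of-residence effects. The latent covariate enters
with a linear and a quadratic term so that non-monotone wealth effects are
testable; the share of latent-response variance attributable to clusters is
the intraclass correlation $\mathrm{ICC} = \sigma_u^2 / (1 + \sigma_u^2)$.

**Measurement block.** The living-conditions score $z_{ij}$ is indicated by
$K$ binary items through a normal-ogive (2-parameter) item response model in
its factor-analytic parameterization,
$$P(v_{ijk} = 1 \mid z_{ij}) = F(\lambda_k z_{ij} - \kappa_k),$$
with $F$ the standard normal CDF by default (a logistic link is available
via `item_link`). The item's *discrimination* is the loading $\lambda_k$ and
its *difficulty* is the ratio $\kappa_k / \lambda_k$ — the latent level at
which endorsement probability is one half, i.e. how rare the asset is.
Items are conditionally independent given $z$.

**Concomitant block.** The latent score is allowed to shift with context:
$z_{ij} \sim N(\boldsymbol\theta'\mathbf{w}_{ij},\, 1)$. The intercept is
zero and the variance fixed at one, so the model stays identified and each
slope $\theta_l$ reads as the shift (in latent SD units) from the reference
category — in the motivating application, a single urban/rural indicator.

The outcome link is probit throughout; we default the item link to probit
as well so the difficulty/discrimination transforms and the closed-form
prevalence checks are internally consistent (classical ML IRT software
often defaults to the logistic; that choice is available but not default).

## Estimation

The marginal likelihood of cluster $j$ integrates both latent quantities:
$$L_j = \int \phi(u; 0, \sigma_u^2) \prod_i
\left[ \int \phi(z; \boldsymbol\theta'\mathbf{w}_{ij}, 1)\,
\textstyle\prod_k P(v_{ijk}\mid z)\; P(y_{ij}\mid \mathbf{x}_{ij}, z, u)\, dz
\right]^{w_{ij}} du,$$
where $w_{ij}$ are household sampling weights normalized to sum to the
sample size and entering as frequency-style exponents; the whole person
contribution (items and outcome jointly) is weighted. Missing items and
missing outcomes simply drop out of the product (missing at random given
the latent score).

Both integrals use Gauss–Hermite quadrature standardized to the latent
priors: the inner rule is centred at $\boldsymbol\theta'\mathbf{w}_{ij}$
with unit scale (the prior variance is fixed at 1, so the prior is already
a natural standardization), the outer rule at 0 with scale $\sigma_u$.
Defaults are 15 nodes per dimension. We verified this choice two ways
rather than by mode-adaptive rescaling: the suite checks that the cluster
log-likelihood matches dense-grid 2-D trapezoid integration to $10^{-6}$
relative on toy clusters, and that doubling the node counts (21 vs 41)
changes the log-likelihood by less than $10^{-4}$ relative at simulation
scale. Prior-standardized rules are accurate here because the inner
posterior cannot be narrower than the information from at most $K$ binary
items allows, and the outer prior SD is modest for realistic
$\sigma_u^2$; mode-adaptive rescaling would pay off mainly for very large
clusters or many more informative indicators.

The log-likelihood and its gradient are computed analytically in compiled
code (the gradient via posterior node weights, the standard marginal-ML
identity), with all products accumulated in log space. Optimization is a
two-stage quasi-Newton on an unconstrained scale ($\sigma_u$ enters as
$\log\sigma_u$): an L-BFGS-B pass covers the distance cheaply and an
`nlminb` pass polishes the gradient. A fit is flagged converged when the
scaled gradient norm $\max_k |g_k| / \max(1, |\ell|)$ falls below `gtol`
(default $10^{-6}$); the relative scaling keeps the criterion meaningful
across sample sizes. `hlc_control(polish = FALSE)` skips the polishing
stage, which large simulation studies that only need likelihood values
(e.g. likelihood-ratio replicates) can afford.

Starting values are deterministic: each item gets a univariate probit of
its responses on a first-principal-component proxy score, the structural
block a plain probit including the proxy and its square, concomitant slopes
start at zero and $\sigma_u^2$ at 0.1. The likelihood is invariant to
jointly flipping the sign of all loadings, slopes and $\gamma_1$; we
identify the sign by requiring the first item's loading to be positive and
flip the whole solution post hoc if needed. Items observed as all-zero or
all-one carry no information about $z$ and are dropped with a warning
(configurable to an error).

**Standard errors.** The sandwich estimator $A^{-1} B A^{-1}$ uses the
observed information $A$ of the weighted log-likelihood (finite differences
of the analytic gradient) and the outer product $B$ of cluster-level
weighted score vectors, so the robust SEs respect both the weighting and
the PSU clustering; naive inverse-information SEs are reported alongside.
A singular information matrix falls back to a pseudo-inverse with a
warning. The variance is mapped to the natural scale ($\sigma_u^2$) by the
delta method.

**The joint latent-effect test.** `lr_test_latent()` tests
$H_0\!: \gamma_1 = \gamma_2 = 0$ by refitting the model with the latent
effect excluded — the measurement and concomitant blocks are re-estimated
under the null, which is the more conservative convention — and referring
$2(\ell_1 - \ell_0)$ to $\chi^2_2$. Under informative weights this
unadjusted statistic is approximate (no Satterthwaite-type correction is
applied); the size simulation in the test suite therefore runs under equal
weights, where the reference distribution is exact asymptotically. If the
statistic comes out negative beyond numerical tolerance the full model is
refitted from the restricted solution before the test errors out.

## Scoring and external validation

`eb_scores()` returns empirical-Bayes (posterior mean) living-conditions
scores with posterior SDs, computed by quadrature from the items and the
concomitant prior. By default the outcome is *excluded* from the
conditioning set: the scores are then a standalone wealth index that can be
aggregated or compared externally without feedback from the dependent
variable — reusing an outcome-conditioned score in another model would
smuggle the first outcome into the second. `include_outcome = TRUE` is
available for diagnostics; it conditions on the person's own outcome and
integrates the cluster intercept over its prior rather than conditioning
on the whole cluster, a deliberate simplification that keeps scoring
per-person.

`cluster_effects()` returns shrinkage estimates (posterior means) of the
cluster intercepts from the full nested quadrature; they are exactly zero
when $\sigma_u^2 = 0$. `aggregate_scores()` produces weighted group means,
SDs and a dense ranking (rank 1 = highest), and `external_validation()`
correlates group means with an external indicator by Pearson (on values)
and Spearman (on ranks, average ranks for ties). The packaged
`state_validation_table()` carries a 29-state table of net state domestic
product per capita alongside weighted mean living-conditions scores, so the
validation arithmetic is reproducible without any data access; recomputing
from it gives Pearson 0.794 and Spearman 0.853 at the printed precision.
All matched groups enter the correlations; no outlier states are excluded.

## The synthetic-data generator

Real applications of this model use registration-gated household survey
data, so the package ships a generator, `simulate_hlc_data()`, that draws
from exactly the process the model assumes: cluster intercepts
$u_j \sim N(0, \sigma_u^2)$; cluster-level urban status (residence is a
characteristic of the sampling cluster) with urban share `p_urban`; latent
scores $z \sim N(\theta\,\mathrm{urban}, 1)$; items from the normal-ogive
model; outcomes from the probit structural equation. Weights are i.i.d.
lognormal with $\sigma_{\log} = 0.25$, normalized — enough spread to
exercise the weighting code without claiming any particular survey design.

`default_paper_scenario()` is the reference configuration: the twelve
published asset/dwelling item parameter pairs, urban shift $\theta = 1.437$
with urban share 0.31 (roughly India's urban population share in the
survey period), latent effects $(\gamma_1, \gamma_2) = (0.202, -0.006)$ and
$\sigma_u^2 = 0.230$. The fixed-effect design is deliberately compact —
one Bernoulli(0.5) covariate with $\beta_1 = 0.3$ and one standard normal
covariate with $\beta_2 = 0.15$ — because parameter-recovery studies need
small, well-conditioned designs; the published threshold belongs to a much
richer covariate set and would push the outcome prevalence to nearly zero
here, so the scenario instead uses $\tau = 0$, which reproduces the
published outcome prevalence of about 58%. The generator emulates the
*statistical structure* of such surveys, not their sampling design: there
is no stratification, no two-stage selection, no non-response. Passing
recovery tests on these data therefore demonstrates correctness of the
estimator under the model's own assumptions, not robustness to the
misspecifications real survey data add.

Default problem sizes in the shipped studies were chosen for a single CPU:
recovery uses 500 clusters of 10 with all 12 items over 20 seeds at reduced
(15, 9) quadrature; the LR size study uses 200 replicates of 100 clusters
of 10 with a 6-item battery. Six items is also a deliberate floor for
small samples: with 4 items and a few hundred persons the profile
likelihood of a loading can go flat (the classic Heywood-type ridge), and
estimates on such ridges are unstable even though the fit is valid.

## Numerical choices and limitations

* All likelihood products are accumulated in log space; a non-finite
  cluster likelihood raises immediately rather than propagating silently.
* $\log\sigma_u$ is box-constrained to $[\log 10^{-4}, \log 50]$; at the
  lower bound the model is numerically single-level and the
  $\sigma_u$-score vanishes, so boundary fits still flag convergence
  correctly.
* Response probabilities returned to users are clamped to the open unit
  interval so downstream logs never overflow.
* Ties in Spearman rankings use average ranks; group ranking in
  `aggregate_scores()` is dense (1 = highest weighted mean).
* Quadratic continuous covariates (e.g. age) are centred at their sample
  mean before squaring (configurable constant) for conditioning; the
  latent quadratic term needs no centring since the latent scale is fixed.
* Not covered by design: multinomial outcomes, random slopes, differential
  item functioning (concomitants shift only the latent mean, never item
  parameters), three-level designs, polytomous or guessing-parameter item
  models, and limited-information (e.g. WLSMV-style) estimation.

## Reproducing the shipped studies

```{r, eval = FALSE}
sim <- simulate_hlc_data(default_paper_scenario(), seed = 1)
fit <- fit_sim(sim, quad = quad_spec(13, 7))
tidy(fit)
glance(fit)
lr_test_latent(fit)

scores <- eb_scores(fit)
tab <- state_validation_table()
external_validation(tab, tab, by = "state",
                    score = "hlc_mean", indicator = "nsdp_pc")
```
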