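---
title: "Latent variable models for longitudinal patient-reported outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent variable models for longitudinal patient-reported outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Multi-item patient-reported outcome (PRO) instruments calibrated under item
response theory — of which the NIH PROMIS banks are the prominent example —
are increasingly used as endpoints in randomized clinical trials. The routine
analysis scores each assessment (summed scores or a summed-score-to-EAP
table), then feeds the scores into a linear mixed model. That two-step
approach discards the calibrated measurement model and is vulnerable to the
well-known bias that individually optimal point scores induce in population
and change estimates.

`proirt` instead keeps the measurement model in the likelihood. Item
responses follow the logistic graded response model with slopes and
intercepts *fixed at their banked values*, which identifies the location and
scale of the latent outcome without re-calibration; the free parameters are
the structural ones a trialist cares about: latent means over visits,
variance components, treatment effects, and site effects.

## Model

For subject $j$ in site $i$, item $k$ at visit $t$, the response
probabilities are differences of cumulative logits,

$$P(Y_{ijkt} \ge c \mid \eta_{ijt}, \xi_k)
  = \mathrm{logit}^{-1}\!\left(c^*_{k,c} + a^*_k \eta_{ijt} + s_k \xi_k\right),$$

where starred parameters are banked and fixed. Two modifications adapt the
cross-sectional graded model to repeated administration:

* an item-specific factor $\xi_k \sim N(0,1)$ with free slope $s_k$
  (constrained equal over visits) absorbs the residual dependence of the same
  item administered repeatedly — the residual-correlation analogue of a
  mixed-model analysis. The squared slope $s_k^2$ is the item's residual
  dependence variance component;
* the occasion composite $\eta_{ijt}$ is a linear combination of structural
  latent variables, chosen by the analyst:
  * **growth** (`growth_spec`): $\eta_{jt} = \theta_{0j} + x(t)\,\theta_{1j} +
    \epsilon_{jt}$ with free means, variances and covariance for Intercept
    and Slope and unit-variance occasion residuals. The default time code is
    $x(t) = t - 1$;
  * **correlated occasion factors** (`two_tier_spec`): one general factor per
    visit with free means and an unstructured covariance matrix — the
    longitudinal two-tier item factor model;
  * **latent differences** (`latent_difference_spec`): the cumulative pattern
    $\eta_{ijt} = \theta_i + \theta_{ij1} + \cdots + \theta_{ijt}$, so factor
    $t \ge 2$ *is* the change from visit $t-1$ to $t$, with uncorrelated
    difference factors. Regressing a difference factor on the treatment dummy
    yields a latent difference-in-differences estimator.

A site-level random intercept $\theta_i$ (`add_site_level`) captures the
clustering of patients in sites; its variance against the baseline
subject-level variance gives the intraclass correlation. Latent regressions
(`attach_regression`) shift the latent means by covariates such as the
reference-cell treatment dummy, turning means into intercepts.

The growth model can be fitted in two algebraically identical
parameterizations: the single-level five-factor form (wide data) and a
multilevel three-factor form in which Intercept and Slope sit at level 2 and
a single level-1 factor absorbs the occasion residuals (block data). The
package represents both with the same internal structure — a "cluster" level
that is the subject in the multilevel growth form and the site in the
multilevel models — so their estimates and likelihoods agree by construction,
a useful cross-check that the test suite exercises at $n = 500$.

## Estimation

**Bock–Aitkin EM (`fit_baem`).** Marginal maximum likelihood with fixed-grid
quadrature. The two-tier structure is exploited for dimension reduction:
general factors are integrated jointly, each specific factor one dimension at
a time conditionally on the generals, and the site factor on an outer grid.
For the 3-visit, 8-item two-tier model the 11-dimensional latent space
therefore needs only 4 joint dimensions (`integration_dimension()`).

The grid lives on the *standardized* latent metric: `quadpts` (default 21)
equally spaced nodes over $[-5, 5]$ prior standard deviations per dimension,
with correlation captured by the node weights, and 11 nodes for the site
factor. Placing the grid on the standardized metric rather than on a fixed
absolute scale matters: a growth model's slope factor can have a variance
near 0.05, and a fixed absolute grid with spacing 0.5 cannot represent such a
prior (the discretized EM then collapses the variance). The grid is fixed
given the current parameters — there is no posterior-adaptive quadrature —
and trapezoid-type rules on Gaussians are spectrally accurate at this
spacing. For the two-tier and latent-difference structures the integration
runs in the occasion-composite space (a linear bijection of the factors), so
each visit contributes about `quadpts` distinct composite values and response
probabilities are computed once per distinct value.

The M-step is closed form for latent means, covariance blocks and regression
coefficients (restricted GLS on the posterior moments) and an exact
one-dimensional maximization for each specific slope over expected count
tables, so the log-likelihood is non-decreasing across iterations up to
quadrature precision. Convergence is declared when the largest parameter
change falls below `tol` (default `1e-4`, at most `max_iter = 2000`
iterations).

**Standard errors (BAEM).** Observed information by Richardson-extrapolated
central differences of the *analytic* marginal score, obtained from the
E-step posterior expectations via Fisher's identity; combining steps $h$ and
$h/2$ as $(4D(h/2) - D(h))/3$ with $h = 10^{-3}(1 + |v|)$.

**MH-RM (`fit_mhrm`).** For higher-dimensional problems, stochastic
approximation: each cycle imputes all latent variables (general, specific,
site) by componentwise random-walk Metropolis sweeps vectorized over
subjects, computes the analytic complete-data score and observed information,
and applies a Robbins–Monro update with a recursively averaged curvature
matrix. Design choices that matter:

* **Stage 1 is stochastic EM**: the complete-data ML map (closed-form
  means/covariances, damped Newton for the $s_k$) is applied to the imputed
  latents. Newton-type steps this far from the solution are unstable —
  single-sweep imputations whipsaw the covariance block — while the ML map
  keeps every iterate inside the parameter space.
* **Stage 2** uses gain $(1/j)^{0.75}$ with the Newton-type recursion and a
  per-cycle step cap. Convergence is judged on window means of the updates
  (3 windows of 50 cycles with mean absolute update below `1e-3`, the
  tolerance customary for this algorithm class): single-cycle updates have a
  Monte-Carlo noise floor and never individually fall to zero.
* For site models the sampler includes a likelihood-preserving *translation
  move* that shifts a site's intercept and compensates its subjects' latent
  factors along the matching composite direction. The site intercepts and
  the baseline mean are separated only by their priors, and componentwise
  moves mix across that ridge too slowly to be usable; the translation move
  restores proper mixing. Without it the sampler settles on a degenerate
  ridge point with inflated site variance.
* All randomness flows from one `seed`; the same seed and configuration
  reproduce the fit bitwise.

**Standard errors (MH-RM).** Louis-identity observed information accumulated
recursively over extra imputation cycles at the solution (default 1500,
thinned), i.e. the running average of complete-data information minus score
outer products. These agree with the Richardson standard errors to within a
few percent on models both engines can fit.

**Monte-Carlo marginal likelihood (`mc_marginal_loglik`).** The MH-RM engine
does not produce the marginal likelihood, so model comparison uses a
Chib–Jeliazkov posterior-ordinate estimate at the posterior mean of each
subject's latent vector, with the numerator over thinned posterior draws and
the denominator over fresh proposals. Two implementation details are load
bearing: the ordinate point is estimated from the first half of the draws and
the ordinate itself from the second half (evaluating the proposal density at
a point chosen from the same draws biases the ordinate upward), and the
reported value uses all retained draws while 10 batch means provide the
two-sided 95% interval. For site models the one-dimensional site factor is
integrated on its quadrature grid with per-subject ordinates estimated at
each node. The default 250 samples per subject follow common reporting
practice for this estimator.

## Fit assessment and inference

* `information_criteria()` implements `AIC = -2LL + 2k`,
  `BIC = -2LL + k log N` with `N` the number of unique subjects (a subject
  missing at baseline but seen later still counts once).
* `m2_rmsea()` computes the limited-information M2 statistic from univariate
  and bivariate category margins with the standard reduced weight matrix, and
  the associated RMSEA with truncation at zero. The model-implied weight
  matrix needs joint probabilities of up to four variables, so cost grows
  with the square of the number of margins; `max_margins` caps the request
  and the statistic is intended for single-level unconditional models of
  moderate size (for a 24-variable 5-category model the full M2 weight matrix
  has ~4500 rows and is out of scope for this implementation).
* `wald_test()` tests arbitrary linear hypotheses on the estimates with
  their error covariance, e.g. a 4-df omnibus treatment test in a five-arm
  trial; singular contrast covariances fall back to a generalized inverse
  with reduced degrees of freedom.
* `cov_to_corr()` and `icc()` are the reporting transforms for covariance
  blocks and site variance components.

## Scoring

`eap_score()` and `summed_score_table()` reproduce standard single-visit bank
scoring: the plain unidimensional graded model (the item-specific factors
exist only in the longitudinal measurement model and are excluded), a
standard-normal default prior, 49 quadrature points over $[-6, 6]$, and the
Lord–Wingersky recursion for the summed-score distribution. T-scores are
`50 + 10 * theta` (or the bank's declared metric), rounded to one decimal for
reporting only.

## The synthetic trial generator

The motivating data — a phase-2, multicenter, placebo-controlled trial whose
item responses are not public — is emulated by `default_trial_design()`:
67 sites with 1–12 subjects each (250 subjects in total), two 50/50 arms,
three visits, eight 5-category items with published slopes
(3.39, 2.58, 2.80, 2.51, 2.30, 2.47, 2.37, 2.77), a latent-difference
generating model with placebo means (1.42, −0.81, −0.25), within-site
variances (0.47, 0.86, 0.32), site variance 0.17 (baseline intraclass
correlation 0.27), a treatment effect of −0.56 on the first difference only,
item-specific slopes (0.96, 1.16, 0, 1.14, 0.64, 0.33, 1.17, 1.33), monotone
dropout with per-visit retention (1, 0.964, 0.920), and one subject missing
the baseline visit but present later.

Assumptions the generator makes where the emulated trial is underdetermined,
all recorded in the manifest:

* site sizes are drawn uniformly on 1–12 and then adjusted to the exact
  250-subject total (only the range and totals are known);
* the bank's category intercepts are synthetic — banks publish them
  separately and none are reproduced here — spaced for roughly uniform
  category usage at $\theta = 1.4$, the baseline severity region of such a
  sample;
* dropout is missing completely at random; informative dropout is out of
  scope.

What passing simulation-based tests does and does not show: the generator
draws exactly from the fitted model family, so recovery tests validate the
estimation machinery, not the model's adequacy for real data (no
cross-loadings, no differential item functioning over time or arms, no
informative missingness, exact logistic curves).

## Numerical choices and limitations

* Problem sizes in the test suite are scaled to keep the default run short:
  recovery uses 5 seeds of the 250-subject design (the full 20-seed study is
  a long-running variant of the same code), engine agreement uses the
  250-subject two-tier trial with an 11-point grid, and the
  parameterization-equivalence check uses 500 subjects with a 9-point grid
  (the equivalence is algebraic, so the grid only needs to be shared).
* EM with a latent regression whose covariates take many distinct values
  still works but loses the shared-probability-table speedup; the intended
  designs use a small number of arms.
* `s_k` is kept non-negative by the EM maximizer (the specific factor's sign
  is not identified); MH-RM leaves it unconstrained, so small negative
  estimates can occur for items whose residual dependence is near zero.
* The BIC identity reproduces printed reference values only to the precision
  of their inputs: a deviance printed to two decimals determines the BIC to
  about ±0.005, and one published pair differs in the second decimal for
  exactly that reason.
* The block (multilevel growth) parameterization is fitted by BAEM;
  MH-RM covers the single-level and site models, which is where stochastic
  estimation is needed.
* No 3PL/nominal/partial-credit measurement models; no item calibration from
  trial data (banks arrive calibrated); no crossed random effects; no
  discrete latent variables.

## A worked run

```{r, eval = FALSE}
library(proirt)
des <- default_trial_design(seed = 1)
sim <- simulate_trial(des)
fit <- proirt(sim$data, des$spec, des$bank, engine = "mhrm", seed = 1)
summary(fit)
mc_marginal_loglik(sim$data, des$spec, des$bank, fit$params, seed = 1)
```

The summary prints the latent means (reference-cell intercepts), treatment
coefficients per difference factor, variance components with the implied
intraclass correlation, and the item-specific slopes with recursive standard
errors. The README shows the numbers one such run prints.
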