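---
title: "Species distribution models with uncertain spatial covariates: methods"
author: "krigsdm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species distribution models with uncertain spatial covariates: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Species distribution models (SDMs) regress presence/absence records on
environmental ("abiotic") covariates such as soil chemistry. Two features of
real survey data make the covariates uncertain at exactly the places where
the species was recorded:

* **Measurement error.** Repeated laboratory measurements of, say, soil
  nitrogen at the same spot disagree; the observation is a noisy realization
  of the underlying value (classical error: the observed values are *more*
  variable than the truth).
* **Spatial misalignment.** Abiotic surveys and vegetation surveys are
  separate campaigns; covariate measurements usually do not exist at the
  field-visit locations and must be interpolated. Kriging predictions are
  *less* variable than the truth (a Berkson-type error).

Treating interpolated or noisy covariate values as exact biases effect
estimates — using raw noisy values attenuates the slope toward zero
("regression dilution"), and either form of uncertainty misstates the
confidence in the estimated association. `krigsdm` implements and compares
three estimators on point-referenced data:

* **direct** — logistic GAMM on the observed covariate values (only possible
  when data are aligned);
* **two-stage** — kriging each covariate first, then plugging the posterior
  mean surface into the SDM as a known quantity;
* **joint** — a single hierarchical model in which the covariate values at
  the field-visit locations are latent random variables, so their
  uncertainty propagates into the species model and, conversely, the species
  records inform the covariate fields.

# Model components

## Kriging layer

Each covariate $j$ is modelled as a latent Gaussian random field with
constant mean $\alpha_j$ and Matérn covariance with smoothness $\nu = 1$,

$$C(d) = \sigma_j^2 \, \kappa d \, K_1(\kappa d), \qquad \kappa = \sqrt{8}/r_j,$$

observed with independent measurement error of variance $\delta_j^2$
(the nugget). With $\nu = 1$ the correlation at distance $d = r$ is
$\sqrt{8}K_1(\sqrt 8) \approx 0.14$, which is why the range $r$ is described
as the distance at which spatial correlation is "close to zero".

Default priors are deliberately vague: $\alpha_j \sim N(0, 1000)$;
$1/\delta_j^2 \sim \mathrm{Gamma}(1, 10^{-5})$; and
$\log\sigma_j^2, \log r_j \sim N(0, 10)$ (variance scale). The Normal
hyperpriors are placed directly on the log variance and log range rather
than on an internal precision parameterization; with the amount of data the
package targets (tens to thousands of points) the posterior is dominated by
the likelihood and the exact vague-prior convention is immaterial, but it is
configurable through `prior_config()`.

## Species layer

Presence/absence $y_i$ at field visit $i$ follows a Bernoulli distribution
with the logistic link and a structured additive predictor

$$\eta_i = \beta_0 + \textstyle\sum_j \beta_j x_j(s_i) +
  \sum_l f_l(z_l(s_i)) + W(s_i),$$

with linear effects for the uncertain covariates, optional nonlinear effects
of exactly known covariates through second-order random-walk (RW2) splines
over a binned domain, and a Matérn spatial residual $W$ that absorbs spatial
pattern in occurrence not explained by the covariates. Fixed effects get
$N(0, 1000)$ priors; spline and residual variances get the same vague
conventions as the kriging layer.

**Spline identifiability.** The RW2 prior is improper: adding any linear
function of the bin index leaves its density unchanged. Each spline is
therefore decomposed into an explicit (vague-prior) linear-trend coefficient
plus a penalized part spanned by the positive eigenvectors of the RW2
penalty, and both parts are constrained to sum to zero across bins. The
constraint costs no flexibility (the trend is retained explicitly) and makes
the intercept identifiable; it is recorded in exported fit metadata.
Default discretization is 20 equal-width bins over the observed range;
categorical covariates should use their levels as bins.

# Inference: a nested Laplace scheme

The reference implementation is deterministic, in the spirit of integrated
nested Laplace approximation, rather than MCMC:

1. **Latent layer.** Conditional on all hyperparameters the model is a
   latent-Gaussian logistic regression. Its posterior mode is found by
   iteratively reweighted least squares with backtracking; the Laplace
   (Gauss–Newton) approximation provides the conditional posterior and the
   marginal likelihood. All linear algebra is pushed through the Woodbury
   identity into observation space, so the only factorizations are
   $n \times n$ Cholesky decompositions and the dense prior covariances are
   never inverted. Posterior draws, when needed (maps, prevalence
   intervals), use Matheron's rule: a prior draw corrected by a kriging-type
   update, which samples the Laplace posterior exactly.
2. **Hyperparameter layer.** The handful of hyperparameters (log variances,
   log ranges, and — in the joint model — the coefficients of the uncertain
   covariates) are optimized by Nelder–Mead on the Laplace marginal
   posterior, with a restart whenever a subsequent exploration point beats
   the optimum. Curvature is estimated by finite differences (cross terms
   within parameter blocks; between-block couplings are near zero and
   skipped), and uncertainty is propagated by mixing conditional posteriors
   over the mode and one point either side along each principal curvature
   axis, weighted by the posterior — a deterministic design in the style of
   central composite integration.

**Why the joint model's covariate coefficients are hyperparameters.** If
$\beta_j$ and the latent covariate values $v_j$ both sit inside the Gaussian
latent vector, the joint maximum a posteriori problem is degenerate: the
likelihood term $\beta_j v_j$ lets $|\beta_j|$ grow without bound while the
latent values shrink, and mode-finding lands in a spike of negligible
posterior mass (observed in development as $\hat\beta \approx 70$).
Conditioning on $\beta_j$ instead makes the latent problem strictly
log-concave; the same device is used for measurement-error models in
latent-Gaussian software. The resulting posterior for $\beta_j$ comes from
the hyperparameter layer (mixture mean over exploration points; spread from
the curvature), and was validated in development against brute-force grid
integration of the same marginal posterior (agreement within a few percent
on the posterior sd).

**Feedback policy.** In the joint model the latent covariate *values* at
the field visits always receive full feedback from the species data. The
covariate-field *hyperparameters* $(\alpha_j, \sigma_j^2, r_j, \delta_j^2)$
are, by default, conditioned on their stage-1 kriging posteriors
(`feedback = "latent"`), which keeps the outer optimization low-dimensional;
`feedback = "full"` folds them into the joint objective (adding the Gaussian
kriging marginal of the abiotic observations) at considerably higher cost.
The default reflects that species records carry little information about
covariate-field hyperparameters relative to the abiotic observations
themselves.

**Two-stage details.** Stage 1 integrates the kriging intercept analytically
(covariance augmentation by the prior variance of $\alpha$) and mixes
predictions over the hyperparameter exploration points; stage 2 plugs the
resulting posterior-mean surface into the SDM. For the joint model the same
mixture is collapsed, by moment matching, into a single Gaussian conditional
law for the latent covariate values at the field visits, which becomes their
prior in the joint fit.

# Numerical choices

* Matérn correlation is evaluated through a cubic-spline interpolant of
  $x K_1(x)$ built once per session (absolute error below $10^{-10}$,
  far below the covariance jitter); correlation matrices are cached by
  range during finite-difference sweeps.
* Covariance factorizations add a jitter of $10^{-8}\sigma^2$ to the
  diagonal and fail loudly if the matrix still is not positive definite.
* Conditional variances are floored at zero; IRLS weights at $10^{-10}$.
* Hyperparameter moves are clamped to $[-25, 25]$ on the log scale, which
  in particular keeps noiseless data (where $\log\delta^2 \to -\infty$ is
  the supremum) finite; curvature along such flat directions is floored so
  exploration steps stay bounded.
* A smooth quadratic barrier penalizes hyperparameter points whose latent
  mode saturates the likelihood (maximum $|\eta| > 20$, i.e. fitted
  probabilities within $2\times10^{-9}$ of 0 or 1). In that regime the
  IRLS weights collapse and the Laplace determinant no longer penalizes
  complexity, so the approximate marginal likelihood rises spuriously along
  a ridge of extreme residual variance — a known failure of Laplace
  approximations for Gaussian-process classification. The barrier is
  exactly zero wherever the fit is supported by data. Within the
  non-saturated region the Laplace marginal was validated in development
  against a 20&nbsp;000-draw importance-sampling estimate of the exact
  marginal (agreement to well under one posterior sd on effect
  coefficients).
* Degenerate inputs fail early with specific messages: constant covariates
  for splines, missing covariate columns (named), empty grids, mismatched
  point sets.

# The synthetic-data generator

`generate_dataset()` draws the study conditions used throughout the tests:
uniform locations on the unit square ($N = 1000$ field visits, $M = 100$
abiotic points by default); three independent Matérn fields
$Z, Z_1, Z_2$ with variance $0.5$ and range $0.3$ combined into confounded
covariates $X_1 = Z + Z_1$, $X_2 = Z + Z_2$ (variance 1, covariance 0.5);
classical measurement error of variance $0.3$ on the observed values;
$\eta = -2 + X_1 + X_2 + W$ with an independent spatial residual $W$ drawn
from the same Matérn law; and Bernoulli occurrences (implied prevalence
$\mathbb{E}[\mathrm{logistic}(N(-2, 3.5))] \approx 0.2$). Aligned variants
additionally observe the covariates at all field visits ("$M + N$"
observations); noise-free variants set $\delta^2 = 0$.

What it deliberately does **not** emulate: non-Gaussian or skewed abiotic
variables, preferential (non-uniform) sampling of survey locations,
anisotropy or non-stationarity, temporal misalignment, and covariate
effects that are nonlinear in the uncertain covariates. Passing the
simulation study therefore demonstrates correct behaviour of the estimators
under the model's own assumptions — it does not certify performance on real
survey data, where all of the above occur.

The study runner (`run_study()`) scores each estimator by the posterior mean
and sd of $\beta_1$, the error of the estimate against the true value 1,
and RMSEs of the predicted occurrence-probability and covariate maps against
the simulated truth on a 25×25 evaluation grid of cell centres (the
reference text leaves the grid resolution open; 25×25 keeps map scoring well
below fitting cost and is configurable). Truth fields are carried in a
separate element that is never passed to fitters.

## Problem sizes and replicate counts

Replicate counts are not fixed by the reference study; the package defaults
to 20–30 runs and the acceptance workflow uses 20. The misaligned setting
runs at the full $N = 1000$, $M = 100$ because posterior sds scale with the
data size. The aligned settings are run at $N = 300$ (plus 100 extra
abiotic points), which keeps the whole study at desk scale; their headline
quantities are mean posterior means of $\beta_1$. One finite-sample caveat
of the reduced size: the estimated spatial residual $W$ partially absorbs
the smooth covariate signal, attenuating mean effect estimates by roughly
5% at $N = 300$ (measured: $\approx 0.95$ for the direct model on noiseless
aligned data, rising to $\approx 0.97$ at $N = 1000$ on the same seeds).
At 20 replicates the Monte-Carlo standard error of a batch mean is
$\approx 0.05$–$0.08$, so individual batch means carry visible noise on
top. Map RMSEs are computed for the misaligned setting, where interpolation
quality is the scientific question.

# Validation design

* Closed-form Gaussian conditioning (`gp_conditional`) is checked against a
  brute-force joint-MVN partition oracle; the IRLS/Laplace engine against
  maximum-likelihood logistic regression (vague-prior limit, no spatial
  term) and against an elliptical-slice-sampling MCMC oracle with the
  spatial covariance fixed.
* Generator moments (variances, covariance, prevalence) are checked against
  Monte-Carlo oracles that exploit the known zero mean of the fields —
  centering a single realization of a correlated field at its own spatial
  average removes real variance, so raw second moments are the right
  estimator.
* Coverage checks (hyperparameter intervals, credible intervals for
  $\beta_1$, prevalence prediction intervals) run at reduced replicate
  counts with binomial-error allowances.
* Leave-region-out cross-validation holds out species field visits only, by
  default: abiotic surveys typically cover all regions regardless of where
  the species model is applied. Removing abiotic observations inside the
  held-out region is supported (`hold_out_abiotic = TRUE`) and recorded in
  the output metadata, since the right choice depends on the deployment
  scenario.

# Known limitations

* The Laplace/exploration-point machinery reports moment-matched Gaussian
  summaries; extreme posterior skewness (tiny data sets, separation) is
  summarized only through its first two moments.
* The joint model's default feedback policy conditions covariate-field
  hyperparameters on stage-1; full feedback is available but slow, and
  small differences from a fully hierarchical fit are expected — in
  development the joint model's mean posterior sd for $\beta_1$ ran
  slightly above the fully hierarchical reference value while preserving
  the joint-vs-two-stage ordering.
* Because the logistic model is non-collapsible, plug-in (two-stage)
  estimates target a slightly attenuated marginal slope whenever genuine
  covariate uncertainty remains; the joint model estimates the
  covariate-conditional effect and therefore tends to sit a few percent
  above the two-stage estimate on the same data. This is a property of the
  estimands, not an approximation artifact (verified by exact
  importance-sampling computation of the joint conditional posterior).
* Dense covariance limits problem sizes to a few thousand locations; there
  is no sparse-precision (SPDE) backend.
* Smoothness is fixed at $\nu = 1$; anisotropy, non-stationarity and
  geodesic distances are out of scope. Coordinates are used as supplied.
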