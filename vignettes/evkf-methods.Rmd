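---
title: "Online variational filtering and dynamics learning in exponential families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Online variational filtering and dynamics learning in exponential families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evkf)
```

## The problem

Neural population recordings arrive as a stream of high-dimensional
observations $y_t$ (spike counts per time bin, or calcium/LFP-like real
vectors) that are well described by a low-dimensional latent state $z_t \in
\mathbb{R}^L$ evolving under a Markov transition $p_\theta(z_t \mid z_{t-1})$
with an observation model $p_\psi(y_t \mid z_t)$. Offline methods infer the
latent trajectory after the experiment; this package addresses the *online*
problem: after each new observation, update the belief about the current
state — and the model of the dynamics itself — in constant time and memory,
so the estimate can drive closed-loop experiments.

## The model class

All beliefs live in one *minimal, constant base measure* exponential family,

$$q(z) = h \exp\left(\lambda^\top t(z) - A(\lambda)\right),$$

where the base measure $h$ does not depend on $z$ (Gaussian, Bernoulli,
Beta, Gamma, continuous Bernoulli, ...). Minimality makes the natural
parameters $\lambda$ and mean parameters $\mu = \mathbb{E}[t(z)] = \nabla
A(\lambda)$ dual coordinates of the same object. The dynamics are specified
through a natural-parameter map $\lambda_\theta(\cdot)$: the transition is the
family member with parameters $\lambda_\theta(z_{t-1})$. Shipped families:
multivariate Gaussian, factorized continuous Bernoulli on $[0,1]^L$,
factorized Gamma, and Bernoulli (for conjugacy tests).

**Gaussian coordinate convention.** The flat layout is $\lambda = (P^{-1}m,\,
\mathrm{vech}(-\tfrac12 P^{-1}))$ with `vech` the row-major upper triangle.
The mean vector stores the second-moment block with *doubled off-diagonal
entries*, so that the plain Euclidean inner product of a natural and a mean
vector equals $\lambda_1^\top z + \mathrm{tr}(\Lambda_2 z z^\top)$ and the
finite-difference gradient of `log_partition()` is literally
`natural_to_mean()`. All KL/entropy identities then hold coordinate-wise with
no weighting matrices.

## The four-step recursion

Each arriving observation triggers:

1. **Variational predict.** The KL-optimal prediction within the family has
   natural parameters $\bar\lambda = \mathbb{E}_{q_{t-1}}[
   \lambda_\theta(z)]$ — the *expected dynamics natural parameters* under the
   previous posterior. The expectation is computed exactly when
   $\lambda_\theta$ is affine in the sufficient statistics (linear-Gaussian,
   affine-CB, constant maps) and by Monte Carlo otherwise (`n_mc_predict`,
   default 64). `free_energy()` exposes the objective this solution
   minimizes, and the test suite verifies the optimality numerically.
2. **Variance correction.** Because state-independent blocks of
   $\lambda_\theta$ propagate no uncertainty, the prediction underestimates
   the variance (for the linear-Gaussian model, by exactly $A P A^\top$).
   The `ekf_like` correction inflates the Gaussian predictive covariance by
   $M P M^\top$, $M$ the Jacobian of the conditional-mean map at the previous
   mean, recovering the exact Kalman prediction in the linear case. For the
   Gamma family the correction moment-matches a Monte-Carlo law-of-total-
   variance estimate (two free parameters per coordinate suffice). For the
   continuous Bernoulli the single natural parameter determines mean and
   variance jointly, so no widening can preserve the mean: the correction is
   a documented pass-through there.
3. **Update.** Conjugate pairs (Gaussian latent, Gaussian likelihood) get the
   exact Bayes update. Otherwise `cvi_update()` performs natural-gradient
   ascent of the per-step ELBO
   $\mathbb{E}_q[\log p(y|z)] - \mathrm{KL}(q \,\|\, \bar q)$:
   $\lambda \leftarrow (1-\beta)\lambda + \beta(\bar\lambda + g)$ with $g$
   the mean-parameter gradient of the expected log likelihood. For the
   Gaussian-latent/Poisson pair the expectation is closed form
   ($\mathbb{E}[e^{c^\top z}] = e^{c^\top m + \frac12 c^\top P c}$), so no
   sampling is involved; for CB/Gamma latents with Gaussian observations the
   gradient uses the analytic derivatives of the per-coordinate log-partition
   (`A'`, `A''`, `A'''`). With $\beta = 1$ and one iteration CVI reproduces
   the conjugate update exactly. Steps that would leave the natural domain
   are backtracked by halving $\beta$ (at most 20 times).
4. **Learn.** With the fresh posterior $\lambda^*$ held fixed, the dynamics
   parameters take one (configurable) stochastic-gradient step. The default
   objective is the square natural-parameter loss
   $\tfrac12\|\lambda^* - \bar\lambda_\theta\|^2$, re-estimating
   $\bar\lambda_\theta$ by Monte Carlo from $q_{t-1}$ each step; at its
   minimum (reachable when the map can realize any natural parameter) the
   posterior-to-prediction KL is zero, which the suite checks.

## Two deliberate deviations worth knowing about

**The learning loss for constrained Gaussian maps.** The square loss is an
exact surrogate for the variational M-step only when $\lambda_\theta$ can
reach any valid natural parameter. A Gaussian map with *fixed* noise
covariance `Q` cannot (its precision block is frozen), and then the square
loss's stationary point rescales the learned mean map by $Q P_*^{-1}$
($P_*$ the stationary posterior covariance). In experiments this plateaued
the recovered scalar transition coefficient at about $0.70$ for a true value
of $0.9$. `loss = "kl"` instead descends the M-step objective
$\mathrm{KL}(q^* \| \bar q_\theta)$ directly — its gradient is
$\mu(\bar\lambda_\theta) - \mu(\lambda^*)$ chained through the map — and is
the recommended (and tested) choice for fixed-`Q` Gaussian dynamics. Both
losses share all other machinery.

**Model noise inflation during online learning.** When the dynamics are
unknown, the model's process noise plays two roles: true stochasticity and
*model error*. With the Van der Pol benchmark's true noise
($\sigma = 0.05$ per bin) a randomly initialized model is so overconfident
that observations (50 Poisson channels at ~0.1 counts/bin) can never correct
it, and learning receives pure noise as targets. The shipped experiment
therefore fixes the learned model's `Q` at $0.04 I$ — roughly the per-bin
squared displacement of the latent flow — which keeps the filter honest about
its ignorance while the drift is being learned. The dynamics-KL metric is
reported against this same model, so the inflation *penalizes* the learned
model's score; the improvement over initialization is measured on equal
terms.

## Numerical choices

* Positive definiteness is enforced by symmetrizing and requiring the
  smallest eigenvalue to be positive and above $10^{-10}$ *relative to the
  largest* (so a well-scaled near-deterministic covariance like $10^{-12}$
  passes while an indefinite matrix raises); violations raise, never project.
* Continuous Bernoulli functions $A, A', A'', A'''$ switch to series
  expansions near $\lambda = 0$ (thresholds $10^{-4}$ for $A, A'$ and
  $10^{-2}$ for the curvature terms) to avoid $0/0$.
* `mean_to_natural` uses closed forms (Gaussian, Bernoulli), monotone
  root-finding plus one Newton polish (CB, relative tolerance $10^{-10}$),
  or a log-scale solve of $\log\alpha - \psi(\alpha) = s$ (Gamma).
* The drift network is a tanh MLP (default 2 x 64) with analytic backprop —
  no autodiff framework is available in this R environment — and its
  gradients and Jacobians are finite-difference-tested. `residual = TRUE`
  parameterizes the conditional mean as $z + \mathrm{net}(z)$, the natural
  choice for Euler-discretized flows; it also keeps the prediction's
  Jacobian near the identity at initialization, which the variance
  correction needs to keep uncertainty alive before the dynamics are learned.
* Online optimization uses Adam with an optional Robbins–Monro rate decay
  `rate/(1 + decay * t)` and an optional gradient-norm clip; the parameter-
  recovery experiment uses `lr = 0.05, decay = 0.03`, the Van der Pol
  experiment `lr = 0.003, decay = 0.001, clip = 1`.
* Initial posteriors default to standard-normal naturals (Gaussian),
  $\lambda = 0$ (CB, i.e. uniform), and a weakly informative Gamma(2, 2).

## What the simulators emulate — and what a green test establishes

`simulate_lds()` exists for oracle tests. `simulate_crnn()` reproduces the
chaotic recurrent network benchmark ($z + \Delta\tau^{-1}(\gamma W \tanh z -
z)$, $\gamma = 2.5$, $\tau = 25$ ms, $\Delta = 1$ ms, $Q = 10^{-3}I$, $W$
i.i.d. $N(0, 1/L)$). `simulate_vdp()` is the Euler-discretized noisy Van der
Pol oscillator ($\tau_{1,2} = 0.1$, $\gamma = 1.5$, $\sigma = 0.05$,
$\Delta = 0.01$) with Poisson counts $y \sim \mathrm{Poisson}(\Delta
e^{Cz+b})$, $C_{ij} \sim N(0, 0.25)$ and $b$ calibrated so each channel
averages 0.1 counts/bin. `simulate_cb()` draws factorized continuous
Bernoulli latents with an affine natural map $\lambda(z) = \kappa R_\phi (z -
\tfrac12)$; the gain must exceed the linearized Hopf threshold
($\kappa/12 > 1$) for the mean map to possess a limit cycle, and the shipped
$\kappa = 16$, $\phi = \pi/4$ sits comfortably above it. The noise term of
the Van der Pol system is drawn independently per coordinate (the shared-
versus-independent choice is not determined by the model statement).

These are synthetic worlds with known, fixed readouts ($\psi$ is never
learned). A green suite establishes exactness against the Kalman filter on
linear-Gaussian models, the optimality/tightness/equivalence properties of
the variational construction, and qualitative learning behavior
(improvement over time, family-appropriateness of CB vs Gaussian
generation). It does not establish performance on real recordings, bins with
model mismatch in $\psi$, or the wall-clock claims of any particular
hardware.

## Known limitations

* The learned model's `Q` is fixed, not learned; likelihood parameters
  $\psi$ are fixed, not learned.
* Smoothing (backward passes) is out of scope; the filter never revisits a
  past belief.
* The non-Gaussian variance correction is heuristic (moment matching for
  Gamma, identity for CB).
* The bootstrap particle filter uses systematic resampling at ESS $< n/2$
  and will, like any BPF, degenerate in high dimensions; the EnKF applies no
  inflation or localization.
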