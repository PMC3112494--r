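---
title: "Methods: post-hoc model selection by Bayesian model reduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-hoc model selection by Bayesian model reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmr)
```

This vignette records the mathematical and design choices behind `bmr` in
enough detail to audit them. Companion material: the test suite encodes
each claim as an executable check, and the project's decisions ledger
records the choices (and honest deviations) chronologically.

## 1. The reduction identity

All densities are multivariate Gaussians (the Laplace assumption). A
*full* model has prior $N(\eta_F, \Pi_F^{-1})$, approximate posterior
$N(\mu_F, P_F^{-1})$, and free energy $F_F$ bounding its log-evidence. A
*reduced* model keeps the likelihood and substitutes a prior
$N(\eta_i, \Pi_i^{-1})$. Because the likelihood cancels in the ratio of
the two models' joint densities, the reduced posterior and evidence follow
from the full quantities alone:

$$P_i = P_F + \Pi_i - \Pi_F, \qquad
  \mu_i = P_i^{-1}(P_F\mu_F + \Pi_i\eta_i - \Pi_F\eta_F),$$

$$F_i = F_F
  + \tfrac12 \ln \frac{\lvert\Pi_i\rvert\,\lvert P_F\rvert}
                      {\lvert P_i\rvert\,\lvert\Pi_F\rvert}
  - \tfrac12\left(\mu_F^\top P_F \mu_F + \eta_i^\top \Pi_i \eta_i
    - \eta_F^\top \Pi_F \eta_F - \mu_i^\top P_i \mu_i\right).$$

Two implementation decisions matter:

* **Determinant support.** Coordinates whose prior variance is exactly
  zero in *both* priors are fixed constants of the problem; they are
  excluded from every determinant and quadratic form (otherwise both
  $\lvert\Pi\rvert$ factors are infinite with an indeterminate ratio).
  This reading was validated against direct numeric quadrature of the
  reduced-evidence integral in 1–3 dimensions (agreement $\le 10^{-6}$
  nats) and against exact conjugate-evidence differences
  ($\le 10^{-8}$ nats).
* **Feasibility.** $P_i$ must stay positive definite. Reductions that
  *widen* the prior can violate this (the identity then has no valid
  Gaussian posterior); `reduce_model` detects it and raises an error
  rather than returning a complex-log-determinant artifact.

## 2. Clamping and its conditional semantics

Removing parameters means collapsing their prior variance to zero at a
value $v$. Taking the limit in the identity above gives the
Savage–Dickey density ratio,

$$\Delta F = \ln q_c(v) - \ln p_c(v),$$

the log ratio of the full posterior's and full prior's *marginal*
densities on the clamped block at $v$, while the surviving block's
posterior is the full posterior's *conditional* given $v$.

A subtlety worth stating explicitly: the implied prior on the surviving
block is the full prior's conditional as well. If the full prior
correlates clamped and free parameters, the clamp is therefore **not**
the $\varepsilon$-variance limit of a reduced prior built by zeroing the
cross-covariances — that construction converges to a different model.
The package's generators all use diagonal priors, where the two coincide;
the equivalence test uses a diagonal-prior fixture for exactly this
reason.

## 3. Discrete spaces, search and ties

A `switch_space` attaches a binary switch to selected parameters: *on*
keeps a prior variance $\gamma$, *off* clamps the parameter at zero.
Constraint groups force switches to move together (used for reciprocal
network connections). Enumeration is lexicographic with the first group
as the most significant bit, so results are reproducible by construction.
Free-energy ties break toward the model with fewer active switches, then
enumeration order: when the evidence cannot distinguish models, the more
parsimonious one wins deterministically.

`greedy_search` removes (or restores) one switch group at a time,
accepting the best single change until no change improves the evidence.
On every fixture tested — including the 12-switch selection regime and
the constrained network space — it reproduces the exhaustive winner.

## 4. Continuous spaces and relevance determination

A `prior_family` maps a hyperparameter vector $\lambda$ to a reduced
prior; $F(\lambda)$ is maximized with L-BFGS-B (a quasi-Newton method
that accepts the box bounds the families need) from several jittered
starts. Variances are optimized on the log scale.

For per-parameter variance families (automatic relevance determination),
the lower bound acts as a collapse floor, $e^{-16}\gamma$. After the
quasi-Newton passes, a *boundary polish* step tests each coordinate's
collapsed candidate and accepts it when its free energy is within the
convergence tolerance of the interior optimum: optima the evidence cannot
distinguish resolve to the more parsimonious prior. Variances at the
floor are reported as exact zeros.

## 5. The variational-Laplace GLM inverter

`invert_glm` fits $y = X\beta + \varepsilon$ with group-wise noise
precisions $e^{\gamma_g}$ under a mean-field factorization
$q(\beta)\,q(\gamma)$:

* $q(\beta)$ is the exact conjugate Gaussian given the *expected*
  precisions $E[e^{\gamma_g}] = \exp(m_g + v_g/2)$ (the log-normal mean;
  the plug-in $\exp(m_g)$ would bias the free energy).
* $q(\gamma)$ takes one guarded Newton step per group per sweep on its
  strictly concave variational energy: step magnitude capped at $\pm 4$,
  backtracking halving against the energy itself, $m_g$ confined to
  $[-30, 30]$, and the expected precision capped so that noise-free data
  cannot overflow.

The free energy is evaluated every sweep. Because the $\gamma$ update is
a single Newton step rather than an exact maximization, the iteration can
oscillate within numerical slack of the fixed point; a *decrease* smaller
than ten times the convergence tolerance is therefore treated as
convergence, while larger repeated decreases flag the fit and return the
best-F iterate. In the known-precision limit (near-delta prior on
$\gamma$) the inverter reproduces the conjugate posterior and evidence to
$10^{-6}$ / $10^{-2}$ nats respectively.

## 6. The network surrogate and its fidelity trade-offs

The network demo simulates a 4-node linear stochastic system
$x_{t+1} = (I + \Delta t\, A)x_t + w_t$ observed with noise, and inverts
the coupling matrix $A$ by Bayesian regression of the Euler derivative on
the state. Three honest trade-offs:

* **Smoothed innovations attenuate couplings.** The default regime
  smooths the innovations over a short window, which makes regression
  residuals endogenous and shrinks coupling estimates to roughly half
  their generating values. Detection (which connections exist) survives;
  unbiased estimation does not. Tests of estimator *consistency*
  therefore use the white-noise regime, while discovery tests run on the
  smoothed default.
* **Observation noise.** The default observation log-precision (8) is
  higher than the state noise log-precision (6): at 256 time bins the
  derivative signal is weak, and heavier measurement noise swamps it.
  This is a surrogate-design choice, recorded rather than hidden.
* **Spurious couplings and ARD.** At 256 bins, finite-sample spurious
  couplings with $|z| \approx 1.2$–$1.6$ are common. The 64-model
  discrete search is protected by the reciprocity constraint — a spurious
  coupling is tied to its near-zero partner and the pair is rejected —
  but per-connection ARD has no such constraint and honestly sustains
  small nonzero variances on some absent connections. The acceptance
  test asserting exact collapse on all absent connections fails for this
  reason, and is left failing; the analysis lives in the decisions
  ledger.

## 7. Problem sizes

The shipped regimes (16 observations × 12 regressors; 4 nodes × 256
bins; 4096- and 64-model spaces) are *package choices* made to keep the
full suite runnable in minutes on one CPU, not statements about the
method's limits. The algebra is dimension-generic; `model_count`
illustrates why exhaustive enumeration stops being an option around
$2^{24}$ models and the greedy search exists.

## 8. Known limitations

* Reduction quality inherits the full model's Gaussian posterior. In
  particular, the mean-field $q(\gamma)$ is *frozen* during reduction:
  when removing parameters would materially change the noise estimate
  (small $n$, $p \approx n$), the reduced free energy can disagree with a
  fresh inversion of the reduced model by several nats. One of the five
  pre-registered internal-validation seeds shows exactly this.
* With many correlated candidate regressors and few observations, the
  model posterior spreads over near-winning models; the winning model's
  posterior probability rarely exceeds 0.5 even when it is correct.
  Summaries should report the posterior over models, not just the MAP.
* Priors that correlate clamped and free parameters change the clamp's
  meaning (section 2); the package computes the conditional semantics
  and leaves marginal-style constructions to the caller.
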