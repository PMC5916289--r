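---
title: "Modeling reaction-norm evolution with evolvable reference environments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling reaction-norm evolution with evolvable reference environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnevol)
```

## The model

`rnevol` propagates the mean state of a population of plastic organisms one
generation at a time. Three ingredients define a model.

**Reaction norm.** Individual $i$ expresses the $m$-dimensional phenotype

$$ y_{i,t} = z_{a,i,t} + Z_{b,i,t}\,\tilde u_{i,t} + e_{i,t}, $$

where $z_a$ are elevation traits, $Z_b$ an $m \times p$ matrix of slope and
shape traits, and $\tilde u$ a vector of $p$ monomials ("cue products") in
the shifted cues $u_{j,t} - z_{c,j,i,t}$. The reference traits $z_c$ shift
the whole norm along the cue axes; they are ordinary quantitative traits and
may carry genetic variance. An `rn_spec` lists the exponent vector of each
cue product and a boolean mask of which slope coefficients exist, so the
univariate linear norm ($m = p = q = 1$, product $u - c$), polynomial norms,
and multi-cue norms are all instances of one structure. The flat state layout
is fixed as (elevations, active slopes column-major, references), which makes
the blocks of the augmented covariance matrices unambiguous.

**Fitness.** Gaussian stabilizing selection
$W = W_{max} \exp(-D/2\omega^2)$, with mismatch $D$ either
$\sum_j (y_j - \theta_j)^2$ (`sum_of_squares`, the constructor default and
the standard multivariate form) or $\bigl(\sum_j (y_j - \theta_j)\bigr)^2$
(`squared_sum`). $\omega^2$ is the width of the fitness function in squared
phenotype units (all bundled experiments use $\omega^2 = 10$, weak
selection); $W_{max}$ only scales mean fitness. An optional plasticity cost
multiplies fitness by $\exp(-\sum_k c_k z_{b,k}^2 / 2\omega^2)$; it is off by
default because in the two-cue experiment its effect is negligible.

**Environment.** Each generation one joint multinormal draw of cues and
optimum $(u_t, \theta_t)$, independent across generations (white process),
with fixed covariance and means that may change in scheduled steps. The
stationary stochastic environment is fully described by $\mu_U$,
$\mu_\Theta$, the cue covariance, the optimum covariance and the cue–optimum
covariance; the latter is what selects nonzero stationary slopes.

The mean state then evolves by the augmented multivariate breeder's equation

$$ \bar z_{t+1} = \bar z_t + \frac{1}{\bar W_t} G_{aug} P_{aug}^{-1}
   \operatorname{cov}(W_i, z_i), $$

with $G_{aug}$ and $P_{aug}$ the additive-genetic and phenotypic covariance
matrices over the full layout, both held constant. Zero genetic variance in a
reference trait makes its row of $G_{aug}$ zero and its mean an exact
constant — the classic fixed-zero-point model is the $G_{cc} = 0$ special
case, which the tests verify against a deterministic quadrature oracle.

## The Monte-Carlo estimator

The selection differential $\operatorname{cov}(W, z)$ and $\bar W$ have no
convenient closed form for nonlinear norms, so each generation the package
samples $n$ individuals from $N(\bar z_t, P_{aug})$ plus independent
residuals $N(0, \Sigma_e)$, evaluates phenotypes and fitness, and uses the
unbiased sample covariance. Consequences:

* The update is unbiased in expectation but carries $O(n^{-1/2})$ noise; one
  test verifies the error against the quadrature oracle shrinks accordingly.
* Sampling noise acts like drift on any selection-neutral direction of trait
  space (see *Limitations*).
* Directly after a large step in the mean optimum, $\bar W$ can collapse by
  many orders of magnitude and the $1/\bar W$ factor amplifies sampling
  noise; the simulator survives this (selection is then effectively
  truncation on the few fittest sampled individuals) but the transient is
  noisy at moderate $n$.

Experiment presets use $n = 5000$ individuals per generation and full run
lengths of 10,000 generations (about 30 s per run); the general default is
$n = 10{,}000$. Unit tests use a few hundred individuals and tens of
generations; the oracle comparison uses a single step at $n = 10^6$.

**Residual representation.** The non-additive component $e$ is additive on
the phenotype and drawn separately from the traits (`resid_cov`), so in the
fully additive experiments $P_{aug} = G_{aug}$. Folding $e$ into $z_a$ (with
$P_{aa} = G_{aa} + \sigma_e^2$) is mathematically equivalent: for jointly
multinormal traits, $\operatorname{cov}(W, x) = G P^{-1}
\operatorname{cov}(W, z)$ by the normal projection identity, so both
representations give the same expected update. $P_{aug} - G_{aug}$ must be
positive semidefinite and is validated as such.

**Seeds.** One master seed drives everything. The full environment sequence
is pre-drawn under a seed derived from it, and individual sampling uses a
second derived stream, so two runs differing only in $n$ experience an
identical environment — useful when studying estimator noise.

## Fitness mismatch form in the bivariate experiment

For a single phenotype the two mismatch forms coincide. For the bivariate
nonlinear step experiment (`build_preset("fig2")`) they do not, and the
choice matters scientifically:

* Under `sum_of_squares`, each phenotype is pinned to its own optimum. The
  second phenotype has no linear cue product of its own, and because the
  first cue covaries with the second optimum, the population settles into an
  equilibrium that recruits the cross product $(u_1-c_1)(u_2-c_2)$ as a
  surrogate linear channel: the mean reference trait $\bar c_2$ is displaced
  from $\mu_{U2}$ and the cross slope $\bar b_{23}$ is materially nonzero at
  stationarity.
* Under `squared_sum`, selection acts on the summed deviation; the genuine
  linear slope $b_{11}$ absorbs all linear tracking of $\theta_1 + \theta_2$
  and the variance cost pins every other slope mean at zero.

Only the second form produces the experiment's defining stationary pattern —
a single nonzero slope mean, both reference traits assimilating to the new
mean cue, and full recovery of mean fitness after the step — so the `fig2`
preset uses `squared_sum` explicitly, while the constructor default remains
`sum_of_squares`. Both forms are available in `fitness_spec()` for
sensitivity analysis.

## Closed-form diagnostics

For the linear univariate norm $y = a + b(u - c) + e$:

* `variance_minimum_env()`: the cue value minimizing phenotypic variance,
  $u_0 = \bar c + (\bar b G_{bc} - G_{ab})/G_{bb}$, reducing to $\bar c$ when
  $G_{ab} = G_{bc} = 0$. The formula is treated as exact only in that stated
  case; `empirical_variance_curve()` provides the brute-force check (common
  random numbers across the grid, parabolic refinement of the argmin).
* `lande_reference_env()`: in the two-trait model with a fixed zero point,
  the implied reference environment is $-G_{ab}/G_{bb}$.
* `psd_slope_bound()` / `psd_elevation_bound()`: if one instead tried to move
  the reference by evolving the ratio $G_{ab}/G_{bb}$ to a target $r$,
  positive semidefiniteness ($|G_{ab}| \le \sqrt{G_{aa}G_{bb}}$) caps
  $G_{bb}$ at $G_{aa}/r^2$ and floors $G_{aa}$ at $r^2 G_{bb}$ — e.g. a
  ratio of 10 with $G_{aa} = 0.5$ forces $G_{bb} \le 0.005$, a drastically
  different system. This is the quantitative argument for preferring
  evolvable reference *traits* over an evolvable G matrix.

`equilibrium_summary()` reports time averages with batch-means standard
errors (robust to autocorrelation of the mean-trait series when batches are
longer than the mixing time; a window of length one is flagged as having an
undefined SE). `assimilation_metrics()` compares two stationary windows and
flags complete assimilation when slope means and mean fitness have returned
to pre-step values while the reference traits have moved by the realized
step in the mean cue.

## What the generator emulates — and what it does not

The synthetic experiments emulate: multinormal trait and environment
distributions, constant G and P, non-overlapping generations, one shared
environment per generation, and white environmental noise. They do not
emulate: autocorrelated or spatially structured environments, evolving
covariance matrices, finite-population drift (sampling noise here is an
estimator artifact, not biology), mutation, or biological constraints on
assimilation such as real plasticity costs. Passing tests therefore support
the correctness of the state propagation under the model's assumptions, not
the realism of those assumptions for any particular organism.

Values not fixed by the experiments themselves are package defaults, marked
in each preset's `notes`: the two-cue experiment's environment block
($\mu_U = (1,1)$, component variance 0.5, cue correlation 0.5,
development–selection correlation 0.8, optimum scale $B = 1$) and its
$\omega^2 = 10$; the univariate presets' fitness/environment block (borrowed
from the bivariate experiment's printed scalars, with $\mu_U = \mu_\Theta
= 6$). These were chosen once to give correlated cues, a cue–optimum
covariance, and weak stabilizing selection, and are not tuned thereafter.

## Numerical choices

* Positive semidefiniteness uses a relative eigenvalue tolerance of
  $10^{-10} \max(\mathrm{diag})$, so exact-boundary cases (zero matrices,
  pinned traits) validate cleanly.
* Sampling uses an eigendecomposition square root of $P_{aug}$, tolerant of
  singular (pinned-trait) states; the gradient is solved only on the
  positive-variance block, other components are exactly zero. A singular
  positive-variance block raises an error advising to drop the redundant
  traits.
* The initial mean state defaults to all zeros in the step experiment;
  simulations abort with a diagnostic if a mean becomes non-finite
  (typically a sign that $\omega^2$ is far too small for the trait scales).
* Trajectories store the initial state as generation 0 and one row per
  generation with the realized environment, $\bar W$, and gradient, so any
  analysis can be reproduced from the CSV alone.

## Known limitations

* **Selection-neutral directions random-walk.** In the bivariate step
  experiment both $b_{12}$ and $b_{22}$ multiply $(u_1 - c_1)^2$, one per
  phenotype. Under the squared-sum fitness only their sum is selected; the
  difference receives pure Monte-Carlo kicks, concentrated in the
  high-amplification transient right after the step. At $n = 5000$ the
  post-step window can retain a remnant of order 0.05–0.15 in each of
  $\bar b_{12}$ and $-\bar b_{22}$ (summing to ≈ 0) even though noise-free
  expectation propagation would keep both exactly zero. The acceptance test
  for the step experiment asserts the tight noise-free tolerances and may
  therefore fail on precisely these components; this is a property of the
  Monte-Carlo estimator at the prescribed sample size, not of the model.
  Raising $n$ shrinks the remnant like $n^{-1/2}$.
* At stationarity the phenotype distribution is slightly asymmetric
  (products of normal traits), so time-averaged means deviate from
  $\mu_\Theta$ and $\mu_U$ by a small amount independent of the means
  themselves; the equilibrium tests use 3 batch-means SEs, which covers the
  deviation at the tested sample sizes.
* The breeder's equation itself assumes multinormal traits each generation;
  strong nonlinearity or strong selection (mean steps much larger than
  $\omega$) pushes the model outside its derivation, visible as the
  transient fitness collapse discussed above.
* G and P are constant by construction; questions about evolving covariance
  structure are out of scope.
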