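---
title: "Costly Bayesian inference of a Bernoulli probability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Costly Bayesian inference of a Bernoulli probability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(costbayes)
```

## The model

An observer infers the head probability $p$ of a (possibly biased) coin from
a sequence of i.i.d. flips $x_1, x_2, \dots$, updating a belief
$\hat P_N(p)$ after each flip. Representing a probability distribution is
assumed to carry a cognitive cost $C[\hat P]$, so instead of the Bayesian
posterior the observer chooses, at every flip, the minimizer of

$$ L(\hat P_N) \;=\; D_{KL}(\hat P_N \,\|\, P_N) \;+\; \lambda\, C[\hat P_N],
   \qquad \lambda \ge 0, $$

where $P_N$ is the Bayesian target at flip $N$ and $\lambda$ — the only
parameter of the theory — sets the weight of the cost. The prior is uniform
on $(0,1)$.

**The sequential target.** We interpret $P_N$ as the *one-step* Bayes update
of the previous inferred belief: $P_N \propto \hat P_{N-1}(p)\,
p^{x_N}(1-p)^{1-x_N}$. The alternative reading — tempering the full-history
Bayesian posterior at each step — collapses to a single global tempering and
does not produce the filtered-count/power-profile structure derived below.
The package hard-codes the sequential reading, and
`sequential_inference(..., target = "full_data")` retains the other reading
solely to demonstrate the mismatch (see `cmd_oracle_check`); the
variational-oracle tests verify that the sequential reading reproduces both
closed forms to total variation below $10^{-5}$ on random instances.

### Precision cost

$C[P] = \int P \ln P\, dp$, the negative differential entropy: sharp beliefs
are expensive, the uniform belief is free. The per-flip optimum is the
tempered target $\hat P_N \propto P_N^{1/(1+\lambda)}$. Iterated from the
uniform prior this gives a Beta-shaped belief
$\hat P_N \propto p^{\hat n_1}(1-p)^{\hat n_0}$ in exponentially filtered
counts

$$ \hat n_1 = \sum_{k=0}^{N-1} r^{k+1} x_{N-k}, \qquad r = \tfrac{1}{1+\lambda}, $$

(and symmetrically for tails), equivalently the recursion
$\hat n_1' = r(\hat n_1 + x)$. Consequences, all exposed as functions and
covered by tests:

* the counts are bounded ($\hat n_1 + \hat n_0 < 1/\lambda$), so the
  posterior variance plateaus instead of vanishing — beliefs fluctuate
  forever (`posterior_variance`);
* the estimate $\hat p = (\hat n_1 + 1)/(\hat n_1 + \hat n_0 + 2)$ is
  confined to $[\lambda/(1+2\lambda),\,(1+\lambda)/(1+2\lambda)]$
  (`stationary_bounds`) and its long-run mean
  $E[\hat p] = (p+\lambda)/(1+2\lambda)$ *underestimates* the coin's bias
  (`expected_estimate`);
* in the stationary regime $\hat p$ is an AR(1) process with coefficient
  $1/(1+\lambda)$ and innovation gain $\lambda/((1+\lambda)(1+2\lambda))$
  (`ar1_parameters`); the recursion reproduces the exact update to
  $10^{-10}$;
* for $\lambda \ge 1$ a single flip always suffices to move $\hat p$ across
  $1/2$, so on a fair coin the sign of the inferred bias reverses with
  probability $1/2$ per flip and flight durations are geometric with mean 2.

**Expected posterior variance.** The long-run expectation of the Beta
variance follows from two facts: the count sum $S_N = \hat n_1 + \hat n_0$
is deterministic with limit $1/\lambda$, and the stationary filtered head
count has mean $p/\lambda$ and variance $p(1-p)/(\lambda(\lambda+2))$
(geometric sums of the filter weights). Substituting into
$E[(\hat n_1 + 1)(\hat n_0 + 1)]$ gives the closed form implemented in
`expected_posterior_variance`,

$$ E[\mathrm{Var}] \;=\;
   \frac{\lambda\,\bigl(\lambda(1+\lambda)(2+\lambda) + 2p(1-p)\bigr)}
        {(2+\lambda)(1+2\lambda)^2(1+3\lambda)}, $$

with limits $\lambda\,p(1-p)$ as $\lambda \to 0$ and
$\tfrac{1}{12}\bigl(1 - \tfrac{1}{3\lambda}\bigr) \to \tfrac{1}{12}$ (the
uniform-density variance) as $\lambda \to \infty$. Because printed renderings
of such expressions are easy to mis-parse, the package treats the
Monte-Carlo average of the exact per-sequence variance
(`mc_expected_posterior_variance`) as the source of truth: the test suite
requires the closed form to agree with it within three Monte-Carlo standard
errors at $\lambda \in \{0.05, 0.5, 5\}$, which it does (a variant of the
formula with coefficient 4 instead of 2 on the $p(1-p)$ term fails that
check decisively).

### Unpredictability cost

$C[P] = \int H(p) P(p)\, dp$ with $H(p) = -p\ln p - (1-p)\ln(1-p)$: beliefs
that imply an unpredictable environment are expensive. The per-flip optimum
multiplies the target by $e^{-\lambda H(p)}$; iterating from the uniform
prior gives

$$ \hat P_N(p) \propto \bigl[\varphi_{n/N}(p)\bigr]^N, \qquad
   \varphi_f(p) = p^f (1-p)^{1-f} e^{-\lambda H(p)}, $$

so the belief depends on the history only through the empirical frequency
$f = n/N$ and concentrates on the maxima of $\varphi_f$ as $N$ grows.
The derivative of $\log\varphi_f$ is
$(f-p)/(p(1-p)) + \lambda \ln\!\bigl(p/(1-p)\bigr)$; its curvature at
$p = 1/2$ for $f = 1/2$ equals $4(\lambda - 1)$, so the symmetric profile
undergoes a pitchfork bifurcation at $\lambda = 1$:

* $\lambda < 1$: a single maximum; on a fair coin the estimate converges to
  $1/2$;
* $\lambda > 1$: two maxima $p_<^\lambda = 1 - p_>^\lambda$
  (`fixed_points`; e.g. $0.102/0.898$ at $\lambda = 2$). The global maximum
  sits above $1/2$ exactly when $n > N/2$, so the inferred bias tracks the
  sign of the random walk $n - N/2$ and *never converges*: even an
  infinitesimal empirical bias is amplified to an appreciable inferred bias
  (`asymptotic_estimate`).

On a fair coin the walk's sojourn statistics are arcsine-distributed, so a
run typically spends most of its time on one "majority" belief; the
expected majority-side fraction is the folded-arcsine mean
$1/2 + 1/\pi \approx 0.818$ (`folded_arcsine_mean`,
`switch_fraction_unpredictability`).

## The variational oracle

`minimize_loss` minimizes $L$ directly over the simplex of grid masses by
exponentiated-gradient (mirror-descent) updates
$q \leftarrow q\,e^{-\eta \nabla L}/Z$. The objective is convex over the
simplex for both costs, the iteration preserves positivity and
normalization, and the step starts at $\eta = 1/(1+\lambda)$ — the natural
curvature unit, since the KL term contributes Hessian $1/q$ and the
precision cost adds $\lambda/q$ — with halving on any loss increase.
Convergence is declared when the largest component of the simplex-projected
gradient falls below $10^{-10}$ (iteration cap $10^5$; descent steps are
accepted up to $10^{-13}$ relative loss noise so the iteration terminates
cleanly at the numerical floor). For the precision cost this step is exact
and the minimizer converges in one iteration; for the unpredictability cost
it contracts geometrically (tens to hundreds of iterations at the tested
$\lambda$). The oracle exists to show, without using the closed forms, that
they are the true optima — `oracle_check` reports per-flip total-variation
distances, required to be below $10^{-5}$.

## Numerical choices

* **Grid.** Densities on $p \in (0,1)$ are midpoint-rule cell masses; the
  default resolution is $K = 2001$ — odd, so $p = 1/2$ is a representable
  cell center, which symmetric fair-coin profiles require. Endpoints are
  excluded so $\ln p$, $\ln(1-p)$ stay finite; $H(0)=H(1)=0$ by the limit
  convention only in `bernoulli_entropy`. Entropy on the grid is
  $\sum m_i \ln(m_i K)$, exactly zero for the uniform density and equal to
  the KL divergence to uniform; normalization is enforced to $10^{-10}$,
  functional identities tested at $10^{-8}$.
* **Log space.** The $N$-th power in the unpredictability posterior is
  computed as $N \log\varphi$ with max-subtraction before exponentiation;
  $N$ up to $10^6$ is safe.
* **Root-finding.** Profile maxima are bracketed by sign changes of the
  derivative on a 4001-point scan and refined by `uniroot` to $10^{-12}$;
  the fair-coin fixed point uses the bracket $(1/2 + 10^{-9}, 1 - 10^{-9})$,
  where the derivative crosses zero exactly once for $\lambda > 1$. The
  frequency $f$ is always the exact rational $n/N$, never a grid value.
  For long trajectories `estimate_profile` interpolates the argmax curve
  (1024 nodes per half-interval, separately on each side of the
  $f = 1/2$ discontinuity; interpolation error below $10^{-4}$).
* **Ties and hysteresis.** An estimate exactly at $1/2$ (possible at
  $\lambda \ge 1$ for the precision observer, and at $n = N/2$ for the
  unpredictability observer) inherits the previous sign, and a walk value
  of exactly 0 inherits the previous side — the classical sojourn
  convention, and the reading under which a belief switches only when the
  walk actually crosses zero. At $\lambda = 1$ the extreme state lands
  exactly on $1/2$ after one opposing flip, so the convention is
  load-bearing and is fixed package-wide. `asymptotic_estimate` reports an
  exact tie (symmetric $f = 1/2$, $\lambda > 1$) as both locations with a
  `tie` attribute rather than choosing silently.
* **Censoring.** The final flight of a trajectory is right-censored by the
  end of the run and is excluded from duration statistics; the first flight
  starts at flip 1 under the uniform prior and is kept by default
  (`censor = "both"` drops it too; the geometric-law and mean-duration
  results are insensitive to the choice).
* **Burn-in.** Stationary-regime statistics of the precision observer
  discard the first $\lceil 10(1 + 1/\lambda)\rceil$ flips (geometric
  convergence of the filter sum); fair-coin switching statistics use a
  100-flip burn-in, and results are insensitive to doubling it.

## The synthetic generator and what the tests show

`simulate_coin` draws i.i.d. Bernoulli flips with fixed $p$ — exactly the
stationary environment the theory assumes; ensemble commands derive per-run
seeds by unit increments from a base seed, so every pipeline output is
byte-reproducible from its configuration. Real behavioral or environmental
data would add features deliberately absent here — non-stationary $p$,
serial dependence, observation noise, finite attention — so passing tests
certify the *model's* internal mathematics (closed forms, bifurcation,
sojourn laws), not the model's fit to any empirical data.

Scales used by the test suite and the acceptance script (chosen so each
statistic's Monte-Carlo error sits well inside its assertion band): flight
statistics from $10^6$ flips; AR(1) and mean-estimate recovery from $10^5$
flips with block-mean standard errors; expected-variance oracle from 200
sequences of $10^4$ flips; sojourn ensembles of 5000 walks and 2000
observer runs of $10^4$ steps.

## Known limitations

* Only the uniform prior is implemented (as the theory specifies); there is
  no hierarchical or informative-prior machinery.
* $\lambda$ is a given constant — the package simulates observers, it does
  not fit $\lambda$ to data.
* Environments are stationary Bernoulli; volatile or non-binary settings
  are out of scope.
* The two shipped costs are the precision and unpredictability penalties;
  `minimize_loss` accepts only these tags (the minimizer itself is generic,
  but no plug-in cost interface is exposed).
* Finite-$N$ corrections to the maxima locations of the unpredictability
  posterior are handled by grid evaluation, not analytically; transient
  behavior near $N \approx \varepsilon^{-2}$ for a nearly fair coin is
  exercised only by simulation.
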