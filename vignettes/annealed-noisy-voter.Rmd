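---
title: "The noisy voter model on networks: annealed theory, simulation and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The noisy voter model on networks: annealed theory, simulation and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noisyvoter)
```

## The model

Each of $N$ nodes of an undirected simple graph carries a binary state
$s_i \in \{0, 1\}$. Node $i$ flips its state at rate

$$\pi_i = a + \frac{h}{k_i} \sum_{j \in nn(i)} \mathbf{1}[s_j \neq s_i],$$

the sum running over its $k_i$ neighbours: a spontaneous ("noise") term
with rate $a$ and a pairwise copying ("herding") term with rate $h$ per
unit of disagreeing-neighbour fraction. With $a = 0$ and time in units of
$1/h$ this is the classical voter model, with its two absorbing
consensus configurations; any $a > 0$ restores ergodicity. Because one of
the two rates can always be absorbed into the time unit, the only
relevant parameter is $a/h$; the package keeps both explicit and the
numerical material fixes $h = 1$.

The aggregate observable is $n = \sum_i s_i$. Two exact facts anchor
everything else. First, on a complete graph $n$ is itself a birth--death
chain whose stationary law is a symmetric beta-binomial, exactly uniform
on $\{0,\dots,N\}$ at $a = h/(N-1)$; this fixes the prefactor convention
of the rates (a convention with noise rate $a/2$, or an interaction term
not normalized by $k_i$, would displace this point away from the
mean-field critical value $h/N$). `birth_death_stationary()` implements
this chain and the package's tests use it as a transcription gate.
Second, the drift of $n$'s conditional mean closes at rate $2a$ on the
complete graph, so its autocorrelation there is a pure exponential
$e^{-2a\tau}$.

The competition between copying (ordering) and noise (disordering)
produces a finite-size transition in the stationary distribution of
$n$: bimodal with peaks at $0$ and $N$ for small $a$, unimodal around
$N/2$ for large $a$. Following the standard criterion, the critical
point is the noise level at which the stationary variance of $n$ equals
the discrete-uniform value $N(N+2)/12$; the distribution is indeed
uniform there in the cases we have checked numerically.

## The annealed approximation

For uncorrelated networks of the configuration ensemble (structural
cutoff $k_{max} \le \sqrt{\mu_k N}$), the adjacency matrix can be
replaced by the expected connection probabilities
$w_{ij} = k_i k_j / (N \mu_k)$, turning the fixed graph into a weighted
fully-connected one while preserving every node's degree:
$\sum_j w_{ij} = k_i$ up to the excluded self-term $k_i^2/(N\mu_k)$,
which is $O(1/N)$. The package adopts $w_{ii} = 0$ throughout
(`annealed_weights()`); we verified algebraically that the moment
equations are unchanged if the self-term is instead retained, so the
convention is immaterial at the order of the results.

Under these weights the flip rates depend on the configuration only
through the degree-weighted magnetization
$m = \sum_j k_j s_j / (N\mu_k)$: an up-flip has rate $a + hm$, a
down-flip $a + h(1-m)$. The first- and second-moment equations then
close. Writing $\lambda = h/(2(2a+h))$ and
$g = \langle k^2\rangle/\mu_k^2 = 1 + \sigma_k^2/\mu_k^2$, the
stationary solution worked out in the package is

$$\tilde V/\mu_k^2 = \frac{(Ng/4)\,(2a+h)(4a+h)}{2a(4a+h) + h^2 g/N},
\qquad
S_1 = \frac{N/4 + \lambda \tilde V/\mu_k^2}{1-\lambda},
\qquad
\sigma^2_{st}[n] = \frac N4 + \frac{h}{2a+h}\,S_1,$$

where $\tilde V$ is the degree-weighted covariance sum
$\sum_{ij} k_i k_j \sigma_{ij}$ and $S_1 = N\,\mathrm{Cov}_{st}(n, m)$
is the weight of the slow aggregate mode. The denominator condition
$2a(4a+h) + h^2 g/N > 0$ is the necessary and sufficient condition for a
stationary fluctuation balance; it always holds for $h > 0$. At exactly
$a = 0$ there is no stationary balance and `variance_st()` returns the
voter limit $N^2/4$ with `validity_ok = FALSE`.

The closed form interpolates between $N^2/4$ (voter limit, $a \to 0$)
and $N/4$ (independent spins, $a \to \infty$) for every degree
distribution, and increases with $g$ at every finite $a$: degree
heterogeneity amplifies aggregate fluctuations. Three independent
oracles validate it in the tests: the exact birth--death chain (relative
error $\le 4/N$ on complete graphs), the full $2^N$ master-equation
solver `ctmc_solve()` on arbitrary small graphs, and direct Gillespie
simulation on ER, dichotomous and complete graphs.

## Asymptotic branches, crossover and critical point

A first-order treatment in $N$ splits into two regimes according to
whether $aN$ is below or above $O(\sqrt N)$:

$$\sigma^2_{small}(a) = \frac N4 + \frac{h N^2 g}{4\,(2aN + hg)},
\qquad
\sigma^2_{large}(a) = \frac N4 + \frac{Nh}{2(4a+h)} +
  \frac{h^2 N g}{8a(4a+h)}.$$

Both are explicit functions of the normalized heterogeneity alone. The
crossover $a^*$ between them is defined as the minimizer of
$|\log \sigma^2_{small} - \log \sigma^2_{large}|$; `crossover_a()`
locates it by a 400-point logarithmic grid scan plus bracketed
refinement to $10^{-6}$ relative tolerance (the definition fixes no
tolerance, so we chose one well below every use of $a^*$). For the
Barabási--Albert ensemble at $N = 2500$, $h = 1$, mean degree 8, with
ensemble-averaged empirical moments over 20 graphs, this gives
$a^* \approx 0.0144$; the value is insensitive to the ensemble
fluctuations of $g$ (it moves by under $1\%$ for $g \in [2.0, 2.3]$, so
single-network and ensemble-averaged moments give practically the same
crossover). $a^*$ scales as $h N^{-1/2}$ at fixed $g$ and is exactly
proportional to $h$. Two caveats are worth recording. First, for
vanishing heterogeneity the two branches approach each other
monotonically as $a$ grows and never cross, so the minimizer runs to the
search boundary; `crossover_a()` warns in that case. Second, the
additive $N/4$ in the small-$a$ branch matters: dropping it (or keeping
the $3N/4$ that a different grouping of the $O(N)$ terms suggests)
moves $a^*$ by tens of percent; the grouping above is the one retained
throughout the package, chosen together with the rate convention when
the closed forms were frozen.

Solving $\sigma^2_{small}(a_c) = N(N+2)/12$ gives the critical point in
closed form,

$$a_c = \frac{h\,g\,(2N+1)}{2N(N-1)} \approx \frac hN\left(1 +
\frac{\sigma_k^2}{\mu_k^2}\right),$$

linear in the degree variance at fixed $N$, $h$, $\mu_k$, against the
mean-field $a_c = h/N$ which carries no network dependence beyond size.
The transition remains a finite-size effect. For the package's matched
ensembles at mean degree 8 (ER with $\sigma_k^2 \approx 8$, dichotomous
with degrees 4 and 12 in equal halves, $\sigma_k^2 = 16$) the predicted
ratio of critical points is about $1.11$; under the linear law above, an
equal-halves dichotomous graph can never exceed twice the ER value,
because its heterogeneity is bounded by $(1 - 1/\mu_k)^2 < 1$ while the
intercept term is common. Larger shifts require substantially heavier
degree tails than a two-valued equal-split sequence can produce.

## Interface density

The local order parameter $\rho$ is the fraction of edges joining
disagreeing nodes (0 = consensus, 1/2 = random states), always computed
on the real adjacency. Through the annealed weights its stationary mean
reduces to a function of the variance:

$$\langle\rho\rangle_{st} = \frac12 - \frac{g}{2N} -
\frac{2(4a+h)}{hN^2}\left(\sigma^2_{st}[n] - \frac N4 -
\frac{Nh}{2(4a+h)}\right),$$

clamped to $[0, 1/2]$ (the raw expression undershoots 0 by $O(1/N)$ as
$a \to 0$). It is exact in the limits ($0$ as $a \to 0$, $1/2$ as
$a \to \infty$) and decreases with heterogeneity, but for intermediate
noise it disagrees with simulations on real networks by design: the
annealed view erases precisely the local structure $\rho$ measures.
`rho_st()` should be read as the annealed prediction, not as a
quantitative estimate in that regime, and the tests deliberately do not
assert agreement there.

## Autocorrelation and the inference problem

Under the annealed dynamics the conditional mean of $n$ relaxes through
exactly two modes: the degree-weighted magnetization at rate $2a$ and
the individual deviations from it at rate $2a + h$. Hence

$$K_{st}[n](\tau) = S_1 e^{-2a\tau} +
\left(\sigma^2_{st}[n] - S_1\right) e^{-(2a+h)\tau}.$$

For homogeneous degrees $S_1 = \sigma^2_{st}[n]$ up to $O(1/N)$ and the
fast component vanishes — the mean-field single exponential, confirmed
by lattice simulations. For heterogeneous degrees $S_1$ *exceeds* the
variance, so the fast weight is negative: in log-linear scale the
normalized autocorrelation starts with a shallower slope and settles
parallel to $e^{-2a\tau}$ with a positive vertical offset
$\log(S_1/\sigma^2)$ that grows with heterogeneity. (A formulation in
which both weights are positive is not consistent with this offset; the
package follows the derivation.) The two-class annealed simulator
`simulate_nvm_annealed()` — exact for the annealed dynamics, $O(1)$ per
event — reproduces this mixture to within sampling error and is the
independent check on $S_1$.

Because the exponents $2a$ and $2a+h$ are different functions of the two
rates, and the weights carry $\sigma_k^2/\mu_k^2$, the triple
$(a, h, \sigma_k^2/\mu_k^2)$ can be inferred from the aggregate series
alone, given $N$. `fit_acf()` implements this with the amplitudes tied
to the closed forms: the free parameters are exactly $(a, h,
\text{het})$, the modelled curve is the normalized mixture above, and a
log-scale penalty matches the observed $K(0)$ to the modelled variance.
Weighted least squares uses weights $\propto 1/\tau$ (the sampling
variance of short-lag autocorrelation estimates grows linearly in the
lag), the fit window ends at the noise floor (three times the noise
level estimated from the last quarter of the supplied curve), and the
initializer is deterministic: tail slope for $a$, a fixed coarse grid
for $(h, \text{het})$. Fitting both asymptotic regimes separately is
unnecessary in this parametrization; the branch consistent with the
fitted noise level relative to $a^*(h, \text{het})$ is reported as
`branch_used`.

Identifiability deserves honesty. The tail slope pins $a$ sharply. The
variance level pins the product $h(1 + \sigma_k^2/\mu_k^2)$ sharply.
Splitting that product requires the fast component, whose relative
weight $S_1/\sigma^2 - 1$ is below $2a/(2a+h)$ for any heterogeneity —
under $1\%$ in the small-noise regime of the headline protocol. Three
consequences, all visible in the package's numerical experiments:

* On noiseless theory curves the inversion is exact (the round-trip
  tests recover all three parameters to $10^{-4}$ relative across a
  parameter grid).
* Under the annealed dynamics itself the estimator is Monte-Carlo
  consistent: over 20 replicates of the two-class simulator in an
  identifiable regime ($a = 0.1$, degrees $\{4, 20\}$, $N = 1200$),
  the median estimates recover $a$ to a few percent and the
  heterogeneity to well within 30%.
* On real dichotomous graphs at the reference protocol ($a = 0.01$,
  degrees $\{4, 12\}$, $N = 2500$) two model errors intrude: the
  annealed variance overestimates the simulated one by roughly 12%,
  and the real early-lag autocorrelation contains fast local structure
  beyond the two annealed modes. The fit absorbs these into a
  heterogeneity estimate biased upward and an interaction rate biased
  downward (typically $h \approx 0.7$ instead of 1, with $a$ still
  recovered to a few percent). A fitted $h$ somewhat below its true
  value is thus the expected signature of the annealed approximation at
  this protocol, not a failure of the optimizer; the magnitude of the
  bias grows with the variance overestimation (on a 2D lattice, where
  the annealed view is poorest, the fitted $h$ halves).

## Generators and study conditions

The ensembles are matched on mean degree $\langle k\rangle = 8$ so they
differ only in heterogeneity: ER with edge probability $8/(N-1)$
(regenerated while isolated nodes occur, since the rates divide by
$k_i$), BA with attachment count $m = 4$ grown from a complete seed of
$m+1$ nodes, dichotomous with equal halves of degrees 4 and 12
(heterogeneity $0.25$), random-regular, complete, and the periodic 2D
lattice as the zero-heterogeneity reference. Dichotomous graphs are
drawn with the Viger--Latapy uniform simple-graph sampler rather than
raw stub matching: for $N = 2500$ nodes with these degrees the
probability that a raw configuration draw is simple is around
$e^{-10}$, so rejection sampling is not viable, while the VL sampler
draws uniformly from the simple connected graphs with the exact degree
sequence. No constraint beyond simplicity is imposed to suppress degree
correlations; `check_uncorrelated()` reports the realized assortativity
and structural-cutoff status.

What the generated data do and do not emulate: configuration-ensemble
graphs are uncorrelated by construction, so passing tests say nothing
about degree-assortative, clustered, weighted or temporal networks; the
lattice deliberately violates the uncorrelated-ensemble assumption and
is used only where exact statements survive (the $e^{-2a\tau}$ tail).
All trajectories start from i.i.d. Bernoulli(1/2) states unless stated,
and stationary averages discard an initial transient of $N$ time units,
pooling time and ensemble averages.

## Numerical choices

The simulator is an event-driven Gillespie algorithm: per-node rates in
a Fenwick tree ($O(\log N)$ selection), incremental disagreement counts
(so one event costs $O(k_i \log N)$), exponential waiting times, and
observables sampled on a fixed grid by carrying the last value forward
— unbiased for time averages of a piecewise-constant process. Rate sums
are rebuilt every $2^{21}$ events to cap floating-point drift. Model
time is the CTMC's own clock; one unit corresponds to roughly $N$
flips. A frozen configuration ($a = 0$ at consensus) simply stops
producing events and the remaining grid is filled with the constant
state. Seeds map one-to-one onto trajectories through R's RNG, with
realization and graph indices offsetting the base seed so ensembles are
reproducible as a whole.

The exact solvers order the $2^N$ configurations by bit-encoding with
node 1 in the least significant bit; the stationary vector comes from a
sparse linear solve with a normalization row replacing one balance
equation, and relaxation rates from a dense eigendecomposition (kept to
$N \le 10$ by default). The $a = 0$ case returns the absorbing
decomposition rather than regularizing a singular solve.

Problem sizes in the tests were chosen to keep the full suite around
two minutes on one core while leaving each assertion statistically
comfortable: exactness checks at $N \le 10$ against $2^N$ solvers,
limit checks at $N = 400$, ACF and inference checks at $N$ between 900
and 2500 with horizons of $6\,000$–$15\,000$ time units, and the
acceptance script runs the inference protocol at eight networks, one
realization and $30\,000$ units — a reduced version of the full-scale
study design (ten networks, two realizations, $200\,000$ units) that
keeps the noise-rate estimate sharp while accepting more spread in the
interaction rate.

## Known limitations

* The annealed closed forms systematically overestimate the simulated
  variance on real networks at intermediate noise (the only
  approximation involved is the annealed one); the bias is a few
  percent for ER and grows with structural correlation, reaching a
  factor of two on the 2D lattice.
* $\langle\rho\rangle_{st}$ is unreliable at intermediate noise, as
  discussed above.
* The interaction rate inferred from aggregate autocorrelations
  inherits the variance bias; its heterogeneity companion is only
  identifiable when the fast component rises above the sampling noise
  of the autocorrelation estimate.
* The variance bound $\sigma^2_{st}[n] \le N^2/4$ is respected only up
  to an additive $O(N)$ term near $a = 0$, a harmless artifact of the
  expansion order.
* Exact solvers stop at $N = 12$; beyond that the simulator is the
  only ground truth.
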