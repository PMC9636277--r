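---
title: "Direct reciprocity in group-structured populations: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct reciprocity in group-structured populations: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grouprecip)
```

## The repeated game

The unit of interaction is the infinitely repeated donation game. In each
round both players choose to cooperate (pay cost $c = 1$ so the partner
receives benefit $b > 1$) or defect. Strategies are memory-1: a vector
$\mathbf p = (p_{CC}, p_{CD}, p_{DC}, p_{DD})$ of cooperation probabilities
conditioned on the previous round's outcome, written from the focal player's
perspective. Implementation errors flip the intended action with probability
$e$, so the strategy actually played is $(1-e)\mathbf p + e(1-\mathbf p)$.

For an ordered pair the round outcomes form a Markov chain on
$\{CC, CD, DC, DD\}$. For $e > 0$ every transition probability is positive,
the chain is primitive, and the unique stationary distribution $\mathbf v$
gives cooperation levels $\gamma_{pq} = v_{CC} + v_{CD}$,
$\gamma_{qp} = v_{CC} + v_{DC}$ and long-run payoffs
$\pi_{pq} = b\,\gamma_{qp} - c\,\gamma_{pq}$. `pair_game()` computes
$\mathbf v$ by a direct linear solve of $\mathbf v (T - I) = 0$ with the
normalization row replaced — not by power iteration — so results are
deterministic and reproducible to machine precision. The same quantity is
available through a Press–Dyson determinant ratio
(`cooperation_determinant()`); the two routes agree to $10^{-10}$ for all
$16 \times 16$ ordered deterministic pairs at $e = 10^{-3}$, which the test
suite checks. The 16 deterministic strategies are numbered by a 4-bit id
(bit $k$ = 1 means defect at outcome $k$, in CC, CD, DC, DD order), so
$S_0$ = AllC, $S_6$ = WSLS, $S_{10}$ = TFT, $S_{14}$ = Grim,
$S_{15}$ = AllD.

## Exact error-free limits

Without errors many deterministic pairs produce reducible chains (Grim
against itself has two absorbing outcome classes), so the $e = 0$ game has
no unique stationary distribution and `stationary_distribution()` refuses it
with a dedicated condition class. The physically meaningful object is the
limit $e \to 0^+$ of the perturbed chain. Because every perturbed entry is
$e$ or $1 - e$, each entry of the Press–Dyson determinant is a degree-1
integer polynomial in $e$; the determinant is therefore a polynomial with
small integer coefficients, exact in double precision. `pair_game_limit()`
and `self_cooperation_limit()` expand these polynomials, and the limit of a
ratio is the ratio of the lowest-order non-vanishing coefficients — an exact
rational. This is how the package states, for example, that $S_2$ cooperates
with itself three quarters of the time in the rare-error limit, as the
fraction $3/4$ rather than $0.7499\ldots$:

```{r}
self_cooperation_limit("S_2")
```

Two classifications are defined on this limit. A strategy is a **rival** if
$\pi_{pq} \ge \pi_{qp}$ against every deterministic opponent; the check runs
on the exact limit payoffs because the defining equalities (for instance
TFT's payoff fairness) hold exactly only there — at $e > 0$ they are broken
by $O(e)$, which would make any fixed small tolerance either too strict or
meaningless. The comparison against WSLS uses the same limits; its sign is
independent of $b$, which the tests verify at $b \in \{1.5, 3, 6\}$. Only
deterministic memory-1 opponents are examined; a rival certificate against
this finite set does not preclude a stochastic or longer-memory strategy
from beating the focal strategy, which is a known limitation of the
classification.

## Evolutionary dynamics

A population of $M$ groups of $N$ players evolves by pairwise comparison:
the focal player imitates a role model with the Fermi probability
$f = 1/(1 + \exp[\sigma(\pi_{\text{focal}} - \pi_{\text{role}})])$, with
selection strength $\sigma_{\text{in}}$ for in-group and
$\sigma_{\text{out}}$ for out-group comparisons; mutation replaces the
strategy uniformly at random. Payoffs within a mixed group of $i$
$p$-players and $N - i$ $q$-players are the pairwise payoffs averaged over
the $N - 1$ co-players (`mixed_group_payoffs()`); the boundary cases $i = 0$
and $i = N$ are deliberately outside the contract since a lone type has no
co-player of the other type and the fixation formulas never need them.

**Complete separation of time scales.** When mutation is much rarer than
out-group imitation, which is much rarer than in-group imitation, at most
two strategies coexist and each group is homogeneous except during brief
takeovers. The fixation probability of a single in-group mutant is the
standard birth–death expression, a sum of $N$ exponentials whose exponents
grow like $\sigma_{\text{in}} N$; `fixation_probability()` evaluates it as
$\exp(-\operatorname{logsumexp})$ so that $\sigma_{\text{in}} = 10$,
$N = 120$ (exponents of order $10^3$) neither overflows nor silently
saturates. Group-level competition multiplies an out-group Fermi factor on
the groups' self-payoffs by the immigrant's fixation probability;
population-wide fixation $\Psi_{pq}$ divides by a geometric sum in the
ratio $\eta$ of backward to forward group-level rates, again via
log-sum-exp, which makes the $\eta = 1$ case an ordinary evaluation rather
than a special branch.

Fixation times are the one place where the textbook closed forms are
numerically treacherous: near $\eta = 1$ their numerators cancel to second
order and lose all precision. The package instead evaluates the defining
double sums over the group-count chain term-by-term in the log domain
($O(M^2)$ work, continuous in $\eta$, overflow raises an explicit
numeric-range error). The closed forms survive as test oracles: for
$M \le 4$ the times are checked against direct linear solves of the
absorbing chain to $10^{-8}$. The reported unit is one out-group imitation
event; these times can be astronomically large (a WSLS mutant facing AllD
groups at $\sigma = 10$ needs $\sim 10^8$ events at $M = 2$), and the model
itself is silent on whether the separation assumption still holds at such
scales, so the package reports the number without asserting regime
validity.

Whether selection favors $p$ over $q$ reduces to a linear criterion in the
four pairwise payoffs. `is_favored()` reports its sign with an absolute
zero-band of $10^{-9}$: exactly neutral pairs (mirror-image strategies)
produce floating-point residues up to $\sim 10^{-13}$ after amplification by
$\sigma N$, while the smallest genuine effects at the baseline parameters
are of order $\sigma N e \approx 10^{-2}$, so the band separates the two
regimes by many decades. With $\sigma_{\text{in}} = \sigma_{\text{out}}$ the
criterion depends on $(N, M)$ only through the product $MN$; the tests
verify the sign is identical across all fifteen factorizations of
$MN = 120$ for every strategy pair.

**Monte Carlo of the resident chain.** `run_resident_chain()` simulates the
embedded chain of homogeneous resident populations: per step a uniform
mutant (self-draws allowed — they waste a step but leave the stationary law
unchanged) replaces the resident with probability $\Psi$. All
$|\mathcal S|^2$ fixation probabilities are computed once and cached; the
loop itself is compiled code driven by R's RNG, so a seed reproduces runs
bit-for-bit. The exact stationary distribution of the same chain
(`resident_chain_exact()`) is kept as a cross-check; it underflows sooner at
strong selection, which is why simulation is the primary path.

**Partial separation.** When mutation and out-group imitation are
comparable ($r = \nu / (\nu + \mu_{\text{out}})$), groups remain homogeneous
but the population is polymorphic. In the large-$M$ limit the group-strategy
frequencies follow a replicator–mutator equation whose selection part uses
antisymmetric pairwise flow coefficients and whose mutation part injects
uniform mutants weighted by in-group fixation. `solve_fixed_point()`
integrates this system with `deSolve::lsoda` in chunks, renormalizing onto
the simplex between chunks, until $\|\dot x\|_\infty$ falls below `tol`
(default $10^{-10}$); direct iteration of the stationarity relation is
ill-posed as $r \to 0$, so integration is the primary path and the algebraic
fixed-point relation — obtained by solving the stationarity condition for
each component, $x_p = r \sum_q \rho_{pq} x_q / |\mathcal S| \big/
(r \sum_q \rho_{qp}/|\mathcal S| - (1-r) \sum_q \alpha_{pq} x_q)$ — is used
only as a residual check. Non-convergence by `t_max` raises an error
carrying the last state; nothing is returned silently. The finite-$M$
group-level Monte Carlo (`group_level_mc()`) simulates the same process
directly and agrees with the fixed point within sampling error at
$M = 100$.

## Parameters and defaults

| parameter | meaning | default | rationale |
|---|---|---|---|
| $b$ | benefit of cooperation ($c = 1$) | required | the central control parameter; thresholds of interest sit at $b = 2, 3, 5$ |
| $e$ | implementation error rate | $10^{-3}$ | small enough to stay near the rare-error limit, large enough to keep every chain primitive |
| $\sigma_{\text{in}}, \sigma_{\text{out}}$ | selection strengths | 10 | strong-selection baseline for the complete-separation regime |
| $\sigma$ (partial sep.) | both strengths | $30/(b-1)$ | scales selection with the payoff range so the dynamics' time scale is comparable across $b$ |
| steps | resident-chain MC steps | $10^6$ (tests use $10^5$) | long runs with 10% burn-in; the reproduction tests use the scaled size, at which the qualitative orderings are far outside Monte Carlo error |
| sweeps | group-level MC sweeps ($M$ steps each) | $10^4$–$10^6$ | $2 \times 10^4$ sweeps at $M = 100$ put mean-cooperation estimates well within $\pm 0.02$ |
| $r$ | relative mutation probability | required | $r \lesssim 0.1$ is the regime where cooperation plateaus near $1/2$ |

## What the simulations do and do not show

The Monte Carlo components generate synthetic evolutionary trajectories
under the model's own assumptions: infinitely repeated games, payoffs known
exactly, homogeneous groups between takeovers, uniform mutation over the 16
deterministic memory-1 strategies. Passing tests therefore demonstrate
internal consistency (simulation against exact chain solutions, ODE against
finite-$M$ simulation) and reproduction of the model's analytic
predictions — not that real populations behave this way. In particular the
model excludes finitely repeated or discounted games, strategies with longer
memory (where "friendly rival" strategies exist that are simultaneously
efficient and unbeatable), heterogeneous group sizes, overlapping group
membership, and any crossover regime between the two time-scale limits; the
order in which the limits are taken matters, and the $r \to 0$ limit of the
partial-separation dynamics need not coincide with the complete-separation
results.

## Numerical conventions, in brief

* All sums of exponentials (fixation probabilities, $\eta$-geometric sums,
  fixation times) go through log-sum-exp; raw powers $\eta^M$ are never
  formed.
* Stationary distributions of small chains are direct linear solves with a
  normalization row; degenerate (reducible) chains raise a condition rather
  than returning one of many stationary vectors.
* Exact limits use integer polynomial arithmetic; every coefficient stays
  far below $2^{53}$, so doubles are exact.
* Brute-force linear-system oracles are themselves ill-conditioned when the
  probabilities they compute fall below $\sim 10^{-12}$; equivalence tests
  against them run at moderate selection strengths where both routes are
  accurate.
* Every stochastic routine takes an explicit integer seed and uses R's RNG
  stream end-to-end (including the compiled loops), so identical seeds give
  identical output across platforms.
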