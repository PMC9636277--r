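# grouprecip

Evolutionary dynamics of direct reciprocity in group-structured populations.

People reciprocate mostly within their own community: repeated interactions
happen inside groups, while strategies can still spread between groups by
imitation. `grouprecip` implements a game-theoretic model of this situation
and asks when group structure helps or hurts the evolution of cooperation,
compared to a well-mixed population of the same total size.

## The model

Pairs play an infinitely repeated **donation game**: cooperating pays cost
`c = 1` and gives the partner benefit `b > 1`, so the one-shot payoff matrix
is `((b-1, -1), (b, 0))`. Players use **memory-1 strategies**
`p = (p_CC, p_CD, p_DC, p_DD)` — cooperation probabilities conditioned on the
previous round's outcome — and implement them with an error rate `e`
(effective strategy `(1-e)p + e(1-p)`). For a pair `(p, q)` the game is a
4-state Markov chain over outcomes; its stationary distribution `v` gives
cooperation levels `γ_pq = v_CC + v_CD`, `γ_qp = v_CC + v_DC` and payoffs
`π_pq = b·γ_qp − c·γ_pq`. The 16 deterministic strategies `S_0 .. S_15`
(AllC, ..., WSLS, ..., TFT, ..., AllD) form the evolving strategy space.

A population of `M` groups of size `N` evolves by a pairwise-comparison
process: a focal player imitates a role model with the Fermi probability
`1 / (1 + exp(σ (π_focal − π_role)))`, where the role model comes from the
same group (selection strength `σ_in`), from another group (`σ_out`), or the
player mutates to a random strategy. Two regimes are tractable:

* **Complete separation of time scales** (mutation ≪ out-group ≪ in-group
  imitation): the population is homogeneous between rare invasion attempts.
  The package provides exact intra-group fixation probabilities `ρ_pq`
  (closed-form sum over the birth–death chain, evaluated in the log domain),
  population-wide fixation probabilities `Ψ_pq`, fixation times, the
  favored-strategy criterion, and Monte Carlo simulation of the embedded
  resident→mutant chain.
* **Partial separation** (mutation and out-group imitation comparable):
  groups stay homogeneous but the population is polymorphic. The package
  integrates the replicator–mutator equation for group-strategy frequencies
  (large-`M` limit) and simulates the finite-`M` group-level chain.

Error-free limits (`e → 0`) of cooperation levels and payoffs are computed
*exactly*, by integer polynomial arithmetic in `e` on a Press–Dyson-style
determinant, so quantities such as self-cooperation levels come out as
rationals (e.g. `3/4`), not floating-point approximations.

## Worked example

```r
library(grouprecip)

# the 16 deterministic strategies: exact self-cooperation in the rare-error
# limit, rival status, and the comparison against Win-Stay Lose-Shift
strategy_profile()
#> # A tibble: 16 × 10
#>       id label actions  p_cc ... self_coop self_coop_num self_coop_den rival vs_wsls
#>    0     AllC  CCCC     1        1         1             1             FALSE -
#>    6     WSLS  CDDC     1        1         1             1             FALSE 0
#>   10     TFT   CDCD     1        0.5       1             2             TRUE  0
#>   15     AllD  DDDD     0        0         0             1             TRUE  +

# a lone TFT mutant in a group of two AllD players is exactly neutral:
# TFT equalizes payoffs, so its fixation probability is 1/2
fixation_probability("TFT", "AllD", N = 2, b = 1.5, sigma_in = 10, e = 0)
#> [1] 0.5

# in a well-mixed population of 120 the same invasion is much harder
fixation_probability("TFT", "AllD", N = 120, b = 3, sigma_in = 10, e = 1e-3)
#> [1] 0.1809116

# stationary strategy abundances under rare mutations, intermediate benefit:
# the well-mixed population learns WSLS and cooperates almost fully,
# the fully group-structured population does not
mixed  <- run_resident_chain(N = 120, M = 1, b = 3, steps = 1e5, seed = 11)
struct <- run_resident_chain(N = 2, M = 60, b = 3, steps = 1e5, seed = 11)
mean_cooperation(mixed)   #> [1] 0.997006
mean_cooperation(struct)  #> [1] 0.33179
```

The first two numbers illustrate the core trade-off: small groups make the
"fair" rival strategy TFT a strong invader of defectors (cooperation gains a
foothold when `b` is small), but they also favor spiteful strategies that
undermine Win-Stay Lose-Shift, which is why well-mixed populations cooperate
more when `b` is intermediate.

A command-line interface mirrors the main entry points:

```sh
inst/exec/grouprecip fixation --p TFT --q AllD --N 2 --b 1.5 --error-rate 0
inst/exec/grouprecip stationary --N 2 --M 60 --b 3 --steps 100000 --seed 1 --out out.csv
```

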