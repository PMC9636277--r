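# Partial separation of time scales: mutations and out-group imitation are
# comparably rare, intra-group imitation is fast. Groups are homogeneous but
# the population is polymorphic; the state is the fraction of groups playing
# each strategy.

# Default selection strength for the partial-separation regime: scaling both
# strengths as 30/(b-1) keeps the typical payoff scale (and hence the time
# scale of the dynamics) comparable across benefit values.
partial_sigma <- function(b) 30 / (b - 1)

# Intra-group fixation matrix rho[p, q] and self-payoff vector over a set.
rho_matrix <- function(set, N, b, sigma_in, e) {
  k <- length(set)
  labels <- purrr::map_chr(set, ~ attr(strategy_from_id(.x), "label"))
  rho <- matrix(0, k, k, dimnames = list(labels, labels))
  selfpay <- numeric(k)
  for (a in seq_len(k)) {
    selfpay[a] <- if (e == 0) pair_game_limit(set[a], set[a], b = b)$pi_pq
                  else pair_game(set[a], set[a], b = b, e = e)$pi_pq
    for (d in seq_len(k)) {
      if (a == d) next
      rho[a, d] <- fixation_probability(set[a], set[d], N = N, b = b,
                                        sigma_in = sigma_in, e = e)
    }
  }
  list(rho = rho, selfpay = setNames(selfpay, labels))
}

#' Selection flow coefficient between two group strategies
#'
#' The antisymmetric coefficient
#' `alpha_pq = rho_pq / (1 + exp(sigma_out (pi_qq - pi_pp))) - rho_qp / (1 + exp(sigma_out (pi_pp - pi_qq)))`
#' giving the net flow of groups from strategy `q` to strategy `p` by
#' out-group imitation followed by intra-group fixation.
#'
#' @inheritParams population_fixation
#' @return A scalar; `alpha_flow(p, q) == -alpha_flow(q, p)`.
#' @export
alpha_flow <- function(p, q, N, b, sigma_in = 10, sigma_out = 10, e = 1e-3) {
  N <- check_count(N, "N", 2)
  check_benefit(b); check_selection(sigma_in, "sigma_in")
  check_selection(sigma_out, "sigma_out"); check_error_rate(e)
  core <- pair_competition_core(p, q, N, b = b,
                                sigma_in = sigma_in, sigma_out = sigma_out, e = e)
  d <- core$pay$pi_qq - core$pay$pi_pp
  exp(core$log_rho_pq) / (1 + exp(sigma_out * d)) -
    exp(core$log_rho_qp) / (1 + exp(-sigma_out * d))
}

alpha_matrix <- function(set, N, b, sigma_in, sigma_out, e) {
  k <- length(set)
  A <- matrix(0, k, k)
  for (a in seq_len(k - 1)) {
    for (d in (a + 1):k) {
      val <- alpha_flow(set[a], set[d], N = N, b = b, sigma_in = sigma_in,
                        sigma_out = sigma_out, e = e)
      A[a, d] <- val
      A[d, a] <- -val
    }
  }
  A
}

# Right-hand side of the replicator-mutator equation on the simplex, given
# precomputed alpha and rho matrices. Component sum is zero by construction.
ode_rhs_core <- function(x, r, A, R) {
  k <- length(x)
  sel <- (1 - r) * x * as.numeric(A %*% x)
  mut <- r * (as.numeric(R %*% x) - x * unname(colSums(R))) / k
  unname(sel + mut)
}

#' Replicator-mutator flow for group-strategy frequencies
#'
#' Rate of change of the fraction of groups playing each strategy in the
#' large-`M` limit: selection moves groups along the pairwise flow
#' coefficients [alpha_flow()], mutation introduces uniform mutants that fix
#' with the intra-group fixation probability. The component sum of the
#' returned rates is zero, so the unit simplex is invariant.
#'
#' @param x Abundance vector on the unit simplex (one entry per strategy in
#'   `set`).
#' @param set Integer vector of deterministic strategy ids.
#' @param r Relative mutation probability in `[0, 1]`.
#' @inheritParams population_fixation
#' @return The rate vector `dx/dt`.
#' @export
ode_rhs <- function(x, set = 0:15, r, N, b, sigma_in = NULL, sigma_out = NULL,
                    e = 1e-3) {
  if (is.null(sigma_in)) sigma_in <- partial_sigma(b)
  if (is.null(sigma_out)) sigma_out <- partial_sigma(b)
  stopifnot(length(x) == length(set))
  if (abs(sum(x) - 1) > 1e-8 || any(x < -1e-12)) {
    abort_invalid("`x` must lie on the unit simplex.")
  }
  check_probability(r, "r")
  A <- alpha_matrix(set, N = N, b = b, sigma_in = sigma_in,
                    sigma_out = sigma_out, e = e)
  rm <- rho_matrix(set, N = N, b = b, sigma_in = sigma_in, e = e)
  ode_rhs_core(x, r, A, rm$rho)
}

#' Selection-mutation equilibrium of the group-frequency dynamics
#'
#' Integrates the replicator-mutator equation from `x0` (uniform by
#' default) until the flow is below `tol` in the maximum norm, renormalizing
#' onto the simplex between integration chunks. The returned state is also
#' checked against the algebraic fixed-point relation obtained by solving
#' the stationarity condition for each component.
#'
#' @inheritParams ode_rhs
#' @param x0 Initial abundance vector (default uniform).
#' @param t_max Maximum integration time before giving up.
#' @param tol Convergence tolerance on the maximum norm of `dx/dt`.
#' @return A `strategy_distribution` with extra fields `residual_rhs`
#'   (final `max |dx/dt|`), `residual_fp` (fixed-point relation residual)
#'   and `time` (integration time used).
#' @examples
#' solve_fixed_point(set = c(6, 7, 15), r = 0.01, N = 2, b = 3)
#' @export
solve_fixed_point <- function(set = 0:15, r, N, b, sigma_in = NULL,
                              sigma_out = NULL, e = 1e-3, x0 = NULL,
                              t_max = 1e7, tol = 1e-10) {
  if (is.null(sigma_in)) sigma_in <- partial_sigma(b)
  if (is.null(sigma_out)) sigma_out <- partial_sigma(b)
  check_probability(r, "r")
  k <- length(set)
  x <- if (is.null(x0)) rep(1 / k, k) else x0
  if (abs(sum(x) - 1) > 1e-8) abort_invalid("`x0` must lie on the unit simplex.")
  A <- alpha_matrix(set, N = N, b = b, sigma_in = sigma_in,
                    sigma_out = sigma_out, e = e)
  rm <- rho_matrix(set, N = N, b = b, sigma_in = sigma_in, e = e)
  R <- rm$rho
  deriv <- function(t, y, parms) list(ode_rhs_core(y, r, A, R))
  t_now <- 0
  chunk <- 100
  repeat {
    rhs <- ode_rhs_core(x, r, A, R)
    if (max(abs(rhs)) < tol) break
    if (t_now >= t_max) {
      abort_no_convergence(
        sprintf("no fixed point reached by t = %g (max |dx/dt| = %g).",
                t_max, max(abs(rhs))),
        last_state = x)
    }
    sol <- deSolve::ode(y = x, times = c(0, chunk), func = deriv,
                        parms = NULL, method = "lsoda",
                        rtol = 1e-12, atol = 1e-14)
    x <- pmax(as.numeric(sol[nrow(sol), -1]), 0)
    x <- x / sum(x)
    t_now <- t_now + chunk
    chunk <- min(chunk * 2, t_max / 10)
  }
  # algebraic fixed-point check: x_p = r sum_q rho_pq x_q / k /
  #   (r sum_q rho_qp / k - (1-r) sum_q alpha_pq x_q)
  num <- r * as.numeric(R %*% x) / k
  den <- r * colSums(R) / k - (1 - r) * as.numeric(A %*% x)
  residual_fp <- max(abs(x * den - num))
  params <- list(N = N, M = Inf, b = b, sigma_in = sigma_in,
                 sigma_out = sigma_out, e = e, r = r)
  new_strategy_distribution(x, set, params,
                            extra = list(residual_rhs = max(abs(ode_rhs_core(x, r, A, R))),
                                         residual_fp = residual_fp,
                                         time = t_now))
}

#' Group-level Monte Carlo for the partial-separation regime
#'
#' Simulates the finite-`M` chain of homogeneous group strategies. Per
#' elementary step a random group is selected; with probability `r` a
#' uniform mutant arises in it and fixes with the intra-group fixation
#' probability, otherwise a role-model group is drawn and its strategy is
#' adopted with the out-group Fermi probability times the fixation
#' probability. `M` elementary steps form one sweep. Abundances are
#' averaged over post-burn-in steps.
#'
#' @inheritParams ode_rhs
#' @param M Number of groups (>= 2).
#' @param sweeps Number of MC sweeps (each `M` elementary steps).
#' @param burn_in_fraction Fraction of initial steps discarded.
#' @param seed Integer seed.
#' @param runs Independent runs averaged (seeds `seed + 0:(runs-1)`).
#' @return A `strategy_distribution` with extra field `mean_cooperation`.
#' @examples
#' group_level_mc(set = c(6, 15), N = 2, M = 20, b = 3, r = 0.05,
#'                sweeps = 200, seed = 1)
#' @export
group_level_mc <- function(set = 0:15, N, M, b, r, sigma_in = NULL,
                           sigma_out = NULL, e = 1e-3, sweeps = 1e4,
                           burn_in_fraction = 0.1, seed = 1, runs = 1) {
  if (is.null(sigma_in)) sigma_in <- partial_sigma(b)
  if (is.null(sigma_out)) sigma_out <- partial_sigma(b)
  M <- check_count(M, "M", 2)
  check_probability(r, "r")
  stopifnot(sweeps >= 1, runs >= 1)
  rm <- rho_matrix(set, N = N, b = b, sigma_in = sigma_in, e = e)
  k <- length(set)
  total_steps <- sweeps * M
  burn <- floor(total_steps * burn_in_fraction)
  acc <- rep(0, k)
  for (run in seq_len(runs)) {
    set.seed(seed + run - 1L)
    state0 <- sample.int(k, M, replace = TRUE) - 1L
    sim <- group_mc_cpp(state0, rm$rho, rm$selfpay, sigma_out, r,
                        total_steps, burn)
    acc <- acc + sim$abundance
  }
  params <- list(N = N, M = M, b = b, sigma_in = sigma_in,
                 sigma_out = sigma_out, e = e, r = r, steps = total_steps,
                 burn_in = burn, seed = seed, runs = runs)
  dist <- new_strategy_distribution(acc / runs, set, params)
  dist$mean_cooperation <- mean_cooperation(dist, e = e)
  dist
}
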