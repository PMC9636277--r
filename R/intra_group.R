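# Within-group pairwise-comparison (Fermi) dynamics between two strategies.

# The four pairwise payoffs a mixed group needs. e = 0 selects the exact
# rare-error limit path (deterministic strategies only).
pairwise_payoffs <- function(p, q, b, e) {
  p <- strategy(p); q <- strategy(q)
  if (e == 0) {
    pp <- pair_game_limit(p, p, b = b)
    pq <- pair_game_limit(p, q, b = b)
    qq <- pair_game_limit(q, q, b = b)
  } else {
    pp <- pair_game(p, p, b = b, e = e)
    pq <- pair_game(p, q, b = b, e = e)
    qq <- pair_game(q, q, b = b, e = e)
  }
  list(pi_pp = pp$pi_pq, pi_pq = pq$pi_pq, pi_qp = pq$pi_qp, pi_qq = qq$pi_pq)
}

#' Average payoffs in a mixed group
#'
#' In a group of size `N` where `i` players use strategy `p` and `N - i` use
#' `q`, each player interacts with all `N - 1` co-players. The average
#' payoffs are
#' `pi_p(i) = (i-1)/(N-1) pi_pp + (N-i)/(N-1) pi_pq` and
#' `pi_q(i) = i/(N-1) pi_qp + (N-i-1)/(N-1) pi_qq`.
#' Both types must be present (`1 <= i <= N - 1`): a lone type has no
#' co-player of the other type, so the boundary payoffs are undefined here.
#'
#' @param p,q Strategies.
#' @param i Number of `p`-players, in `1..N-1`.
#' @param N Group size (>= 2).
#' @param b Benefit (> 1).
#' @param e Error rate; 0 selects the exact limit path.
#' @return A one-row tibble with `i`, `pi_p`, `pi_q`.
#' @examples
#' mixed_group_payoffs("WSLS", "S_7", i = 1, N = 2, b = 3, e = 0)
#' @export
mixed_group_payoffs <- function(p, q, i, N, b, e = 1e-3) {
  N <- check_count(N, "N", 2)
  if (!is.numeric(i) || length(i) != 1L || i != round(i) || i < 1 || i > N - 1) {
    abort_invalid("`i` must be an integer in 1..N-1 (both types present).")
  }
  pay <- pairwise_payoffs(p, q, b, e)
  tibble::tibble(
    i = as.integer(i),
    pi_p = (i - 1) / (N - 1) * pay$pi_pp + (N - i) / (N - 1) * pay$pi_pq,
    pi_q = i / (N - 1) * pay$pi_qp + (N - i - 1) / (N - 1) * pay$pi_qq
  )
}

#' Fermi step probabilities of the within-group birth-death chain
#'
#' Probability that a single intra-group imitation event increases
#' (`t_plus`) or decreases (`t_minus`) the number of `p`-players, given the
#' Fermi imitation rule with selection strength `sigma_in`.
#'
#' @inheritParams mixed_group_payoffs
#' @param sigma_in Intra-group selection strength (>= 0).
#' @return A one-row tibble with `i`, `t_plus`, `t_minus`.
#' @export
step_probabilities <- function(p, q, i, N, b, sigma_in = 10, e = 1e-3) {
  check_selection(sigma_in, "sigma_in")
  pay <- mixed_group_payoffs(p, q, i, N, b, e)
  pref <- (N - i) / N * i / (N - 1)
  tibble::tibble(
    i = as.integer(i),
    t_plus = pref / (1 + exp(sigma_in * (pay$pi_q - pay$pi_p))),
    t_minus = pref / (1 + exp(sigma_in * (pay$pi_p - pay$pi_q)))
  )
}

# Closed-form log fixation probability of a single p-mutant in a q-group,
# from precomputed pairwise payoffs. log-domain sum over the N exponents.
log_rho_from_payoffs <- function(pay, N, sigma_in) {
  i <- 0:(N - 1)
  expo <- sigma_in * i * ((2 * N - i - 3) * pay$pi_qq + (i + 1) * pay$pi_qp -
                          (2 * N - i - 1) * pay$pi_pq - (i - 1) * pay$pi_pp) /
    (2 * (N - 1))
  if (any(!is.finite(expo))) {
    abort_numeric_range("fixation exponent not representable; reduce sigma_in * N.")
  }
  -logsumexp(expo)
}

#' Fixation probability of a single mutant within a group
#'
#' Probability that one `p`-player takes over a group of `N - 1` resident
#' `q`-players under the Fermi pairwise-comparison process. Computed from
#' the closed-form sum of exponentials in the log domain, so large
#' `sigma_in * N` does not overflow.
#'
#' @inheritParams step_probabilities
#' @return The fixation probability (scalar in (0, 1)).
#' @examples
#' fixation_probability("TFT", "AllD", N = 2, b = 1.5, sigma_in = 10, e = 0) # 1/2
#' @export
fixation_probability <- function(p, q, N, b, sigma_in = 10, e = 1e-3) {
  N <- check_count(N, "N", 2)
  check_benefit(b); check_selection(sigma_in, "sigma_in"); check_error_rate(e)
  pay <- pairwise_payoffs(p, q, b, e)
  exp(log_rho_from_payoffs(pay, N, sigma_in))
}

#' Ratio of forward and backward fixation probabilities
#'
#' The closed form
#' `rho_pq / rho_qp = exp(sigma_in * ((pi_pp - pi_qq)(N/2 - 1) + (pi_pq - pi_qp) N/2))`.
#'
#' @inheritParams fixation_probability
#' @return The ratio (positive scalar).
#' @export
fixation_ratio <- function(p, q, N, b, sigma_in = 10, e = 1e-3) {
  N <- check_count(N, "N", 2)
  check_benefit(b); check_selection(sigma_in, "sigma_in"); check_error_rate(e)
  pay <- pairwise_payoffs(p, q, b, e)
  exp(sigma_in * ((pay$pi_pp - pay$pi_qq) * (N / 2 - 1) +
                    (pay$pi_pq - pay$pi_qp) * N / 2))
}

#' Payoff difference through transformed payoffs
#'
#' Re-expresses the mixed-group payoff difference `pi_p(i) - pi_q(i)`
#' through one of two payoff transformations: the `"prime"` variant
#' subtracts the co-player's payoff weighted by `1/(N-1)` (spite-corrected
#' payoffs), the `"tilde"` variant uses the finite-population matrix
#' transformation `A - (A + A^T)/N` rescaled by `N/(N-2)`. Both are exact
#' algebraic re-interpretations of the same difference and serve as
#' cross-checks of the direct formula; they require `N >= 3`.
#'
#' @inheritParams mixed_group_payoffs
#' @param variant `"prime"` or `"tilde"`.
#' @return The payoff difference `pi_p(i) - pi_q(i)` (scalar).
#' @export
transformed_payoff_difference <- function(p, q, i, N, b, e = 1e-3,
                                          variant = c("prime", "tilde")) {
  variant <- match.arg(variant)
  N <- check_count(N, "N", 3)
  if (!is.numeric(i) || length(i) != 1L || i != round(i) || i < 1 || i > N - 1) {
    abort_invalid("`i` must be an integer in 1..N-1.")
  }
  pay <- pairwise_payoffs(p, q, b, e)
  if (variant == "prime") {
    pp <- pay$pi_pp - pay$pi_pp / (N - 1)
    pq <- pay$pi_pq - pay$pi_qp / (N - 1)
    qp <- pay$pi_qp - pay$pi_pq / (N - 1)
    qq <- pay$pi_qq - pay$pi_qq / (N - 1)
    (i - 1) / (N - 2) * (pp - qp) + (N - i - 1) / (N - 2) * (pq - qq)
  } else {
    # payoff matrix transformation A -> (A - (A + A^T)/N) * N/(N-2); the
    # rescale applies to the whole transformed payoff
    sc <- N / (N - 2)
    pp <- (pay$pi_pp - 2 * pay$pi_pp / N) * sc
    pq <- (pay$pi_pq - (pay$pi_pq + pay$pi_qp) / N) * sc
    qp <- (pay$pi_qp - (pay$pi_qp + pay$pi_pq) / N) * sc
    qq <- (pay$pi_qq - 2 * pay$pi_qq / N) * sc
    (i - 1) / (N - 1) * (pp - qp) + (N - i - 1) / (N - 1) * (pq - qq)
  }
}
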