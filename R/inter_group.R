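# Inter-group dynamics under complete separation of time scales. All groups
# are homogeneous; the state is the number of p-groups, a birth-death chain
# whose step probabilities combine an out-group Fermi comparison of the
# self-payoffs with the intra-group fixation probability of the immigrant.

# Shared quantities for an ordered pair under given population structure.
pair_competition_core <- function(p, q, N, b, sigma_in, sigma_out, e) {
  pay <- pairwise_payoffs(p, q, b, e)
  log_rho_pq <- log_rho_from_payoffs(pay, N, sigma_in)
  pay_rev <- list(pi_pp = pay$pi_qq, pi_pq = pay$pi_qp,
                  pi_qp = pay$pi_pq, pi_qq = pay$pi_pp)
  log_rho_qp <- log_rho_from_payoffs(pay_rev, N, sigma_in)
  # log eta from the closed form; identical to log(rho_qp/rho_pq) + Fermi term
  log_eta <- -sigma_in * ((pay$pi_pp - pay$pi_qq) * (N / 2 - 1) +
                            (pay$pi_pq - pay$pi_qp) * N / 2) +
    sigma_out * (pay$pi_qq - pay$pi_pp)
  list(pay = pay, log_rho_pq = log_rho_pq, log_rho_qp = log_rho_qp,
       log_eta = log_eta)
}

#' Group-level step probabilities
#'
#' Probability that a single out-group imitation event increases
#' (`q_plus`) or decreases (`q_minus`) the number of homogeneous `p`-groups,
#' when `i` of the `M` groups currently play `p`. The imitation probability
#' follows the Fermi rule on the groups' self-payoffs and is multiplied by
#' the intra-group fixation probability of the immigrating strategy.
#'
#' @param p,q Strategies.
#' @param i Number of `p`-groups, in `1..M-1`.
#' @param N Group size (>= 2).
#' @param M Number of groups (>= 2).
#' @param b Benefit (> 1).
#' @param sigma_in,sigma_out Selection strengths (>= 0).
#' @param e Error rate; 0 selects the exact limit path.
#' @return A one-row tibble with `i`, `q_plus`, `q_minus`.
#' @export
group_step_probabilities <- function(p, q, i, N, M, b, sigma_in = 10,
                                     sigma_out = 10, e = 1e-3) {
  M <- check_count(M, "M", 2)
  if (!is.numeric(i) || length(i) != 1L || i != round(i) || i < 1 || i > M - 1) {
    abort_invalid("`i` must be an integer in 1..M-1.")
  }
  N <- check_count(N, "N", 2)
  check_benefit(b); check_selection(sigma_in, "sigma_in")
  check_selection(sigma_out, "sigma_out"); check_error_rate(e)
  core <- pair_competition_core(p, q, N, b = b,
                                sigma_in = sigma_in, sigma_out = sigma_out, e = e)
  pref <- i / M * (M - i) / (M - 1)
  fermi_up <- 1 / (1 + exp(sigma_out * (core$pay$pi_qq - core$pay$pi_pp)))
  fermi_dn <- 1 / (1 + exp(sigma_out * (core$pay$pi_pp - core$pay$pi_qq)))
  tibble::tibble(
    i = as.integer(i),
    q_plus = pref * fermi_up * exp(core$log_rho_pq),
    q_minus = pref * fermi_dn * exp(core$log_rho_qp)
  )
}

#' Ratio of backward to forward group-level step probabilities
#'
#' The ratio `eta = Q_i^- / Q_i^+` is independent of `i` and has the closed
#' form
#' `exp(-sigma_in ((pi_pp - pi_qq)(N/2 - 1) + (pi_pq - pi_qp) N/2) + sigma_out (pi_qq - pi_pp))`.
#' Computed in log space; use `log = TRUE` for the exponent itself.
#'
#' @inheritParams group_step_probabilities
#' @param log Return `log(eta)` instead of `eta`.
#' @return A positive scalar (or its log).
#' @export
eta <- function(p, q, N, b, sigma_in = 10, sigma_out = 10, e = 1e-3,
                log = FALSE) {
  N <- check_count(N, "N", 2)
  check_benefit(b); check_selection(sigma_in, "sigma_in")
  check_selection(sigma_out, "sigma_out"); check_error_rate(e)
  core <- pair_competition_core(p, q, N, b = b,
                                sigma_in = sigma_in, sigma_out = sigma_out, e = e)
  if (log) core$log_eta else exp(core$log_eta)
}

# log Psi_pq = log rho_pq - log(sum_{j=0}^{M-1} eta^j), stable for any eta.
log_psi <- function(log_rho, log_eta, M) {
  log_rho - logsumexp((0:(M - 1)) * log_eta)
}

#' Population-wide fixation probabilities
#'
#' Probability that a single `p`-mutant takes over the whole population of
#' `M` groups of size `N` (and the mirrored probability for a `q`-mutant in
#' a `p`-population), under complete separation of time scales. The mutant
#' must first fix in its own group (probability `rho`), then the group-level
#' birth-death chain must reach fixation. With `M = 1` this reduces to the
#' intra-group fixation probability. The geometric sums over `eta` are
#' evaluated by log-sum-exp, so the `eta = 1` case needs no special branch.
#'
#' @inheritParams group_step_probabilities
#' @param M Number of groups (>= 1).
#' @return A one-row tibble with `psi_pq`, `psi_qp`, `eta`, `rho_pq`,
#'   `rho_qp`.
#' @examples
#' population_fixation("TFT", "AllD", N = 2, M = 60, b = 1.5, e = 0)
#' @export
population_fixation <- function(p, q, N, M, b, sigma_in = 10, sigma_out = 10,
                                e = 1e-3) {
  N <- check_count(N, "N", 2); M <- check_count(M, "M", 1)
  check_benefit(b); check_selection(sigma_in, "sigma_in")
  check_selection(sigma_out, "sigma_out"); check_error_rate(e)
  core <- pair_competition_core(p, q, N, b = b,
                                sigma_in = sigma_in, sigma_out = sigma_out, e = e)
  tibble::tibble(
    psi_pq = exp(log_psi(core$log_rho_pq, core$log_eta, M)),
    psi_qp = exp(log_psi(core$log_rho_qp, -core$log_eta, M)),
    eta = exp(core$log_eta),
    rho_pq = exp(core$log_rho_pq),
    rho_qp = exp(core$log_rho_qp)
  )
}

#' Which strategy does selection favor?
#'
#' Sign of the selection criterion
#' `sigma_in (N/2 (pi_pq - pi_qp) + (N/2 - 1)(pi_pp - pi_qq)) + sigma_out (M-1)/M (pi_pp - pi_qq)`.
#' A positive sign means a single `p`-mutant is more likely to replace a
#' `q`-population than vice versa (`psi_pq > psi_qp`).
#'
#' @inheritParams population_fixation
#' @param tol Statistics smaller than this in absolute value count as zero.
#'   The default sits between the floating-point noise of an exactly neutral
#'   pair (below 1e-12 even after amplification by `sigma * N`) and the
#'   smallest genuine selection effects, which are of order
#'   `sigma * N * e` (about 1e-2 at the baseline parameters).
#' @return A one-row tibble with `statistic` and `favored` in `{-1, 0, 1}`.
#' @export
is_favored <- function(p, q, N, M, b, sigma_in = 10, sigma_out = 10,
                       e = 1e-3, tol = 1e-9) {
  N <- check_count(N, "N", 2); M <- check_count(M, "M", 1)
  check_benefit(b); check_selection(sigma_in, "sigma_in")
  check_selection(sigma_out, "sigma_out"); check_error_rate(e)
  pay <- pairwise_payoffs(p, q, b, e)
  stat <- sigma_in * (N / 2 * (pay$pi_pq - pay$pi_qp) +
                        (N / 2 - 1) * (pay$pi_pp - pay$pi_qq)) +
    sigma_out * (M - 1) / M * (pay$pi_pp - pay$pi_qq)
  tibble::tibble(statistic = stat,
                 favored = if (abs(stat) < tol) 0L else as.integer(sign(stat)))
}

#' Unconditional and conditional fixation times of the group-level chain
#'
#' Expected number of out-group imitation events until absorption
#' (either boundary; `t_uc`) and until fixation of `p` conditioned on its
#' success (`t_c`), starting from a single `p`-group. Times are reported in
#' units of inter-group imitation events (1/mu). The defining double sums
#' over the group-count chain are evaluated term-by-term in the log domain,
#' which is continuous across `eta = 1` (the closed-form branches suffer
#' catastrophic cancellation there) and cannot overflow before the final
#' exponentiation; a result beyond the double range raises a
#' numeric-range error rather than returning infinity.
#'
#' @inheritParams group_step_probabilities
#' @return A one-row tibble with `t_uc`, `t_c`, `eta`.
#' @export
fixation_times <- function(p, q, N, M, b, sigma_in = 10, sigma_out = 10,
                           e = 1e-3) {
  N <- check_count(N, "N", 2); M <- check_count(M, "M", 2)
  check_benefit(b); check_selection(sigma_in, "sigma_in")
  check_selection(sigma_out, "sigma_out"); check_error_rate(e)
  core <- pair_competition_core(p, q, N, b = b,
                                sigma_in = sigma_in, sigma_out = sigma_out, e = e)
  lg <- core$log_eta
  # log Q_l^+ = log combinatorial prefactor + log Fermi factor + log rho
  x <- sigma_out * (core$pay$pi_qq - core$pay$pi_pp)
  log1pexp <- function(z) ifelse(z > 35, z, log1p(exp(z)))
  l <- seq_len(M - 1)
  log_q_plus <- log(l) + log(M - l) - log(M) - log(M - 1) -
    log1pexp(x) + core$log_rho_pq
  # success probabilities phi_i from state i, in the log domain
  log_geom <- vapply(0:M, function(i) {
    if (i == 0) -Inf else logsumexp((0:(i - 1)) * lg)
  }, numeric(1))
  log_phi <- log_geom - log_geom[M + 1L]
  # t_uc = phi_1 sum_{k=1}^{M-1} sum_{l=1}^{k} eta^(k-l) / Q_l^+
  # t_c  =       sum_{k=1}^{M-1} sum_{l=1}^{k} phi_l eta^(k-l) / Q_l^+
  terms_uc <- numeric(0)
  terms_c <- numeric(0)
  for (k in seq_len(M - 1)) {
    ll <- seq_len(k)
    base <- (k - ll) * lg - log_q_plus[ll]
    terms_uc <- c(terms_uc, log_phi[2L] + base)
    terms_c <- c(terms_c, log_phi[ll + 1L] + base)
  }
  t_uc <- exp(logsumexp(terms_uc))
  t_c <- exp(logsumexp(terms_c))
  if (!all(is.finite(c(t_uc, t_c)))) {
    abort_numeric_range("fixation-time evaluation left the representable range.")
  }
  tibble::tibble(t_uc = t_uc, t_c = t_c, eta = exp(lg))
}

#' Pairwise competition table
#'
#' Evaluates the complete-separation competition quantities for every
#' ordered pair from a strategy set: `eta`, the population fixation
#' probabilities, the favored sign, and (for `M >= 2`) the fixation times.
#'
#' @param set Integer vector of deterministic strategy ids.
#' @inheritParams population_fixation
#' @return A tibble with one row per ordered pair (`p_id != q_id`).
#' @export
competition_table <- function(set = 0:15, N, M, b, sigma_in = 10,
                              sigma_out = 10, e = 1e-3) {
  grid <- tidyr::expand_grid(p_id = set, q_id = set)
  grid <- dplyr::filter(grid, .data$p_id != .data$q_id)
  purrr::pmap_dfr(grid, function(p_id, q_id) {
    pf <- population_fixation(p_id, q_id, N = N, M = M, b = b,
                              sigma_in = sigma_in, sigma_out = sigma_out, e = e)
    fav <- is_favored(p_id, q_id, N = N, M = M, b = b,
                      sigma_in = sigma_in, sigma_out = sigma_out, e = e)
    times <- if (M >= 2) {
      tryCatch(fixation_times(p_id, q_id, N = N, M = M, b = b,
                              sigma_in = sigma_in, sigma_out = sigma_out, e = e),
               grouprecip_numeric_range = function(cnd) {
                 tibble::tibble(t_uc = NA_real_, t_c = NA_real_, eta = pf$eta)
               })
    } else tibble::tibble(t_uc = NA_real_, t_c = NA_real_, eta = pf$eta)
    tibble::tibble(p_id = p_id, q_id = q_id, eta = pf$eta,
                   psi_pq = pf$psi_pq, psi_qp = pf$psi_qp,
                   favored = fav$favored, t_uc = times$t_uc, t_c = times$t_c)
  })
}
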