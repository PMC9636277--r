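#' Transition matrix of the repeated game between two memory-1 strategies
#'
#' States are the round outcomes (CC, CD, DC, DD) from the first player's
#' perspective. The second player's entries are re-indexed from its own
#' viewpoint (its DC is the first player's CD and vice versa). The caller is
#' responsible for supplying *effective* (error-perturbed) strategies.
#'
#' @param p_eff,q_eff Effective strategies of the two players.
#' @return A 4x4 row-stochastic matrix with dimnames `CC, CD, DC, DD`.
#' @examples
#' p <- apply_error(strategy("WSLS"), 1e-3)
#' q <- apply_error(strategy("AllD"), 1e-3)
#' pair_transition_matrix(p, q)
#' @export
pair_transition_matrix <- function(p_eff, q_eff) {
  p <- as.numeric(strategy(p_eff))
  q <- as.numeric(strategy(q_eff))
  # q is indexed from its own perspective: in the first player's CD state the
  # co-player sees DC, hence q[3] appears in row 2, q[2] in row 3.
  pc <- c(p[1], p[2], p[3], p[4])
  qc <- c(q[1], q[3], q[2], q[4])
  T <- cbind(pc * qc, pc * (1 - qc), (1 - pc) * qc, (1 - pc) * (1 - qc))
  dimnames(T) <- list(c("CC", "CD", "DC", "DD"), c("CC", "CD", "DC", "DD"))
  T
}

#' Stationary distribution of a 4x4 stochastic matrix
#'
#' Solves the linear system `v (T - I) = 0` with the normalization
#' `sum(v) = 1` directly (no power iteration), so the result is
#' deterministic. A reducible chain (which occurs for deterministic
#' strategies without errors) raises a degenerate-chain error; use the exact
#' error-free limit path ([pair_game_limit()]) in that case.
#'
#' @param T A 4x4 row-stochastic matrix.
#' @return A length-4 probability vector over outcomes (CC, CD, DC, DD).
#' @export
stationary_distribution <- function(T) {
  stopifnot(is.matrix(T), all(dim(T) == c(4L, 4L)))
  A <- t(T) - diag(4)
  A[4, ] <- 1
  v <- tryCatch(solve(A, c(0, 0, 0, 1)), error = function(err) NULL)
  if (is.null(v) || any(!is.finite(v)) ||
      max(abs(as.numeric(v %*% T) - v)) > 1e-10 || any(v < -1e-12)) {
    abort_degenerate(paste0(
      "the Markov chain has no unique stationary distribution ",
      "(reducible at e = 0); use the exact limit path instead."))
  }
  v <- pmax(v, 0)
  setNames(v / sum(v), c("CC", "CD", "DC", "DD"))
}

#' Repeated-game result for an ordered pair of strategies
#'
#' Computes the stationary outcome distribution of the repeated donation game
#' with implementation errors, the two players' long-run cooperation levels
#' `gamma_pq = v_CC + v_CD` and `gamma_qp = v_CC + v_DC`, and the payoffs
#' `pi_pq = b * gamma_qp - c * gamma_pq` (cost normalized to c = 1).
#'
#' @param p,q Strategies (anything [strategy()] accepts).
#' @param b Benefit of cooperation (> 1).
#' @param e Error rate in `(0, 1/2)`; `e = 0` is only allowed when both
#'   strategies are interior (use [pair_game_limit()] for deterministic
#'   strategies without errors).
#' @return A one-row tibble: `p_id`, `q_id`, `gamma_pq`, `gamma_qp`,
#'   `pi_pq`, `pi_qp`, and the four stationary probabilities
#'   `v_cc`, `v_cd`, `v_dc`, `v_dd`.
#' @examples
#' pair_game("WSLS", "AllD", b = 3, e = 1e-3)
#' @export
pair_game <- function(p, q, b, e = 1e-3) {
  p <- strategy(p); q <- strategy(q)
  check_benefit(b); check_error_rate(e)
  pe <- apply_error(p, e)
  qe <- apply_error(q, e)
  v <- stationary_distribution(pair_transition_matrix(pe, qe))
  gamma_pq <- v[["CC"]] + v[["CD"]]
  gamma_qp <- v[["CC"]] + v[["DC"]]
  tibble::tibble(
    p_id = attr(p, "id"), q_id = attr(q, "id"),
    gamma_pq = gamma_pq, gamma_qp = gamma_qp,
    pi_pq = b * gamma_qp - gamma_pq,
    pi_qp = b * gamma_pq - gamma_qp,
    v_cc = v[["CC"]], v_cd = v[["CD"]], v_dc = v[["DC"]], v_dd = v[["DD"]]
  )
}

#' Press-Dyson determinant of the repeated game
#'
#' Evaluates the 4x4 determinant `D(p, q, f)` whose first three columns are
#' built from the two (effective) strategies and whose last column is an
#' arbitrary vector `f`. Ratios of such determinants give long-run averages
#' of the repeated game; in particular the cooperation level of the p-player
#' is `(D(p,q,f_CC) + D(p,q,f_CD)) / D(p,q,f_1)` with `f_1 = (1,1,1,1)`,
#' `f_CC = (1,0,0,0)`, `f_CD = (0,1,0,0)`.
#'
#' @param p_eff,q_eff Effective strategies.
#' @param f Length-4 numeric vector.
#' @return The determinant (a scalar).
#' @export
determinant_form <- function(p_eff, q_eff, f) {
  p <- as.numeric(strategy(p_eff)); q <- as.numeric(strategy(q_eff))
  stopifnot(is.numeric(f), length(f) == 4L)
  M <- cbind(
    c(-1 + p[1] * q[1], p[2] * q[3], p[3] * q[2], p[4] * q[4]),
    c(-1 + p[1], -1 + p[2], p[3], p[4]),
    c(-1 + q[1], q[3], -1 + q[2], q[4]),
    f
  )
  det(M)
}

#' Cooperation level via the determinant formula
#'
#' Alternative closed-form route to the p-player's cooperation level, used to
#' cross-validate the stationary-distribution path.
#'
#' @inheritParams determinant_form
#' @return The p-player's long-run cooperation probability.
#' @export
cooperation_determinant <- function(p_eff, q_eff) {
  d1 <- determinant_form(p_eff, q_eff, c(1, 1, 1, 1))
  dcc <- determinant_form(p_eff, q_eff, c(1, 0, 0, 0))
  dcd <- determinant_form(p_eff, q_eff, c(0, 1, 0, 0))
  (dcc + dcd) / d1
}

#' Pairwise game table over a strategy set
#'
#' Evaluates [pair_game()] for every ordered pair drawn from `set`.
#'
#' @param set Integer vector of deterministic strategy ids (default all 16).
#' @inheritParams pair_game
#' @return A tibble with one row per ordered pair, columns as in
#'   [pair_game()].
#' @export
pair_game_table <- function(set = 0:15, b, e = 1e-3) {
  grid <- tidyr::expand_grid(p_id = set, q_id = set)
  purrr::pmap_dfr(grid, function(p_id, q_id) pair_game(p_id, q_id, b = b, e = e))
}
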