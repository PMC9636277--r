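# Exact e -> 0 limits for deterministic strategies.
#
# Every entry of the error-perturbed strategy of a deterministic player is
# either e or 1 - e, i.e. a degree-1 polynomial in e with integer
# coefficients. The Press-Dyson determinant is then a polynomial in e with
# (small) integer coefficients, exact in double precision, and the limit of a
# ratio of two such polynomials is the ratio of their lowest-order non-zero
# coefficients. Polynomials are stored as coefficient vectors in ascending
# powers of e.

poly_trim <- function(a) {
  a <- round(a)
  n <- max(c(1L, which(a != 0)))
  a[seq_len(n)]
}

poly_add <- function(a, b) {
  n <- max(length(a), length(b))
  poly_trim(c(a, rep(0, n - length(a))) + c(b, rep(0, n - length(b))))
}

poly_sub <- function(a, b) poly_add(a, -b)

poly_mul <- function(a, b) {
  out <- rep(0, length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  poly_trim(out)
}

poly_det3 <- function(m) {
  # m: 3x3 list-matrix of polynomials (list of length 9, column-major)
  a <- m[[1]]; d <- m[[2]]; g <- m[[3]]
  b <- m[[4]]; e <- m[[5]]; h <- m[[6]]
  c_ <- m[[7]]; f <- m[[8]]; i <- m[[9]]
  poly_add(
    poly_sub(poly_mul(a, poly_sub(poly_mul(e, i), poly_mul(f, h))),
             poly_mul(b, poly_sub(poly_mul(d, i), poly_mul(f, g)))),
    poly_mul(c_, poly_sub(poly_mul(d, h), poly_mul(e, g)))
  )
}

# Effective entry of a deterministic strategy as a polynomial in e.
eff_poly <- function(x) if (x == 1) c(1, -1) else c(0, 1)

gcd2 <- function(a, b) if (b == 0) abs(a) else gcd2(b, a %% b)

# Limit of num(e)/den(e) as e -> 0+, as a reduced integer fraction.
poly_limit_ratio <- function(num, den) {
  k <- which(den != 0)[1]
  if (is.na(k)) abort_degenerate("denominator polynomial vanishes identically.")
  nk <- if (length(num) >= k) num[k] else 0
  if (any(round(num[seq_len(k - 1)]) != 0)) {
    abort_numeric_range("limit diverges: numerator has lower order than denominator.")
  }
  if (nk == 0) return(c(num = 0, den = 1))
  g <- gcd2(nk, den[k])
  s <- sign(den[k])
  c(num = s * nk / g, den = s * den[k] / g)
}

# Press-Dyson cofactors C_1..C_4 (last-column cofactors) as polynomials in e
# for a deterministic ordered pair. gamma_pq = (C1 + C2) / (C1 + C2 + C3 + C4).
pd_cofactors_poly <- function(p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  pe <- lapply(p, eff_poly)
  qe <- lapply(q, eff_poly)
  one <- c(1); neg1 <- c(-1)
  col1 <- list(poly_add(neg1, poly_mul(pe[[1]], qe[[1]])),
               poly_mul(pe[[2]], qe[[3]]),
               poly_mul(pe[[3]], qe[[2]]),
               poly_mul(pe[[4]], qe[[4]]))
  col2 <- list(poly_add(neg1, pe[[1]]), poly_add(neg1, pe[[2]]), pe[[3]], pe[[4]])
  col3 <- list(poly_add(neg1, qe[[1]]), qe[[3]], poly_add(neg1, qe[[2]]), qe[[4]])
  cof <- vector("list", 4L)
  for (i in 1:4) {
    rows <- setdiff(1:4, i)
    minor <- c(col1[rows], col2[rows], col3[rows])
    cof[[i]] <- poly_mul(c((-1)^(i + 4)), poly_det3(minor))
  }
  cof
}

limit_cache <- new.env(parent = emptyenv())

# Exact e -> 0 cooperation levels for an ordered deterministic pair,
# as reduced fractions.
gamma_limits <- function(p_id, q_id) {
  key <- paste(p_id, q_id)
  if (!is.null(limit_cache[[key]])) return(limit_cache[[key]])
  p <- strategy_from_id(p_id); q <- strategy_from_id(q_id)
  cof <- pd_cofactors_poly(p, q)
  d1 <- Reduce(poly_add, cof)
  g_pq <- poly_limit_ratio(poly_add(cof[[1]], cof[[2]]), d1)
  g_qp <- poly_limit_ratio(poly_add(cof[[1]], cof[[3]]), d1)
  out <- list(gamma_pq = g_pq, gamma_qp = g_qp)
  limit_cache[[key]] <- out
  out
}

#' Error-free limit of the repeated-game result
#'
#' Exact `e -> 0` limits of the cooperation levels and payoffs for an ordered
#' pair of deterministic strategies, computed by rational (integer
#' polynomial) arithmetic on the Press-Dyson determinant. This is the correct
#' path when the error-free Markov chain is reducible and
#' [stationary_distribution()] refuses to answer.
#'
#' @param p,q Deterministic strategies (anything [strategy()] accepts).
#' @param b Benefit of cooperation (> 1).
#' @return A one-row tibble: ids, exact cooperation levels `gamma_pq`,
#'   `gamma_qp`, and payoffs `pi_pq = b * gamma_qp - gamma_pq`,
#'   `pi_qp = b * gamma_pq - gamma_qp`.
#' @examples
#' pair_game_limit("WSLS", "S_7", b = 3)
#' @export
pair_game_limit <- function(p, q, b) {
  check_benefit(b)
  p <- strategy(p); q <- strategy(q)
  if (!is_deterministic(p) || !is_deterministic(q)) {
    abort_invalid("the exact limit path requires deterministic strategies.")
  }
  gl <- gamma_limits(attr(p, "id"), attr(q, "id"))
  g_pq <- gl$gamma_pq[["num"]] / gl$gamma_pq[["den"]]
  g_qp <- gl$gamma_qp[["num"]] / gl$gamma_qp[["den"]]
  tibble::tibble(
    p_id = attr(p, "id"), q_id = attr(q, "id"),
    gamma_pq = g_pq, gamma_qp = g_qp,
    pi_pq = b * g_qp - g_pq, pi_qp = b * g_pq - g_qp
  )
}

# Payoff pi_pq as a linear function a * b + c of the benefit, exact limits.
payoff_linear_limit <- function(p_id, q_id) {
  gl <- gamma_limits(p_id, q_id)
  g_pq <- gl$gamma_pq[["num"]] / gl$gamma_pq[["den"]]
  g_qp <- gl$gamma_qp[["num"]] / gl$gamma_qp[["den"]]
  c(slope = g_qp, intercept = -g_pq)
}

#' Exact self-cooperation level in the rare-error limit
#'
#' For a deterministic strategy playing against itself, returns
#' `lim_{e -> 0} gamma_pp` as an exact rational number, computed by
#' substituting the error-perturbed entries into the closed-form
#' self-cooperation expression and cancelling leading orders in `e`.
#'
#' @param p A deterministic strategy.
#' @return A one-row tibble with `id`, `label`, the exact fraction
#'   (`num`, `den`) and its numeric `value`.
#' @examples
#' self_cooperation_limit("S_2") # 3/4
#' @export
self_cooperation_limit <- function(p) {
  p <- strategy(p)
  if (!is_deterministic(p)) {
    abort_invalid("the exact limit path requires a deterministic strategy.")
  }
  pe <- lapply(as.numeric(p), eff_poly)
  p1 <- pe[[1]]; p2 <- pe[[2]]; p3 <- pe[[3]]; p4 <- pe[[4]]
  X <- poly_add(p2, p3)
  Y <- poly_mul(p2, p3)
  Z <- poly_mul(p1, p4)
  one <- c(1)
  num <- poly_mul(p4, Reduce(poly_add, list(
    one, poly_mul(c(-1), poly_mul(p1, p1)),
    poly_mul(c(-1), poly_mul(p4, X)), poly_mul(c(2), Y), Z)))
  den <- Reduce(poly_add, list(
    poly_mul(poly_sub(one, p1),
             Reduce(poly_add, list(one, poly_mul(p1, poly_sub(one, X)),
                                   poly_mul(c(-1), X), poly_mul(c(2), Y)))),
    poly_mul(c(2), poly_mul(p4, poly_add(one, Y))),
    poly_mul(c(-2), poly_mul(poly_sub(p1, p4), Z)),
    poly_mul(c(-1), poly_mul(poly_mul(p4, p4), poly_add(one, X)))))
  fr <- poly_limit_ratio(num, den)
  tibble::tibble(id = attr(p, "id"), label = attr(p, "label"),
                 num = fr[["num"]], den = fr[["den"]],
                 value = fr[["num"]] / fr[["den"]])
}

#' Is a strategy a rival?
#'
#' A strategy is a rival if it never lets any opponent earn more than itself:
#' `pi_pq >= pi_qp` for every opponent `q`. The check uses the exact
#' error-free limit payoffs by default (`e = 0`), which is how the property
#' is defined for the deterministic strategy table; the sign of
#' `pi_pq - pi_qp` is independent of `b` in the donation game. With `e > 0`
#' the numeric path is used instead (implementation errors perturb the
#' relationship by O(e), so a correspondingly looser `tol` is needed).
#'
#' @param p Strategy to classify.
#' @param opponents Strategy ids to test against (default all 16).
#' @param b Benefit (> 1); the classification does not depend on it.
#' @param e Error rate; 0 selects the exact limit path.
#' @param tol Slack allowed in the payoff inequality.
#' @return A one-row tibble with `id`, `rival` (logical) and `witness_id`
#'   (the first violating opponent, or NA).
#' @examples
#' classify_rival("TFT")
#' classify_rival("AllC") # witness: AllD
#' @export
classify_rival <- function(p, opponents = 0:15, b = 3, e = 0, tol = 1e-9) {
  p <- strategy(p)
  check_benefit(b); check_error_rate(e)
  for (q_id in opponents) {
    res <- if (e == 0) pair_game_limit(p, q_id, b = b)
           else pair_game(p, q_id, b = b, e = e)
    if (res$pi_pq < res$pi_qp - tol) {
      return(tibble::tibble(id = attr(p, "id"), rival = FALSE,
                            witness_id = as.integer(q_id)))
    }
  }
  tibble::tibble(id = attr(p, "id"), rival = TRUE, witness_id = NA_integer_)
}

#' Payoff comparison against Win-Stay Lose-Shift
#'
#' Sign of `pi(p, WSLS) - pi(WSLS, p)` in the rare-error limit. The sign is
#' independent of the benefit `b > 1`.
#'
#' @param p A deterministic strategy.
#' @param b Benefit used for the evaluation (any value > 1 gives the same sign).
#' @return An integer in `{-1, 0, 1}`.
#' @examples
#' compare_vs_wsls("S_7") # +1
#' @export
compare_vs_wsls <- function(p, b = 3) {
  res <- pair_game_limit(p, "WSLS", b = b)
  d <- res$pi_pq - res$pi_qp
  if (abs(d) < 1e-12) 0L else as.integer(sign(d))
}

#' Summary table of the 16 deterministic strategies
#'
#' Reproduces, from first principles, the standard classification of the
#' deterministic memory-1 strategies: exact rare-error self-cooperation
#' level, rival status, and the payoff comparison against WSLS.
#'
#' @return A tibble with columns `id`, `label`, `actions`, `self_coop`,
#'   `self_coop_num`, `self_coop_den`, `rival`, `vs_wsls` (`"+"`, `"0"`,
#'   `"-"`).
#' @examples
#' strategy_profile()
#' @export
strategy_profile <- function() {
  base <- strategies()
  sc <- purrr::map_dfr(base$id, self_cooperation_limit)
  rv <- purrr::map_dfr(base$id, classify_rival)
  vw <- purrr::map_int(base$id, compare_vs_wsls)
  dplyr::mutate(
    base,
    self_coop = sc$value, self_coop_num = sc$num, self_coop_den = sc$den,
    rival = rv$rival,
    vs_wsls = c("-", "0", "+")[vw + 2L]
  )
}

#' Minimal benefit for Win-Stay Lose-Shift to be a Nash equilibrium
#'
#' Finds the smallest benefit `b` (cost `c = 1`) such that no deterministic
#' memory-1 mutant earns strictly more against a resident WSLS population
#' than WSLS earns against itself, in the rare-error limit. Each payoff is
#' linear in `b` with exact rational coefficients, so the threshold is a
#' ratio of small integers.
#'
#' @return The threshold benefit (numeric scalar).
#' @examples
#' wsls_nash_threshold() # 2
#' @export
wsls_nash_threshold <- function() {
  wsls <- 6L
  lower <- 1
  for (q in setdiff(0:15, wsls)) {
    mut <- payoff_linear_limit(q, wsls)    # pi(q, WSLS) = a b + c
    res <- payoff_linear_limit(wsls, wsls) # pi(WSLS, WSLS) = b - 1
    a <- mut[["slope"]] - res[["slope"]]
    c0 <- mut[["intercept"]] - res[["intercept"]]
    if (abs(a) < 1e-12) {
      if (c0 > 1e-12) abort_numeric_range("no finite Nash threshold exists.")
    } else if (a < 0) {
      lower <- max(lower, c0 / (-a))
    } else {
      abort_numeric_range("mutant advantage grows with b; no threshold.")
    }
  }
  lower
}

#' Risk-dominance statistic
#'
#' The quantity `pi_pp + pi_pq - pi_qp - pi_qq`, evaluated from the exact
#' rare-error-limit payoffs. In a large population with equal intra- and
#' inter-group selection strengths, `p` is favored over `q` exactly when this
#' statistic is positive (risk dominance). The statistic is linear in the
#' benefit `b`; its root (when the slope is non-zero) is returned as
#' `root_b`.
#'
#' @param p,q Deterministic strategies.
#' @param b Benefit at which to evaluate the statistic.
#' @return A one-row tibble: `p_id`, `q_id`, `statistic` (at `b`), `slope`,
#'   `intercept`, `root_b` (NA when the statistic does not depend on `b`).
#' @examples
#' risk_dominance("WSLS", "S_7", b = 3) # crosses zero at b = 5
#' @export
risk_dominance <- function(p, q, b = 3) {
  check_benefit(b)
  p <- strategy(p); q <- strategy(q)
  pid <- attr(p, "id"); qid <- attr(q, "id")
  pp <- payoff_linear_limit(pid, pid)
  pq <- payoff_linear_limit(pid, qid)
  qp <- payoff_linear_limit(qid, pid)
  qq <- payoff_linear_limit(qid, qid)
  slope <- pp[["slope"]] + pq[["slope"]] - qp[["slope"]] - qq[["slope"]]
  intercept <- pp[["intercept"]] + pq[["intercept"]] -
    qp[["intercept"]] - qq[["intercept"]]
  root <- if (abs(slope) > 1e-12) -intercept / slope else NA_real_
  tibble::tibble(p_id = pid, q_id = qid,
                 statistic = slope * b + intercept,
                 slope = slope, intercept = intercept, root_b = root)
}
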