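# Independent brute-force oracles for the closed-form formulas. These solve
# the defining linear systems of the absorbing birth-death chains directly
# and never reuse the package's closed-form code paths.

# Absorption probability at state n for a birth-death chain on 0..n with
# up/down probabilities tp[i], tm[i] (i = 1..n-1), started from state 1.
bd_absorption_prob <- function(tp, tm) {
  n <- length(tp) + 1L
  k <- n - 1L # transient states 1..n-1
  A <- diag(k)
  rhs <- numeric(k)
  for (i in seq_len(k)) {
    stay <- 1 - tp[i] - tm[i]
    A[i, i] <- 1 - stay
    if (i < k) A[i, i + 1L] <- -tp[i]
    if (i > 1) A[i, i - 1L] <- -tm[i]
    if (i == k) rhs[i] <- tp[i] # absorption into state n
  }
  solve(A, rhs)[1]
}

# Unconditional and conditional (on reaching n) absorption times from state
# 1, in elementary chain steps.
bd_absorption_times <- function(tp, tm) {
  n <- length(tp) + 1L
  k <- n - 1L
  A <- diag(k)
  for (i in seq_len(k)) {
    stay <- 1 - tp[i] - tm[i]
    A[i, i] <- 1 - stay
    if (i < k) A[i, i + 1L] <- -tp[i]
    if (i > 1) A[i, i - 1L] <- -tm[i]
  }
  t_uc <- solve(A, rep(1, k))[1]
  # conditional: w_i = h_i * tau_i solves A w = h, tau_1 = w_1 / h_1
  h <- numeric(k)
  rhs <- numeric(k)
  for (i in seq_len(k)) if (i == k) rhs[i] <- tp[i]
  h <- solve(A, rhs)
  w <- solve(A, h)
  list(t_uc = t_uc, t_c = w[1] / h[1])
}

# Stationary distribution of a small stochastic matrix by direct solve.
markov_stationary_oracle <- function(P) {
  k <- nrow(P)
  A <- t(P) - diag(k)
  A[k, ] <- 1
  v <- solve(A, c(rep(0, k - 1), 1))
  unname(v / sum(v))
}

# Intra-group birth-death step probabilities assembled from first
# principles (Fermi rule on the mixed-group payoffs), for the oracle chains.
intra_chain_steps <- function(p, q, N, b, sigma_in, e) {
  tp <- numeric(N - 1)
  tm <- numeric(N - 1)
  for (i in seq_len(N - 1)) {
    st <- step_probabilities(p, q, i = i, N = N, b = b,
                             sigma_in = sigma_in, e = e)
    tp[i] <- st$t_plus
    tm[i] <- st$t_minus
  }
  list(tp = tp, tm = tm)
}

# Group-level birth-death step probabilities for the oracle chains.
group_chain_steps <- function(p, q, N, M, b, sigma_in, sigma_out, e) {
  tp <- numeric(M - 1)
  tm <- numeric(M - 1)
  for (i in seq_len(M - 1)) {
    qs <- group_step_probabilities(p, q, i = i, N = N, M = M, b = b,
                                   sigma_in = sigma_in, sigma_out = sigma_out,
                                   e = e)
    tp[i] <- qs$q_plus
    tm[i] <- qs$q_minus
  }
  list(tp = tp, tm = tm)
}
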