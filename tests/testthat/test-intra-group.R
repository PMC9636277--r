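test_that("mixed-group payoffs match the defining averages", {
  # published example: WSLS and S_7 sharing a group of two, error-free limit
  mg <- mixed_group_payoffs("WSLS", "S_7", i = 1, N = 2, b = 3, e = 0)
  expect_equal(mg$pi_p, 3 / 3 - 2 / 3, tolerance = 1e-12) # 1/3 b - 2/3
  expect_equal(mg$pi_q, 2 * 3 / 3 - 1 / 3, tolerance = 1e-12) # 2/3 b - 1/3
  # p = q gives equal payoffs at every interior count
  for (i in 1:3) {
    mg2 <- mixed_group_payoffs("TFT", "TFT", i = i, N = 4, b = 2, e = 1e-3)
    expect_equal(mg2$pi_p, mg2$pi_q, tolerance = 1e-12)
  }
  # N = 3, i = 1: lone p-player sees only q-players
  pay <- pair_game("WSLS", "AllD", b = 3, e = 1e-3)
  qq <- pair_game("AllD", "AllD", b = 3, e = 1e-3)
  mg3 <- mixed_group_payoffs("WSLS", "AllD", i = 1, N = 3, b = 3, e = 1e-3)
  expect_equal(mg3$pi_p, pay$pi_pq, tolerance = 1e-12)
  expect_equal(mg3$pi_q, (pay$pi_qp + qq$pi_pq) / 2, tolerance = 1e-12)
  expect_error(mixed_group_payoffs("WSLS", "AllD", i = 0, N = 3, b = 3),
               class = "grouprecip_invalid_argument")
  expect_error(mixed_group_payoffs("WSLS", "AllD", i = 3, N = 3, b = 3),
               class = "grouprecip_invalid_argument")
})

test_that("Fermi step probabilities obey the ratio identity", {
  st0 <- step_probabilities("WSLS", "AllD", i = 2, N = 5, b = 3, sigma_in = 0)
  expect_equal(st0$t_plus, st0$t_minus)
  expect_equal(st0$t_plus, (5 - 2) * 2 / (2 * 5 * (5 - 1)), tolerance = 1e-12)
  st <- step_probabilities("WSLS", "AllD", i = 2, N = 5, b = 3, sigma_in = 4)
  mg <- mixed_group_payoffs("WSLS", "AllD", i = 2, N = 5, b = 3)
  expect_equal(st$t_minus / st$t_plus, exp(4 * (mg$pi_q - mg$pi_p)),
               tolerance = 1e-10)
  expect_lte(st$t_plus + st$t_minus, 1)
})

test_that("closed-form fixation probability equals the absorbing-chain solve", {
  pairs <- list(c(6, 15), c(10, 15), c(0, 6), c(7, 6), c(14, 2))
  for (N in c(2, 4, 6)) {
    for (ids in pairs) {
      # moderate selection keeps the oracle linear system well-conditioned
      rho <- fixation_probability(ids[1], ids[2], N = N, b = 3,
                                  sigma_in = 2, e = 1e-3)
      steps <- intra_chain_steps(ids[1], ids[2], N = N, b = 3,
                                 sigma_in = 2, e = 1e-3)
      expect_equal(rho, bd_absorption_prob(steps$tp, steps$tm),
                   tolerance = 1e-10,
                   info = sprintf("N=%d pair %d,%d", N, ids[1], ids[2]))
    }
  }
})

test_that("neutral drift fixes with probability 1/N", {
  for (N in c(2, 5, 50)) {
    expect_equal(fixation_probability("WSLS", "AllD", N = N, b = 3,
                                      sigma_in = 0, e = 1e-3),
                 1 / N, tolerance = 1e-12)
  }
  # vanishing selection approaches neutral drift
  expect_equal(fixation_probability("WSLS", "AllD", N = 10, b = 3,
                                    sigma_in = 1e-8, e = 1e-3),
               1 / 10, tolerance = 1e-6)
})

test_that("fixation-ratio closed form agrees with the quotient of probabilities", {
  set.seed(42)
  pair_sample <- replicate(12, sample(0:15, 2), simplify = FALSE)
  for (N in c(2, 4, 32)) {
    for (ids in pair_sample) {
      ratio <- fixation_ratio(ids[1], ids[2], N = N, b = 1.5,
                              sigma_in = 2, e = 1e-3)
      quot <- fixation_probability(ids[1], ids[2], N = N, b = 1.5,
                                   sigma_in = 2, e = 1e-3) /
        fixation_probability(ids[2], ids[1], N = N, b = 1.5,
                             sigma_in = 2, e = 1e-3)
      expect_equal(ratio, quot, tolerance = 1e-8,
                   info = sprintf("N=%d pair %d,%d", N, ids[1], ids[2]))
      if (ids[1] == ids[2]) expect_equal(ratio, 1)
    }
  }
  # N = 2 reduces to a single Fermi comparison
  pay <- pair_game("WSLS", "AllD", b = 3, e = 1e-3)
  expect_equal(fixation_ratio("WSLS", "AllD", N = 2, b = 3, sigma_in = 3,
                              e = 1e-3),
               exp(3 * (pay$pi_pq - pay$pi_qp)), tolerance = 1e-10)
})

test_that("Tit-for-Tat is neutral in a group of two in the error-free limit", {
  for (q in c(0, 3, 7, 14, 15)) {
    for (b in c(1.5, 3, 6)) {
      expect_equal(fixation_probability("TFT", q, N = 2, b = b,
                                        sigma_in = 10, e = 0),
                   0.5, tolerance = 1e-12,
                   info = sprintf("q=%d b=%g", q, b))
    }
  }
  # with errors the equality is broken only at O(e)
  pay <- pair_game("TFT", "AllD", b = 3, e = 1e-3)
  expect_lt(abs(pay$pi_pq - pay$pi_qp), 4 * 3 * 1e-3)
  expect_gt(abs(pay$pi_pq - pay$pi_qp), 0)
})

test_that("payoff transformations re-express the direct payoff difference", {
  pairs <- list(c(6, 15), c(6, 7), c(10, 0), c(9, 12))
  for (ids in pairs) {
    for (N in c(3, 4, 7)) {
      for (i in seq_len(N - 1)) {
        mg <- mixed_group_payoffs(ids[1], ids[2], i = i, N = N, b = 3,
                                  e = 1e-3)
        direct <- mg$pi_p - mg$pi_q
        expect_equal(transformed_payoff_difference(ids[1], ids[2], i = i,
                                                   N = N, b = 3, e = 1e-3,
                                                   variant = "prime"),
                     direct, tolerance = 1e-10)
        expect_equal(transformed_payoff_difference(ids[1], ids[2], i = i,
                                                   N = N, b = 3, e = 1e-3,
                                                   variant = "tilde"),
                     direct, tolerance = 1e-10)
      }
    }
  }
  expect_error(transformed_payoff_difference("WSLS", "AllD", i = 1, N = 2,
                                             b = 3),
               class = "grouprecip_invalid_argument")
})
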