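test_that("degenerate and neutral resident chains behave as expected", {
  # singleton set: all mass on the only strategy
  d1 <- run_resident_chain(set = 6L, N = 2, M = 4, b = 3, steps = 100,
                           seed = 1)
  expect_equal(d1$abundance$abundance, 1)
  # neutral parameters: uniform within Monte Carlo error
  set <- c(0L, 6L, 10L, 15L)
  d0 <- run_resident_chain(set = set, N = 4, M = 5, b = 3, sigma_in = 0,
                           sigma_out = 0, steps = 4e4, seed = 3)
  # neutral switch rate: non-self draw (3/4) times psi = 1/(N M)
  n_switch <- 4e4 * (3 / 4) * (1 / (4 * 5))
  se <- sqrt(0.25 * 0.75 / n_switch)
  expect_true(all(abs(d0$abundance$abundance - 0.25) < 3 * se))
  expect_equal(sum(d0$abundance$abundance), 1, tolerance = 1e-12)
})

test_that("two-strategy abundances follow detailed balance", {
  # moderate selection so both transition rates stay well off zero
  pf <- population_fixation(6L, 15L, N = 2, M = 5, b = 2, sigma_in = 1,
                            sigma_out = 1, e = 1e-3)
  a_p <- pf$psi_pq / (pf$psi_pq + pf$psi_qp) # stationary WSLS occupancy
  steps <- 1e5
  d <- run_resident_chain(set = c(6L, 15L), N = 2, M = 5, b = 2,
                          sigma_in = 1, sigma_out = 1, steps = steps,
                          seed = 5)
  # error scale set by the number of resident switches (renewal cycles)
  n_cyc <- steps / 2 * (pf$psi_pq * (1 - a_p) + pf$psi_qp * a_p)
  se <- sqrt(a_p * (1 - a_p) / n_cyc)
  got <- d$abundance$abundance[d$abundance$id == 6]
  expect_lt(abs(got - a_p), 3 * se)
})

test_that("Monte Carlo agrees with the exact embedded-chain stationary distribution", {
  set <- c(0L, 6L, 7L, 10L, 15L)
  exact <- resident_chain_exact(set = set, N = 2, M = 10, b = 2,
                                sigma_in = 2, sigma_out = 2, e = 1e-3)
  # independent oracle: direct solve of the explicitly assembled chain
  psi <- psi_matrix(set = set, N = 2, M = 10, b = 2, sigma_in = 2,
                    sigma_out = 2, e = 1e-3)
  P <- t(psi) / length(set)
  diag(P) <- 1 - rowSums(P)
  expect_equal(exact$abundance$abundance, markov_stationary_oracle(P),
               tolerance = 1e-10)
  mc <- run_resident_chain(set = set, N = 2, M = 10, b = 2, sigma_in = 2,
                           sigma_out = 2, e = 1e-3, steps = 2e5, seed = 11)
  expect_lt(max(abs(mc$abundance$abundance - exact$abundance$abundance)),
            0.02)
})

test_that("identical seeds reproduce identical simulations", {
  a <- run_resident_chain(N = 2, M = 6, b = 3, steps = 5e3, seed = 99)
  b <- run_resident_chain(N = 2, M = 6, b = 3, steps = 5e3, seed = 99)
  expect_identical(a$abundance, b$abundance)
  c <- run_resident_chain(N = 2, M = 6, b = 3, steps = 5e3, seed = 100)
  expect_false(identical(a$abundance$abundance, c$abundance$abundance))
})

test_that("mean cooperation composes abundances with self-cooperation levels", {
  alld <- tibble::tibble(id = 15L, abundance = 1)
  expect_lt(mean_cooperation(alld, e = 1e-3), 5e-3)
  expect_equal(mean_cooperation(alld, e = 0), 0)
  wsls <- tibble::tibble(id = 6L, abundance = 1)
  expect_gt(mean_cooperation(wsls, e = 1e-3), 0.99)
  half <- tibble::tibble(id = c(0L, 15L), abundance = c(0.5, 0.5))
  expect_equal(mean_cooperation(half, e = 0), 0.5)
})

test_that("transition graphs flag but keep sub-threshold edges", {
  g <- transition_graph(N = 120, M = 1, b = 3, e = 1e-3)
  expect_equal(nrow(g$edges), 20) # all ordered pairs, no diagonal
  expect_true(any(!g$edges$above))
  # well-mixed, intermediate benefit: an above-threshold path from every
  # strategy ends at WSLS, and WSLS has no above-threshold exits
  strong <- g$edges[g$edges$above, ]
  expect_false(any(strong$from == "WSLS"))
  reach_wsls <- function(from, seen = character()) {
    if (from == "WSLS") return(TRUE)
    nxt <- strong$to[strong$from == from & !(strong$to %in% seen)]
    any(vapply(nxt, reach_wsls, logical(1), seen = c(seen, from)))
  }
  for (s in c("AllC", "S_7", "TFT", "AllD")) {
    expect_true(reach_wsls(s), info = s)
  }
  # group-structured case: S_7 invades a WSLS resident
  g2 <- transition_graph(N = 2, M = 60, b = 3, e = 1e-3)
  edge <- g2$edges[g2$edges$from == "WSLS" & g2$edges$to == "S_7", ]
  expect_true(edge$above)
  # DOT export round-trip
  path <- tempfile(fileext = ".dot")
  on.exit(unlink(path), add = TRUE)
  write_dot(g, path)
  expect_true(any(grepl("->", readLines(path))))
})

test_that("sweeps attach one seeded run per grid cell", {
  grid <- tidyr::expand_grid(N = 2, M = c(2, 4), b = c(1.5, 3))
  out <- sweep_cooperation(grid, set = c(6L, 15L), steps = 2e3, seed = 1)
  expect_equal(nrow(out), 4)
  expect_true(all(out$mean_cooperation >= 0 & out$mean_cooperation <= 1))
  expect_equal(length(unique(out$seed)), 4)
  out2 <- sweep_cooperation(grid, set = c(6L, 15L), steps = 2e3, seed = 1)
  expect_identical(out$mean_cooperation, out2$mean_cooperation)
})
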