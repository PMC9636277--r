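# Monte Carlo of the embedded resident-mutant chain under complete
# separation of time scales: the population is homogeneous between rare
# mutations; a uniform mutant replaces the resident with the population-wide
# fixation probability.

#' Matrix of population-wide fixation probabilities
#'
#' `psi[m, r]` is the probability that a single mutant with the m-th strategy
#' of `set` replaces a homogeneous resident population of the r-th strategy.
#' The diagonal is 0 (a self-draw changes nothing).
#'
#' @param set Integer vector of deterministic strategy ids.
#' @inheritParams population_fixation
#' @return A `|set| x |set|` matrix with dimnames set to the strategy labels.
#' @export
psi_matrix <- function(set = 0:15, N, M, b, sigma_in = 10, sigma_out = 10,
                       e = 1e-3) {
  k <- length(set)
  labels <- purrr::map_chr(set, ~ attr(strategy_from_id(.x), "label"))
  psi <- matrix(0, k, k, dimnames = list(labels, labels))
  for (a in seq_len(k)) {
    for (d in seq_len(k)) {
      if (a == d) next
      pf <- population_fixation(set[a], set[d], N = N, M = M, b = b,
                                sigma_in = sigma_in, sigma_out = sigma_out,
                                e = e)
      psi[a, d] <- pf$psi_pq
    }
  }
  psi
}

new_strategy_distribution <- function(abundance, set, params, extra = list()) {
  labels <- purrr::map_chr(set, ~ attr(strategy_from_id(.x), "label"))
  out <- list(
    abundance = tibble::tibble(id = set, label = labels,
                               abundance = as.numeric(abundance)),
    params = params
  )
  structure(c(out, extra), class = "strategy_distribution")
}

#' @export
print.strategy_distribution <- function(x, ...) {
  cat("<strategy_distribution>\n")
  p <- x$params
  cat(sprintf("  N = %s, M = %s, b = %s, sigma_in = %s, sigma_out = %s, e = %s\n",
              p$N, p$M, p$b, p$sigma_in, p$sigma_out, p$e))
  if (!is.null(p$steps)) cat(sprintf("  steps = %s (burn-in %s), seed = %s\n",
                                     p$steps, p$burn_in, p$seed))
  print(dplyr::arrange(x$abundance, dplyr::desc(.data$abundance)), n = 5)
  invisible(x)
}

#' Simulate the resident-mutant chain
#'
#' Runs the embedded Markov chain of homogeneous resident populations: at
#' each step a mutant strategy is drawn uniformly from `set` and replaces
#' the resident with the population-wide fixation probability. The
#' abundance of a strategy is the fraction of post-burn-in steps during
#' which it was resident. Fixation probabilities are cached in a matrix
#' before the loop, so the cost is `|set|^2` analytic evaluations plus a
#' fast simulation loop.
#'
#' @param set Integer vector of deterministic strategy ids.
#' @inheritParams population_fixation
#' @param steps Number of Monte Carlo steps.
#' @param burn_in_fraction Fraction of initial steps discarded.
#' @param seed Integer seed (used via R's RNG).
#' @param runs Number of independent runs averaged (seeds `seed + 0:(runs-1)`).
#' @return A `strategy_distribution` object: a tibble of abundances plus the
#'   run metadata and the cached fixation-probability matrix.
#' @examples
#' run_resident_chain(set = c(0, 6, 7, 10, 15), N = 2, M = 60, b = 1.5,
#'                    steps = 1e4, seed = 1)
#' @export
run_resident_chain <- function(set = 0:15, N, M, b, sigma_in = 10,
                               sigma_out = 10, e = 1e-3, steps = 1e6,
                               burn_in_fraction = 0.1, seed = 1, runs = 1) {
  stopifnot(steps >= 1, runs >= 1)
  psi <- psi_matrix(set, N = N, M = M, b = b, sigma_in = sigma_in,
                    sigma_out = sigma_out, e = e)
  k <- length(set)
  burn <- floor(steps * burn_in_fraction)
  acc <- rep(0, k)
  for (run in seq_len(runs)) {
    set.seed(seed + run - 1L)
    start <- sample.int(k, 1)
    sim <- resident_chain_cpp(psi, as.integer(steps), as.integer(burn), start)
    acc <- acc + sim$counts / sum(sim$counts)
  }
  params <- list(N = N, M = M, b = b, sigma_in = sigma_in,
                 sigma_out = sigma_out, e = e, steps = steps,
                 burn_in = burn, seed = seed, runs = runs)
  new_strategy_distribution(acc / runs, set, params, extra = list(psi = psi))
}

#' Exact stationary distribution of the resident-mutant chain
#'
#' Builds the `|set| x |set|` stochastic matrix of the embedded chain
#' (off-diagonal entries `psi[m, r] / |set|`) and solves for its stationary
#' distribution directly. Useful as an independent check of the Monte Carlo
#' route for moderate selection strengths; very strong selection can
#' underflow the fixation probabilities, which is why the simulation is the
#' primary path.
#'
#' @inheritParams psi_matrix
#' @return A `strategy_distribution` object.
#' @export
resident_chain_exact <- function(set = 0:15, N, M, b, sigma_in = 10,
                                 sigma_out = 10, e = 1e-3) {
  psi <- psi_matrix(set, N = N, M = M, b = b, sigma_in = sigma_in,
                    sigma_out = sigma_out, e = e)
  k <- length(set)
  P <- t(psi) / k # P[r, m]: probability resident r -> resident m
  diag(P) <- 1 - rowSums(P)
  A <- t(P) - diag(k)
  A[k, ] <- 1
  v <- solve(A, c(rep(0, k - 1), 1))
  if (any(v < -1e-10)) abort_numeric_range("stationary solve lost positivity.")
  v <- pmax(v, 0); v <- v / sum(v)
  params <- list(N = N, M = M, b = b, sigma_in = sigma_in,
                 sigma_out = sigma_out, e = e)
  new_strategy_distribution(v, set, params, extra = list(psi = psi))
}

#' Mean cooperation level of a strategy distribution
#'
#' Under complete separation of time scales the population is homogeneous
#' at almost every instant, so the average cooperation level is the
#' abundance-weighted self-cooperation level `sum_p x_p * gamma_pp(e)` of
#' the resident strategies, evaluated at the same error rate as the
#' dynamics.
#'
#' @param dist A `strategy_distribution` (or a tibble with `id` and
#'   `abundance` columns).
#' @param e Error rate used for the self-cooperation levels.
#' @return Mean cooperation level in `[0, 1]`.
#' @export
mean_cooperation <- function(dist, e = 1e-3) {
  tab <- if (inherits(dist, "strategy_distribution")) dist$abundance else dist
  gammas <- purrr::map_dbl(tab$id, function(id) {
    if (e == 0) self_cooperation_limit(id)$value
    else pair_game(id, id, b = 2, e = e)$gamma_pq
  })
  sum(tab$abundance * gammas)
}

#' Fixation-probability transition graph
#'
#' All ordered-pair population-wide fixation probabilities over a strategy
#' set, with edges below `threshold` flagged (not removed). The default set
#' is the five representative strategies AllC, WSLS, S_7, TFT, AllD.
#'
#' @param set Integer vector of strategy ids.
#' @inheritParams population_fixation
#' @param threshold Edges with `psi` below this are flagged `above = FALSE`.
#' @return A `transition_graph` object wrapping an edge tibble
#'   (`from_id`, `from`, `to_id`, `to`, `psi`, `above`); the edge
#'   `from -> to` carries the probability that a `to`-mutant invades and
#'   fixes in a `from`-resident population.
#' @export
transition_graph <- function(set = c(0L, 6L, 7L, 10L, 15L), N, M, b,
                             sigma_in = 10, sigma_out = 10, e = 1e-3,
                             threshold = 0.1) {
  psi <- psi_matrix(set, N = N, M = M, b = b, sigma_in = sigma_in,
                    sigma_out = sigma_out, e = e)
  labels <- rownames(psi)
  grid <- tidyr::expand_grid(from = seq_along(set), to = seq_along(set))
  grid <- dplyr::filter(grid, .data$from != .data$to)
  edges <- purrr::pmap_dfr(grid, function(from, to) {
    tibble::tibble(from_id = set[from], from = labels[from],
                   to_id = set[to], to = labels[to],
                   psi = psi[to, from])
  })
  edges$above <- edges$psi >= threshold
  structure(list(edges = edges, threshold = threshold,
                 params = list(N = N, M = M, b = b, sigma_in = sigma_in,
                               sigma_out = sigma_out, e = e)),
            class = "transition_graph")
}

#' @export
print.transition_graph <- function(x, ...) {
  cat(sprintf("<transition_graph> %d edges (threshold %.2g)\n",
              nrow(x$edges), x$threshold))
  print(dplyr::arrange(x$edges, dplyr::desc(.data$psi)), n = 10)
  invisible(x)
}

#' Export a transition graph as Graphviz DOT
#'
#' @param graph A `transition_graph`.
#' @param path Output file path.
#' @param above_only Write only edges at or above the threshold.
#' @return The path, invisibly.
#' @export
write_dot <- function(graph, path, above_only = TRUE) {
  stopifnot(inherits(graph, "transition_graph"))
  edges <- graph$edges
  if (above_only) edges <- dplyr::filter(edges, .data$above)
  lines <- c(
    "digraph transitions {",
    sprintf("  \"%s\" -> \"%s\" [label=\"%.3f\", penwidth=%.2f];",
            edges$from, edges$to, edges$psi, pmax(0.5, 6 * edges$psi)),
    "}"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Cooperation sweep over population structures
#'
#' Runs one resident-mutant chain per grid cell and records the mean
#' cooperation level. Each cell gets its own deterministic seed derived
#' from `seed` and the cell index.
#'
#' @param grid A data frame with columns `N`, `M`, `b` (one row per cell).
#' @inheritParams run_resident_chain
#' @return The input grid with `seed`, `mean_cooperation`, and the most
#'   abundant strategy per cell.
#' @export
sweep_cooperation <- function(grid, set = 0:15, sigma_in = 10, sigma_out = 10,
                              e = 1e-3, steps = 1e5, burn_in_fraction = 0.1,
                              seed = 1, runs = 1) {
  stopifnot(all(c("N", "M", "b") %in% names(grid)))
  grid <- tibble::as_tibble(grid)
  out <- purrr::pmap_dfr(
    list(grid$N, grid$M, grid$b, seq_len(nrow(grid))),
    function(N, M, b, cell) {
      cell_seed <- seed + 1000L * cell
      dist <- run_resident_chain(set = set, N = N, M = M, b = b,
                                 sigma_in = sigma_in, sigma_out = sigma_out,
                                 e = e, steps = steps,
                                 burn_in_fraction = burn_in_fraction,
                                 seed = cell_seed, runs = runs)
      top <- dplyr::slice_max(dist$abundance, .data$abundance, n = 1,
                              with_ties = FALSE)
      tibble::tibble(N = N, M = M, b = b, seed = cell_seed,
                     mean_cooperation = mean_cooperation(dist, e = e),
                     top_strategy = top$label, top_abundance = top$abundance)
    })
  out
}
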