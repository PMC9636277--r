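#include <Rcpp.h>
using namespace Rcpp;

// Monte Carlo loop of the resident-mutant chain under complete separation of
// time scales. psi(m, r) is the probability that a single mutant of strategy
// m replaces a resident population of strategy r. Uses R's RNG stream so
// results are reproducible from set.seed().
//
// Returns the per-strategy occupation counts over the post-burn-in steps and
// the final resident index (1-based).
// [[Rcpp::export]]
List resident_chain_cpp(NumericMatrix psi, int steps, int burn_in, int start) {
  int k = psi.nrow();
  std::vector<double> counts(k, 0.0);
  int res = start - 1;
  for (int t = 0; t < steps; ++t) {
    int mut = (int)(unif_rand() * k);
    if (mut >= k) mut = k - 1;
    if (mut != res && unif_rand() < psi(mut, res)) res = mut;
    if (t >= burn_in) counts[res] += 1.0;
  }
  return List::create(_["counts"] = NumericVector(counts.begin(), counts.end()),
                      _["final"] = res + 1);
}

// Group-level Monte Carlo for the partial-separation regime. state holds the
// strategy index (0-based) of each of the M homogeneous groups. Per
// elementary step: pick a group i; with probability r a mutation hits it (a
// uniform mutant fixes with probability rho(mut, cur)); otherwise an
// out-group role model j != i is drawn and its strategy fixes with
// probability fermi(sigma_out * (pi_cur - pi_role)) * rho(role, cur).
// Occupation counts are accumulated per elementary step after burn_in steps.
// [[Rcpp::export]]
List group_mc_cpp(IntegerVector state0, NumericMatrix rho, NumericVector selfpay,
                  double sigma_out, double r, double total_steps,
                  double burn_in_steps) {
  int k = rho.nrow();
  int m = state0.size();
  std::vector<int> state(state0.begin(), state0.end());
  std::vector<double> ncur(k, 0.0), acc(k, 0.0);
  for (int g = 0; g < m; ++g) ncur[state[g]] += 1.0;
  double kept = 0.0;
  for (double t = 0; t < total_steps; ++t) {
    int i = (int)(unif_rand() * m);
    if (i >= m) i = m - 1;
    int cur = state[i];
    int newstrat = -1;
    if (unif_rand() < r) {
      int mut = (int)(unif_rand() * k);
      if (mut >= k) mut = k - 1;
      if (mut != cur && unif_rand() < rho(mut, cur)) newstrat = mut;
    } else if (m > 1) {
      int j = (int)(unif_rand() * (m - 1));
      if (j >= m - 1) j = m - 2;
      if (j >= i) ++j;
      int role = state[j];
      if (role != cur) {
        double f = 1.0 / (1.0 + std::exp(sigma_out * (selfpay[cur] - selfpay[role])));
        if (unif_rand() < f * rho(role, cur)) newstrat = role;
      }
    }
    if (newstrat >= 0) {
      ncur[cur] -= 1.0;
      ncur[newstrat] += 1.0;
      state[i] = newstrat;
    }
    if (t >= burn_in_steps) {
      for (int s = 0; s < k; ++s) acc[s] += ncur[s];
      kept += 1.0;
    }
  }
  NumericVector abundance(k);
  for (int s = 0; s < k; ++s) abundance[s] = acc[s] / (kept * m);
  return List::create(_["abundance"] = abundance,
                      _["final_state"] = IntegerVector(state.begin(), state.end()));
}
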