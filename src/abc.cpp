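#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Mean plain Euclidean distance from the rows of X to the center z.
// Plain double accumulation in row-major order; the pure-R reference
// backend accumulates in the identical order so both paths agree bitwise.
static double center_cost(const NumericMatrix &X, const std::vector<double> &z) {
  const int n = X.nrow(), d = X.ncol();
  double total = 0.0;
  for (int r = 0; r < n; ++r) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) {
      double diff = X(r, j) - z[j];
      s += diff * diff;
    }
    total += std::sqrt(s);
  }
  return total / n;
}

// Artificial bee colony minimization of the within-class mean-distance
// cost over the box [lower, upper]. Random draws come from R's global
// stream (seed with set.seed() before calling) in the same order as the
// pure-R run_abc(): initialization food-by-food / dimension-by-dimension,
// then per cycle employed moves, onlooker roulette + moves, scout.
// [[Rcpp::export]]
List abc_cluster_cpp(NumericMatrix samples, NumericVector lower,
                     NumericVector upper, int sn, int mcn, int limit) {
  const int d = samples.ncol();
  if (samples.nrow() < 1) stop("samples must be nonempty");
  if (lower.size() != d || upper.size() != d)
    stop("bounds must match the sample dimension");
  if (sn < 2) stop("at least two food sources are required");

  std::vector<std::vector<double>> pos(sn, std::vector<double>(d));
  std::vector<double> cost(sn), fit(sn);
  std::vector<int> trials(sn, 0);

  for (int i = 0; i < sn; ++i) {
    for (int j = 0; j < d; ++j)
      pos[i][j] = lower[j] + unif_rand() * (upper[j] - lower[j]);
    cost[i] = center_cost(samples, pos[i]);
    fit[i] = 1.0 / (1.0 + cost[i]);
  }

  int b = 0;
  for (int i = 1; i < sn; ++i)
    if (cost[i] < cost[b]) b = i;
  std::vector<double> best_position = pos[b];
  double best_cost = cost[b];
  NumericVector history(mcn + 1);
  history[0] = best_cost;

  std::vector<double> cand(d);
  // one neighbor move + greedy selection on food i
  auto try_move = [&](int i) {
    int j = (int)std::floor(unif_rand() * d);
    if (j >= d) j = d - 1;
    int k0 = (int)std::floor(unif_rand() * (sn - 1));
    if (k0 >= sn - 1) k0 = sn - 2;
    int k = (k0 < i) ? k0 : k0 + 1;
    double phi = -1.0 + 2.0 * unif_rand();
    cand = pos[i];
    double v = cand[j] + phi * (cand[j] - pos[k][j]);
    if (v < lower[j]) v = lower[j];
    if (v > upper[j]) v = upper[j];
    cand[j] = v;
    double c = center_cost(samples, cand);
    if (c <= cost[i]) {
      pos[i] = cand;
      cost[i] = c;
      fit[i] = 1.0 / (1.0 + c);
      trials[i] = 0;
    } else {
      trials[i] += 1;
    }
  };

  std::vector<double> cum(sn);
  for (int cyc = 0; cyc < mcn; ++cyc) {
    // employed phase
    for (int i = 0; i < sn; ++i) try_move(i);
    // onlooker phase: probabilities fixed at phase start
    {
      // R's sum()/cumsum() accumulate in extended precision; match them
      // so the roulette decisions agree with the pure-R backend
      long double total = 0.0L;
      for (int i = 0; i < sn; ++i) total += fit[i];
      double tot = (double)total;
      long double acc = 0.0L;
      for (int i = 0; i < sn; ++i) {
        acc += fit[i] / tot;
        cum[i] = (double)acc;
      }
    }
    for (int t = 0; t < sn; ++t) {
      double u = unif_rand();
      int i = sn - 1;
      for (int q = 0; q < sn; ++q) {
        if (cum[q] >= u) { i = q; break; }
      }
      try_move(i);
    }
    // scout phase: at most one per cycle (first-largest trial counter)
    {
      int s = 0;
      for (int i = 1; i < sn; ++i)
        if (trials[i] > trials[s]) s = i;
      if (trials[s] > limit) {
        for (int j = 0; j < d; ++j)
          pos[s][j] = lower[j] + unif_rand() * (upper[j] - lower[j]);
        cost[s] = center_cost(samples, pos[s]);
        fit[s] = 1.0 / (1.0 + cost[s]);
        trials[s] = 0;
      }
    }
    // track best-ever
    int cb = 0;
    for (int i = 1; i < sn; ++i)
      if (cost[i] < cost[cb]) cb = i;
    if (cost[cb] < best_cost) {
      best_cost = cost[cb];
      best_position = pos[cb];
    }
    history[cyc + 1] = best_cost;
  }

  NumericMatrix positions(sn, d);
  for (int i = 0; i < sn; ++i)
    for (int j = 0; j < d; ++j) positions(i, j) = pos[i][j];

  return List::create(
      _["positions"] = positions,
      _["costs"] = NumericVector(cost.begin(), cost.end()),
      _["trials"] = IntegerVector(trials.begin(), trials.end()),
      _["best_position"] = NumericVector(best_position.begin(), best_position.end()),
      _["best_cost"] = best_cost,
      _["cost_history"] = history);
}
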