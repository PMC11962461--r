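#include <Rcpp.h>
using namespace Rcpp;

// Exact SSA on a column-source rate table. cumR is (n+4) x n: column j holds
// the cumulative jump rates out of state j (targets 1..n transient, n+1..n+4
// sinks). exit[j] is the total exit rate of state j. cum_ic is the cumulative
// initial distribution. Uses R's RNG so results follow set.seed().
// [[Rcpp::export]]
List gillespie_run(NumericMatrix cumR, NumericVector exit,
                   NumericVector cum_ic, int n, int n_traj) {
  IntegerVector fate(n_traj);
  NumericVector time(n_traj);
  int m = cumR.nrow(); // n + 4
  for (int tr = 0; tr < n_traj; ++tr) {
    // sample initial state
    double u = unif_rand();
    int s = 0;
    while (s < n - 1 && u > cum_ic[s]) ++s;
    double t = 0.0;
    for (;;) {
      t += exp_rand() / exit[s];
      double v = unif_rand() * exit[s];
      // find smallest target with cumR[target, s] >= v
      int lo = 0, hi = m - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (cumR(mid, s) < v) lo = mid + 1; else hi = mid;
      }
      if (lo >= n) { fate[tr] = lo - n + 1; time[tr] = t; break; }
      s = lo;
    }
  }
  return List::create(_["fate"] = fate, _["time"] = time);
}
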