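#include <Rcpp.h>
using namespace Rcpp;

// Exact SSA for the 4-reaction toggle switch:
//   0 -> LacI  at  p_tet / (1 + (n_tet/k_tet)^n)
//   LacI -> 0  at  gamma * n_lac
//   0 -> TetR  at  p_lac / (1 + (n_lac/k_lac)^n)
//   TetR -> 0  at  gamma * n_tet
// Hill functions are evaluated on the integer counts directly.
// All randomness comes from R's RNG stream so set.seed() in R makes runs
// reproducible.

static inline double hill_rate(double p, double n, double k, double hill_n) {
  return p / (1.0 + std::pow(n / k, hill_n));
}

// Counts at each requested snapshot time (sorted, >= t0). A snapshot
// records the state holding at that instant. Returns an m x 2 integer
// matrix (n_lac, n_tet).
// [[Rcpp::export]]
IntegerMatrix ssa_snapshots_cpp(int n_lac, int n_tet, double t0,
                                NumericVector times,
                                double p_lac, double p_tet,
                                double k_lac, double k_tet,
                                double gamma_, double hill_n) {
  int m = times.size();
  IntegerMatrix out(m, 2);
  double t = t0;
  int idx = 0;
  while (idx < m) {
    double a1 = hill_rate(p_tet, n_tet, k_tet, hill_n);
    double a2 = gamma_ * n_lac;
    double a3 = hill_rate(p_lac, n_lac, k_lac, hill_n);
    double a4 = gamma_ * n_tet;
    double a0 = a1 + a2 + a3 + a4;
    if (a0 <= 0.0) { // absorbed (only possible when both promoters are off)
      for (; idx < m; ++idx) { out(idx, 0) = n_lac; out(idx, 1) = n_tet; }
      break;
    }
    double t_next = t + R::rexp(1.0 / a0);
    while (idx < m && times[idx] < t_next) {
      out(idx, 0) = n_lac; out(idx, 1) = n_tet; ++idx;
    }
    if (idx >= m) break;
    t = t_next;
    double u = unif_rand() * a0;
    if (u < a1)                ++n_lac;
    else if (u < a1 + a2)      --n_lac;
    else if (u < a1 + a2 + a3) ++n_tet;
    else                       --n_tet;
  }
  return out;
}

// Full event path up to t_end (capped at max_events reactions).
// [[Rcpp::export]]
List ssa_path_cpp(int n_lac, int n_tet, double t0, double t_end,
                  double p_lac, double p_tet,
                  double k_lac, double k_tet,
                  double gamma_, double hill_n, int max_events) {
  std::vector<double> tv; tv.reserve(1024);
  std::vector<int> lv, gv; lv.reserve(1024); gv.reserve(1024);
  double t = t0;
  tv.push_back(t); lv.push_back(n_lac); gv.push_back(n_tet);
  int ev = 0;
  bool truncated = false;
  while (t < t_end) {
    double a1 = hill_rate(p_tet, n_tet, k_tet, hill_n);
    double a2 = gamma_ * n_lac;
    double a3 = hill_rate(p_lac, n_lac, k_lac, hill_n);
    double a4 = gamma_ * n_tet;
    double a0 = a1 + a2 + a3 + a4;
    if (a0 <= 0.0) { t = t_end; break; }
    double tau = R::rexp(1.0 / a0);
    if (t + tau > t_end) { t = t_end; break; }
    t += tau;
    double u = unif_rand() * a0;
    if (u < a1)                ++n_lac;
    else if (u < a1 + a2)      --n_lac;
    else if (u < a1 + a2 + a3) ++n_tet;
    else                       --n_tet;
    tv.push_back(t); lv.push_back(n_lac); gv.push_back(n_tet);
    if (++ev >= max_events) { truncated = true; break; }
  }
  return List::create(_["t"] = tv, _["n_lacI"] = lv, _["n_tetR"] = gv,
                      _["t_final"] = t,
                      _["final"] = IntegerVector::create(n_lac, n_tet),
                      _["truncated"] = truncated);
}

// Final counts for a whole ensemble run through one phase (each row of
// counts0 advanced from t0 to t_end independently, sequential RNG draws).
// [[Rcpp::export]]
IntegerMatrix ssa_ensemble_cpp(IntegerMatrix counts0, double duration,
                               double p_lac, double p_tet,
                               double k_lac, double k_tet,
                               double gamma_, double hill_n) {
  int nc = counts0.nrow();
  IntegerMatrix out(nc, 2);
  NumericVector one = NumericVector::create(duration);
  for (int i = 0; i < nc; ++i) {
    IntegerMatrix fin = ssa_snapshots_cpp(counts0(i, 0), counts0(i, 1), 0.0,
                                          one, p_lac, p_tet, k_lac, k_tet,
                                          gamma_, hill_n);
    out(i, 0) = fin(0, 0); out(i, 1) = fin(0, 1);
  }
  return out;
}
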