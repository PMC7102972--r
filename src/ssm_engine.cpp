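// Gillespie (direct-method) engine for the synthetase sequestration model:
// per tRNA species a 3-state cycle empty -> bound -> charged -> empty with
// mass-action propensities
//   e->b : k1 * (Etilde - b) * e     (association with a free synthetase)
//   b->e : k0 * b                    (dissociation before transfer)
//   b->c : k2 * b                    (aminoacyl transfer)
//   c->e : f * k3 * c                (usage by translation, growth-coupled)
// Counts are integers; totals e+b+c are conserved exactly per species.
// Randomness comes from R's RNG so set.seed() reproduces trajectories.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List ssm_engine_cpp(IntegerVector e0, IntegerVector b0, IntegerVector c0,
                    NumericVector Etilde, NumericVector k1, NumericVector k0,
                    NumericVector k2, double k3, double f,
                    double t_end, double burn_in, int n_batch,
                    double max_events) {
  const int n = e0.size();
  std::vector<double> e(n), b(n), c(n);
  for (int s = 0; s < n; ++s) {
    e[s] = e0[s]; b[s] = b0[s]; c[s] = c0[s];
    if (b[s] > Etilde[s] + 1e-9)
      stop("bound count exceeds synthetase abundance for species %d", s + 1);
  }

  double t = 0.0, t_acc = 0.0, total_events = 0.0;
  bool truncated = false;
  std::vector<double> int_e(n, 0.0), int_b(n, 0.0), int_c(n, 0.0);
  const double T_rec = std::max(t_end - burn_in, 0.0);
  const double batch_len = T_rec > 0 ? T_rec / n_batch : 1.0;
  NumericMatrix int_c_batch(n, n_batch), int_u_batch(n, n_batch);
  std::vector<double> a(4 * n);
  double counts[4] = {0, 0, 0, 0};

  RNGScope scope;

  while (t < t_end) {
    double A = 0.0;
    for (int s = 0; s < n; ++s) {
      a[4 * s + 0] = k1[s] * std::max(Etilde[s] - b[s], 0.0) * e[s];
      a[4 * s + 1] = k0[s] * b[s];
      a[4 * s + 2] = k2[s] * b[s];
      a[4 * s + 3] = f * k3 * c[s];
      A += a[4 * s] + a[4 * s + 1] + a[4 * s + 2] + a[4 * s + 3];
    }
    double t_next = A > 0 ? t + exp_rand() / A : t_end;
    if (t_next > t_end) t_next = t_end;
    double lo = std::max(t, burn_in);
    if (t_next > lo) {
      double w = t_next - lo;
      t_acc += w;
      int bt = std::min((int)((0.5 * (lo + t_next) - burn_in) / batch_len),
                        n_batch - 1);
      for (int s = 0; s < n; ++s) {
        int_e[s] += w * e[s]; int_b[s] += w * b[s]; int_c[s] += w * c[s];
        if (bt >= 0) {
          int_c_batch(s, bt) += w * c[s];
          int_u_batch(s, bt) += w * (e[s] + b[s]);
        }
      }
    }
    if (A <= 0 || t_next >= t_end) { t = t_end; break; }
    t = t_next;

    double r = unif_rand() * A;
    int pick = 4 * n - 1;
    for (int k = 0; k < 4 * n; ++k) {
      r -= a[k];
      if (r <= 0) { pick = k; break; }
    }
    int s = pick / 4, rxn = pick % 4;
    switch (rxn) {
      case 0: e[s] -= 1; b[s] += 1; break;
      case 1: b[s] -= 1; e[s] += 1; break;
      case 2: b[s] -= 1; c[s] += 1; break;
      case 3: c[s] -= 1; e[s] += 1; break;
    }
    counts[rxn] += 1;
    if (++total_events >= max_events) { truncated = true; break; }
  }

  NumericVector me(n), mb(n), mc(n);
  for (int s = 0; s < n; ++s) {
    me[s] = t_acc > 0 ? int_e[s] / t_acc : NA_REAL;
    mb[s] = t_acc > 0 ? int_b[s] / t_acc : NA_REAL;
    mc[s] = t_acc > 0 ? int_c[s] / t_acc : NA_REAL;
  }
  return List::create(
      _["mean_e"] = me, _["mean_b"] = mb, _["mean_c"] = mc,
      _["final_e"] = NumericVector(e.begin(), e.end()),
      _["final_b"] = NumericVector(b.begin(), b.end()),
      _["final_c"] = NumericVector(c.begin(), c.end()),
      _["t_record"] = t_acc, _["events"] = total_events,
      _["truncated"] = truncated, _["batch_len"] = batch_len,
      _["int_c_batch"] = int_c_batch, _["int_u_batch"] = int_u_batch,
      _["n_assoc"] = counts[0], _["n_dissoc"] = counts[1],
      _["n_charge"] = counts[2], _["n_usage"] = counts[3]);
}
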