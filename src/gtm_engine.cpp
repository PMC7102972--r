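// Exact continuous-time kinetic Monte Carlo engine for the whole-cell
// translation model: TASEP lattices with extended ribosome footprints, a
// shared finite ribosome pool driving a stepwise-linear initiation rate,
// codon-specific hopping proportional to cognate charged tRNA counts, and
// stochastic Michaelis-Menten recharging with isoacceptor competition.
//
// Conventions (must stay in sync with the R surface):
//  * Sites are 1-based; a lattice of a category has L = n_sense + 1 sites,
//    site L being the stop codon (termination only, never hopped into by
//    translation of a tRNA-decoded codon beyond L-1).
//  * The tracked position is the codon being translated; a ribosome at p
//    covers p..p+W-1, so exclusion is "tracked-position difference > W-1",
//    a hop from i to i+1 requires the next ribosome to sit at >= i+1+W,
//    and initiation requires the 5'-most ribosome to sit at > W.
//  * A hop out of site i consumes one charged tRNA cognate to codon i.
// All randomness comes from R's RNG (unif_rand/exp_rand), so set.seed()
// makes trajectories exactly reproducible.

#include <Rcpp.h>
#include <deque>
#include <vector>
using namespace Rcpp;

namespace {

struct Lat {
  int cat;                 // 0-based category index
  std::deque<int> pos;     // ascending tracked positions, 1-based
};

}  // namespace

// [[Rcpp::export]]
List gtm_engine_cpp(List lattice_species, List lattice_wobble,
                    IntegerVector copies, NumericVector alpha_eff,
                    int R_total, double R_star, int W,
                    double beta, double gamma, double lambda,
                    IntegerVector Tt, IntegerVector Tc0,
                    NumericVector vmax, NumericVector Km, IntegerVector aa,
                    double t_end, double burn_in,
                    int n_batch, bool record_density, double max_events) {
  const int n_cat = lattice_species.size();
  const int n_sp = Tt.size();
  int n_aa = 0;
  for (int s = 0; s < n_sp; ++s) n_aa = std::max(n_aa, aa[s] + 1);

  std::vector<IntegerVector> site_sp(n_cat);
  std::vector<NumericVector> site_w(n_cat);
  std::vector<int> Lcat(n_cat);
  for (int c = 0; c < n_cat; ++c) {
    site_sp[c] = as<IntegerVector>(lattice_species[c]);
    site_w[c] = as<NumericVector>(lattice_wobble[c]);
    Lcat[c] = site_sp[c].size() + 1;  // + stop site
  }

  std::vector<Lat> lats;
  for (int c = 0; c < n_cat; ++c)
    for (int k = 0; k < copies[c]; ++k) lats.push_back(Lat{c, {}});
  const int n_lat = (int)lats.size();

  std::vector<int> Tc(n_sp), Tu(n_sp);
  for (int s = 0; s < n_sp; ++s) {
    Tc[s] = Tc0[s];
    Tu[s] = Tt[s] - Tc0[s];
    if (Tu[s] < 0) stop("initial charged count exceeds total for species %d", s + 1);
  }
  int R_free = R_total, n_bound = 0;

  // Time-integrated observables (post burn-in only).
  double T_rec = std::max(t_end - burn_in, 0.0);
  double int_nbound = 0, int_Q = 0, int_alpha = 0, int_Rfree = 0, t_acc = 0;
  std::vector<double> int_Qi(n_sp, 0.0);
  std::vector<double> dens;  // per category x site, flattened
  std::vector<int> dens_off(n_cat + 1, 0);
  if (record_density) {
    for (int c = 0; c < n_cat; ++c) dens_off[c + 1] = dens_off[c] + Lcat[c];
    dens.assign(dens_off[n_cat], 0.0);
  }
  double hops = 0, inits = 0, drops = 0, terms = 0, rechs = 0;
  NumericVector term_cat(n_cat);
  NumericVector hops_b(n_batch), nbound_b(n_batch), term_b(n_batch);
  const double batch_len = T_rec > 0 ? T_rec / n_batch : 1.0;
  double total_events = 0;
  bool truncated = false;
  double t = 0.0;

  std::vector<double> chi(n_sp), sumTu(n_aa);
  std::vector<double> lat_alpha(n_lat);

  RNGScope scope;

  while (t < t_end) {
    // ---- propensities -------------------------------------------------
    for (int a = 0; a < n_aa; ++a) sumTu[a] = 0.0;
    for (int s = 0; s < n_sp; ++s) sumTu[aa[s]] += Tu[s];
    double a_rech = 0.0;
    for (int s = 0; s < n_sp; ++s) {
      chi[s] = Tu[s] > 0 ? vmax[s] * Tu[s] / (Km[s] + sumTu[aa[s]]) : 0.0;
      a_rech += chi[s];
    }

    double amin = R_free <= 0 ? 0.0
                              : (R_star > 0 ? std::min((double)R_free / R_star, 1.0) : 1.0);
    double a_init = 0.0, alpha_bar = 0.0;
    for (int l = 0; l < n_lat; ++l) {
      const Lat &La = lats[l];
      double al = alpha_eff[La.cat] * amin;
      alpha_bar += al;
      bool open = La.pos.empty() || La.pos.front() > W;
      lat_alpha[l] = open ? al : 0.0;
      a_init += lat_alpha[l];
    }
    if (n_lat > 0) alpha_bar /= n_lat;

    double a_el = 0.0;
    int n_stop = 0;
    for (int l = 0; l < n_lat; ++l) {
      Lat &La = lats[l];
      const int L = Lcat[La.cat];
      const IntegerVector &sp = site_sp[La.cat];
      const NumericVector &wb = site_w[La.cat];
      const int nr = (int)La.pos.size();
      for (int j = 0; j < nr; ++j) {
        int i = La.pos[j];
        if (i == L) { ++n_stop; continue; }
        bool blocked = (j + 1 < nr) && (La.pos[j + 1] - i <= W);
        if (!blocked) a_el += lambda * wb[i - 1] * Tc[sp[i - 1]];
      }
    }
    double a_term = beta * n_stop;
    double a_drop = gamma * (n_bound - n_stop);
    double A = a_init + a_el + a_term + a_drop + a_rech;

    // ---- advance clock, accumulate time averages ----------------------
    double t_next = A > 0 ? t + exp_rand() / A : t_end;
    if (t_next > t_end) t_next = t_end;
    double lo = std::max(t, burn_in), hi = t_next;
    if (hi > lo) {
      double w = hi - lo;
      t_acc += w;
      int_nbound += w * n_bound;
      int_Rfree += w * R_free;
      int_alpha += w * alpha_bar;
      double qbar = 0.0;
      for (int s = 0; s < n_sp; ++s) {
        double q = Tt[s] > 0 ? (double)Tc[s] / Tt[s] : 0.0;
        int_Qi[s] += w * q;
        qbar += q;
      }
      int_Q += w * (n_sp > 0 ? qbar / n_sp : 0.0);
      int b = std::min((int)((0.5 * (lo + hi) - burn_in) / batch_len), n_batch - 1);
      if (b >= 0) nbound_b[b] += w * n_bound;
      if (record_density) {
        for (int l = 0; l < n_lat; ++l) {
          const Lat &La = lats[l];
          for (size_t j = 0; j < La.pos.size(); ++j)
            dens[dens_off[La.cat] + La.pos[j] - 1] += w;
        }
      }
    }
    if (A <= 0 || t_next >= t_end) { t = t_end; break; }
    t = t_next;
    bool post = t > burn_in;
    int batch = post ? std::min((int)((t - burn_in) / batch_len), n_batch - 1) : -1;

    // ---- select and execute one event ---------------------------------
    double r = unif_rand() * A;
    if (r < a_init) {
      // initiation: pick an open lattice proportional to its rate
      int pick = -1;
      for (int l = 0; l < n_lat; ++l) {
        if (lat_alpha[l] <= 0) continue;
        r -= lat_alpha[l];
        if (r <= 0) { pick = l; break; }
        pick = l;
      }
      lats[pick].pos.push_front(1);
      --R_free; ++n_bound;
      if (post) ++inits;
    } else if ((r -= a_init) < a_el) {
      // elongation: rescan for the chosen ribosome
      int pl = -1, pj = -1, fl = -1, fj = -1;
      bool found = false;
      for (int l = 0; l < n_lat && !found; ++l) {
        Lat &La = lats[l];
        const int L = Lcat[La.cat];
        const IntegerVector &sp = site_sp[La.cat];
        const NumericVector &wb = site_w[La.cat];
        const int nr = (int)La.pos.size();
        for (int j = 0; j < nr; ++j) {
          int i = La.pos[j];
          if (i == L) continue;
          bool blocked = (j + 1 < nr) && (La.pos[j + 1] - i <= W);
          if (blocked) continue;
          double rate = lambda * wb[i - 1] * Tc[sp[i - 1]];
          if (rate <= 0) continue;
          fl = l; fj = j;  // fallback: last eligible, guards float round-off
          r -= rate;
          if (r <= 0) { pl = l; pj = j; found = true; break; }
        }
      }
      if (!found) { pl = fl; pj = fj; }
      if (pl >= 0) {
        Lat &La = lats[pl];
        int i = La.pos[pj];
        int s = site_sp[La.cat][i - 1];
        La.pos[pj] = i + 1;
        --Tc[s]; ++Tu[s];
        if (post) { ++hops; if (batch >= 0) hops_b[batch] += 1; }
      }
    } else if ((r -= a_el) < a_term) {
      // termination: uniform among ribosomes sitting on a stop codon
      int k = std::min((int)(r / beta), n_stop - 1), seen = 0;
      for (int l = 0; l < n_lat; ++l) {
        Lat &La = lats[l];
        if (!La.pos.empty() && La.pos.back() == Lcat[La.cat]) {
          if (seen++ == k) {
            La.pos.pop_back();
            ++R_free; --n_bound;
            if (post) {
              ++terms; term_cat[La.cat] += 1;
              if (batch >= 0) term_b[batch] += 1;
            }
            break;
          }
        }
      }
    } else if ((r -= a_term) < a_drop) {
      // drop-off: uniform among ribosomes not at a stop codon
      int k = std::min((int)(r / gamma), n_bound - n_stop - 1), seen = 0;
      bool done = false;
      for (int l = 0; l < n_lat && !done; ++l) {
        Lat &La = lats[l];
        const int L = Lcat[La.cat];
        for (size_t j = 0; j < La.pos.size(); ++j) {
          if (La.pos[j] == L) continue;
          if (seen++ == k) {
            La.pos.erase(La.pos.begin() + j);
            ++R_free; --n_bound;
            if (post) ++drops;
            done = true;
            break;
          }
        }
      }
    } else {
      // recharging: one uncharged tRNA of the chosen species is aminoacylated
      r -= a_drop;
      int pick = n_sp - 1;
      for (int s = 0; s < n_sp; ++s) {
        r -= chi[s];
        if (r <= 0) { pick = s; break; }
      }
      ++Tc[pick]; --Tu[pick];
      if (post) ++rechs;
    }

    if (++total_events >= max_events) { truncated = true; break; }
  }

  // ---- pack results ----------------------------------------------------
  List final_pos(n_lat);
  IntegerVector final_cat(n_lat);
  for (int l = 0; l < n_lat; ++l) {
    final_pos[l] = IntegerVector(lats[l].pos.begin(), lats[l].pos.end());
    final_cat[l] = lats[l].cat + 1;
  }
  List density = R_NilValue;
  if (record_density) {
    List dl(n_cat);
    for (int c = 0; c < n_cat; ++c) {
      NumericVector v(Lcat[c]);
      for (int i = 0; i < Lcat[c]; ++i)
        v[i] = t_acc > 0 ? dens[dens_off[c] + i] / (t_acc * copies[c]) : 0.0;
      dl[c] = v;
    }
    density = dl;
  }
  NumericVector Qi(n_sp);
  for (int s = 0; s < n_sp; ++s) Qi[s] = t_acc > 0 ? int_Qi[s] / t_acc : NA_REAL;

  return List::create(
      _["t_record"] = t_acc, _["t_final"] = t, _["events"] = total_events,
      _["truncated"] = truncated,
      _["hops"] = hops, _["inits"] = inits, _["terms"] = terms,
      _["drops"] = drops, _["rechs"] = rechs,
      _["term_cat"] = term_cat,
      _["int_nbound"] = int_nbound, _["int_Q"] = int_Q,
      _["int_alpha"] = int_alpha, _["int_Rfree"] = int_Rfree,
      _["Qi"] = Qi, _["density"] = density,
      _["hops_batch"] = hops_b, _["nbound_batch"] = nbound_b,
      _["term_batch"] = term_b, _["batch_len"] = batch_len,
      _["R_free"] = R_free, _["n_bound"] = n_bound,
      _["Tc"] = IntegerVector(Tc.begin(), Tc.end()),
      _["final_positions"] = final_pos, _["final_category"] = final_cat);
}
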