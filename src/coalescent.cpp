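#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Discrete-event continuous-time coalescent over a set of populations with
// piecewise-constant diploid effective sizes, arbitrary origin (split) and
// admixture events, followed by generalized-stepwise mutations dropped on
// branches. Time is measured in generations before present; one locus is
// one independent genealogy. Uses R's RNG so results are reproducible under
// set.seed().

static inline int reflect_state(int s, int R) {
  while (s < 0 || s > R - 1) {
    if (s < 0) s = -s;
    if (s > R - 1) s = 2 * (R - 1) - s;
  }
  return s;
}

// events: columns time, type (0 origin, 1 admix, 2 ne_change), pop, src1,
// src2, rate, ne -- rows sorted by increasing time; pop indices 0-based.
// [[Rcpp::export]]
List sim_coalescent_cpp(IntegerVector samp, NumericVector ne0,
                        NumericMatrix events, NumericVector mu,
                        double p_geom, int allele_range) {
  const int P = samp.size();
  const int n_loci = mu.size();
  int L = 0;                       // total sampled gene copies
  for (int p = 0; p < P; ++p) L += 2 * samp[p];
  const int n_ind = L / 2;
  const int n_nodes = 2 * L - 1;
  const int n_ev = events.nrow();

  IntegerMatrix s1(n_ind, n_loci), s2(n_ind, n_loci);

  std::vector<double> node_time(n_nodes);
  std::vector<int> parent(n_nodes);
  std::vector<int> state(n_nodes);
  std::vector< std::vector<int> > active(P);
  std::vector<double> curNe(P);

  for (int locus = 0; locus < n_loci; ++locus) {
    // initialise sample lineages
    for (int p = 0; p < P; ++p) { active[p].clear(); curNe[p] = ne0[p]; }
    int id = 0;
    for (int p = 0; p < P; ++p)
      for (int c = 0; c < 2 * samp[p]; ++c) {
        node_time[id] = 0.0; parent[id] = -1;
        active[p].push_back(id); ++id;
      }
    int n_active = L;
    double t = 0.0;
    int ev = 0;
    while (n_active > 1) {
      double era_end = (ev < n_ev) ? events(ev, 0) : R_PosInf;
      // coalesce within the era
      while (true) {
        double total = 0.0;
        for (int p = 0; p < P; ++p) {
          double k = (double)active[p].size();
          if (k >= 2.0) total += k * (k - 1.0) / (4.0 * curNe[p]);
        }
        if (total <= 0.0) { t = era_end; break; }
        double wait = R::rexp(1.0 / total);
        if (t + wait >= era_end) { t = era_end; break; }
        t += wait;
        // choose population proportionally to its rate
        double u = R::runif(0.0, total), acc = 0.0;
        int pc = -1;
        for (int p = 0; p < P; ++p) {
          double k = (double)active[p].size();
          if (k >= 2.0) {
            acc += k * (k - 1.0) / (4.0 * curNe[p]);
            if (u <= acc) { pc = p; break; }
          }
        }
        if (pc < 0) pc = P - 1;
        // coalesce a random pair in pc
        std::vector<int> &v = active[pc];
        int k = (int)v.size();
        int i = (int)(R::unif_rand() * k); if (i >= k) i = k - 1;
        int j = (int)(R::unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
        if (j >= i) ++j;
        int a = v[i], b = v[j];
        node_time[id] = t; parent[id] = -1;
        parent[a] = id; parent[b] = id;
        if (i > j) std::swap(i, j);
        v[j] = v.back(); v.pop_back();
        v[i] = id;
        ++id; --n_active;
        if (n_active == 1) break;
      }
      if (n_active == 1) break;
      if (ev >= n_ev) {
        stop("lineages cannot coalesce: no common root reachable");
      }
      // apply all events scheduled at this time
      while (ev < n_ev && events(ev, 0) <= t + 1e-12) {
        int type = (int)events(ev, 1);
        int pop = (int)events(ev, 2);
        if (type == 0) {                       // origin: pop -> src1
          int s = (int)events(ev, 3);
          for (size_t q = 0; q < active[pop].size(); ++q)
            active[s].push_back(active[pop][q]);
          active[pop].clear();
        } else if (type == 1) {                // admixture
          int sA = (int)events(ev, 3), sB = (int)events(ev, 4);
          double r = events(ev, 5);
          for (size_t q = 0; q < active[pop].size(); ++q) {
            if (R::unif_rand() < r) active[sA].push_back(active[pop][q]);
            else active[sB].push_back(active[pop][q]);
          }
          active[pop].clear();
        } else {                               // ne_change
          curNe[pop] = events(ev, 6);
        }
        ++ev;
      }
    }
    int root = id - 1;
    // drop GSM mutations from the root towards the tips
    state[root] = allele_range / 2;
    for (int v2 = root - 1; v2 >= 0; --v2) {
      double len = node_time[parent[v2]] - node_time[v2];
      int s = state[parent[v2]];
      int nm = (int)R::rpois(mu[locus] * len);
      for (int m = 0; m < nm; ++m) {
        int step = 1;
        if (p_geom > 0.0) step = 1 + (int)R::rgeom(1.0 - p_geom);
        if (R::unif_rand() < 0.5) step = -step;
        s = reflect_state(s + step, allele_range);
      }
      state[v2] = s;
    }
    for (int i = 0; i < n_ind; ++i) {
      s1(i, locus) = state[2 * i];
      s2(i, locus) = state[2 * i + 1];
    }
  }
  return List::create(_["s1"] = s1, _["s2"] = s2);
}
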