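#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// STRUCTURE-style admixture model with correlated allele frequencies:
// ancestral frequencies PA_l ~ Dirichlet(lambda), cluster frequencies
// P_kl ~ Dirichlet(PA_l (1-F_k)/F_k), per-copy cluster labels Z, individual
// admixture proportions Q_i ~ Dirichlet(alpha). F_k has a truncated
// N(0.01, 0.05^2) prior, alpha a U(0, alpha_max) prior; both move by
// Metropolis random walks. Missing allele copies are dropped from the
// likelihood. Uses R's RNG throughout.

static void rdirichlet(std::vector<double> &out, const std::vector<double> &par) {
  double s = 0.0;
  for (size_t i = 0; i < par.size(); ++i) {
    double g = R::rgamma(par[i] > 1e-8 ? par[i] : 1e-8, 1.0);
    if (g < 1e-300) g = 1e-300;
    out[i] = g; s += g;
  }
  for (size_t i = 0; i < par.size(); ++i) out[i] /= s;
}

static double ldirichlet(const std::vector<double> &x, const std::vector<double> &par) {
  double s = 0.0, sp = 0.0;
  for (size_t i = 0; i < x.size(); ++i) {
    sp += par[i];
    s += (par[i] - 1.0) * std::log(x[i] > 1e-300 ? x[i] : 1e-300) - R::lgammafn(par[i]);
  }
  return s + R::lgammafn(sp);
}

// x1, x2: n x L matrices of 0-based allele indices, -1 = missing
// [[Rcpp::export]]
List admixture_gibbs_cpp(IntegerMatrix x1, IntegerMatrix x2, IntegerVector nA,
                         int K, int iters, int burnin, double lambda,
                         double alpha_max, double alpha_step) {
  const int n = x1.nrow(), L = x1.ncol();
  const double f_prior_mean = 0.01, f_prior_sd = 0.05, f_step = 0.01;

  // state
  std::vector< std::vector< std::vector<double> > > P(K), PA1(1);
  std::vector< std::vector<double> > PA(L);
  for (int l = 0; l < L; ++l) {
    PA[l].assign(nA[l], 1.0 / nA[l]);
  }
  for (int k = 0; k < K; ++k) {
    P[k].resize(L);
    for (int l = 0; l < L; ++l) P[k][l].assign(nA[l], 1.0 / nA[l]);
  }
  NumericMatrix Q(n, K);
  std::fill(Q.begin(), Q.end(), 1.0 / K);
  std::vector<double> Fk(K, 0.01), alpha1(1, 1.0);
  double alpha = 1.0;
  IntegerMatrix Z1(n, L), Z2(n, L);

  NumericMatrix Qsum(n, K);
  std::vector< std::vector< std::vector<double> > > Psum(K);
  for (int k = 0; k < K; ++k) {
    Psum[k].resize(L);
    for (int l = 0; l < L; ++l) Psum[k][l].assign(nA[l], 0.0);
  }
  std::vector<double> logl_trace;
  logl_trace.reserve(iters);
  int kept = 0;

  std::vector<double> prob(K), tmp(64), par(64);
  std::vector< std::vector<int> > nik(n, std::vector<int>(K));
  // counts n_kla
  std::vector< std::vector< std::vector<int> > > nkla(K);
  for (int k = 0; k < K; ++k) {
    nkla[k].resize(L);
    for (int l = 0; l < L; ++l) nkla[k][l].assign(nA[l], 0);
  }

  for (int it = 0; it < iters; ++it) {
    // reset counts
    for (int i = 0; i < n; ++i) std::fill(nik[i].begin(), nik[i].end(), 0);
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l)
        std::fill(nkla[k][l].begin(), nkla[k][l].end(), 0);
    double logl = 0.0;
    // --- Z updates (and log-likelihood of the mixture) ---
    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        for (int c = 0; c < 2; ++c) {
          int a = (c == 0) ? x1(i, l) : x2(i, l);
          if (a < 0) continue;
          double tot = 0.0;
          for (int k = 0; k < K; ++k) {
            prob[k] = Q(i, k) * P[k][l][a];
            tot += prob[k];
          }
          logl += std::log(tot > 1e-300 ? tot : 1e-300);
          double u = R::unif_rand() * tot, acc = 0.0;
          int zk = K - 1;
          for (int k = 0; k < K; ++k) { acc += prob[k]; if (u <= acc) { zk = k; break; } }
          if (c == 0) Z1(i, l) = zk; else Z2(i, l) = zk;
          ++nik[i][zk];
          ++nkla[zk][l][a];
        }
      }
    }
    // --- Q updates ---
    for (int i = 0; i < n; ++i) {
      par.assign(K, 0.0); tmp.assign(K, 0.0);
      for (int k = 0; k < K; ++k) par[k] = alpha + nik[i][k];
      rdirichlet(tmp, par);
      for (int k = 0; k < K; ++k) Q(i, k) = tmp[k];
    }
    // --- P updates ---
    for (int k = 0; k < K; ++k) {
      double fr = (1.0 - Fk[k]) / Fk[k];
      for (int l = 0; l < L; ++l) {
        int A = nA[l];
        par.assign(A, 0.0); tmp.assign(A, 0.0);
        for (int a = 0; a < A; ++a) par[a] = PA[l][a] * fr + nkla[k][l][a];
        rdirichlet(tmp, par);
        P[k][l] = std::vector<double>(tmp.begin(), tmp.begin() + A);
      }
    }
    // --- PA updates: pairwise mass-shift Metropolis per locus ---
    for (int l = 0; l < L; ++l) {
      int A = nA[l];
      if (A < 2) continue;
      int a = (int)(R::unif_rand() * A); if (a >= A) a = A - 1;
      int b = (int)(R::unif_rand() * (A - 1)); if (b >= A - 1) b = A - 2;
      if (b >= a) ++b;
      double d = R::unif_rand() * 0.1 - 0.05;
      double na_ = PA[l][a] + d, nb_ = PA[l][b] - d;
      if (na_ <= 1e-6 || nb_ <= 1e-6) continue;
      double lr = (lambda - 1.0) * (std::log(na_ / PA[l][a]) + std::log(nb_ / PA[l][b]));
      for (int k = 0; k < K; ++k) {
        double fr = (1.0 - Fk[k]) / Fk[k];
        // Dirichlet(P_kl ; PA*fr) ratio for components a and b
        lr += (na_ * fr - 1.0) * std::log(P[k][l][a] > 1e-300 ? P[k][l][a] : 1e-300)
            - (PA[l][a] * fr - 1.0) * std::log(P[k][l][a] > 1e-300 ? P[k][l][a] : 1e-300);
        lr += (nb_ * fr - 1.0) * std::log(P[k][l][b] > 1e-300 ? P[k][l][b] : 1e-300)
            - (PA[l][b] * fr - 1.0) * std::log(P[k][l][b] > 1e-300 ? P[k][l][b] : 1e-300);
        lr -= R::lgammafn(na_ * fr) - R::lgammafn(PA[l][a] * fr);
        lr -= R::lgammafn(nb_ * fr) - R::lgammafn(PA[l][b] * fr);
      }
      if (std::log(R::unif_rand()) < lr) { PA[l][a] = na_; PA[l][b] = nb_; }
    }
    // --- F updates ---
    for (int k = 0; k < K; ++k) {
      double fn = Fk[k] + R::norm_rand() * f_step;
      if (fn <= 1e-4 || fn >= 0.999) continue;
      double lr = (R::dnorm4(fn, f_prior_mean, f_prior_sd, 1) -
                   R::dnorm4(Fk[k], f_prior_mean, f_prior_sd, 1));
      double fro = (1.0 - Fk[k]) / Fk[k], frn = (1.0 - fn) / fn;
      for (int l = 0; l < L; ++l) {
        int A = nA[l];
        std::vector<double> po(A), pn(A);
        for (int a = 0; a < A; ++a) { po[a] = PA[l][a] * fro; pn[a] = PA[l][a] * frn; }
        lr += ldirichlet(P[k][l], pn) - ldirichlet(P[k][l], po);
      }
      if (std::log(R::unif_rand()) < lr) Fk[k] = fn;
    }
    // --- alpha update ---
    {
      double an = alpha + R::norm_rand() * alpha_step;
      if (an > 1e-4 && an < alpha_max) {
        double lr = 0.0;
        for (int i = 0; i < n; ++i) {
          double s = 0.0;
          for (int k = 0; k < K; ++k)
            s += std::log(Q(i, k) > 1e-300 ? Q(i, k) : 1e-300);
          lr += (an - alpha) * s;
        }
        lr += n * (R::lgammafn(K * an) - K * R::lgammafn(an)
                 - R::lgammafn(K * alpha) + K * R::lgammafn(alpha));
        if (std::log(R::unif_rand()) < lr) alpha = an;
      }
    }
    // --- accumulate ---
    if (it >= burnin) {
      ++kept;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) Qsum(i, k) += Q(i, k);
      for (int k = 0; k < K; ++k)
        for (int l = 0; l < L; ++l)
          for (int a = 0; a < nA[l]; ++a) Psum[k][l][a] += P[k][l][a];
      logl_trace.push_back(logl);
    }
  }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Qsum(i, k) /= kept;
  List Pout(K);
  for (int k = 0; k < K; ++k) {
    List Pk(L);
    for (int l = 0; l < L; ++l) {
      NumericVector v(nA[l]);
      for (int a = 0; a < nA[l]; ++a) v[a] = Psum[k][l][a] / kept;
      Pk[l] = v;
    }
    Pout[k] = Pk;
  }
  return List::create(_["Q"] = Qsum, _["P"] = Pout,
                      _["logl"] = wrap(logl_trace),
                      _["alpha"] = alpha, _["F"] = wrap(Fk));
}
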