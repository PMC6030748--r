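#include <Rcpp.h>
using namespace Rcpp;

// mean proportion of shared alleles between individuals of different
// groups: for each group pair, average over all cross-group individual
// pairs of the per-pair mean (over loci with both genotypes present) of
// 0.5 * |multiset intersection of the two genotypes|.
// a1, a2: allele matrices (NA = missing), grp: 0-based group index.
// [[Rcpp::export]]
NumericMatrix shared_allele_ps_cpp(IntegerMatrix a1, IntegerMatrix a2,
                                   IntegerVector grp, int G) {
  const int n = a1.nrow(), L = a1.ncol();
  NumericMatrix out(G, G);
  for (int g1 = 0; g1 < G - 1; ++g1) {
    for (int g2 = g1 + 1; g2 < G; ++g2) {
      double tot = 0.0; long npair = 0;
      for (int i = 0; i < n; ++i) {
        if (grp[i] != g1) continue;
        for (int j = 0; j < n; ++j) {
          if (grp[j] != g2) continue;
          double s = 0.0; int nl = 0;
          for (int l = 0; l < L; ++l) {
            int ia = a1(i, l), ib = a2(i, l);
            int jc = a1(j, l), jd = a2(j, l);
            if (ia == NA_INTEGER || jc == NA_INTEGER) continue;
            ++nl;
            int inter;
            if (ia == ib) {
              inter = (ia == jc) + (ia == jd);
              if (jc == jd) inter = (ia == jc) ? 2 : 0;
            } else if (jc == jd) {
              inter = (ia == jc) + (ib == jc);
            } else {
              // both het, all within-genotype alleles distinct
              inter = ((ia == jc) || (ia == jd)) + ((ib == jc) || (ib == jd));
            }
            s += 0.5 * inter;
          }
          if (nl > 0) { tot += s / nl; ++npair; }
        }
      }
      double v = npair > 0 ? tot / npair : NA_REAL;
      out(g1, g2) = v; out(g2, g1) = v;
    }
  }
  return out;
}
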