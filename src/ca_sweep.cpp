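#include <Rcpp.h>
using namespace Rcpp;

// One allocation sweep of the cellular automaton.
//
// Cells are visited in the supplied (pre-shuffled) order. A cell whose
// class currently exceeds its demand may convert, by roulette draw over
// the combined scores sp * omega * inertia, to a class that is still below
// its demand and that the conversion-cost matrix allows from the cell's
// class. Staying put competes with its own combined score and is always
// allowed. Counts are updated immediately, so no class ever overshoots its
// demand within a sweep and the total cell count is conserved exactly.
//
// Uses R's RNG stream (unif_rand) so results are reproducible under
// set.seed from the calling R code.
// [[Rcpp::export]]
List ca_sweep(IntegerVector cur, NumericMatrix sp, NumericMatrix omega,
              NumericVector inertia, IntegerMatrix cost,
              IntegerVector demand, IntegerVector counts,
              IntegerVector visit) {
  int K = sp.ncol();
  IntegerVector cls = clone(cur);
  IntegerVector cnt = clone(counts);
  std::vector<double> w(K);
  int changed = 0;
  for (int vi = 0; vi < visit.size(); ++vi) {
    int p = visit[vi] - 1;                 // 1-based cell index from R
    int c = cls[p];
    if (c == NA_INTEGER) continue;
    int ci = c - 1;
    if (cnt[ci] <= demand[ci]) continue;   // class at/below demand: locked
    double tot = 0.0;
    for (int k = 0; k < K; ++k) {
      double wk = 0.0;
      if (k != ci && cost(ci, k) == 1 && cnt[k] < demand[k])
        wk = sp(p, k) * omega(p, k) * inertia[k];
      w[k] = wk;
      tot += wk;
    }
    double stay = sp(p, ci) * omega(p, ci) * inertia[ci];
    tot += stay;
    if (tot <= 0.0) continue;              // all-zero scores: keep class
    double u = unif_rand() * tot;
    double acc = stay;
    if (u < acc) continue;                 // roulette chose to stay
    int k = 0;
    for (; k < K; ++k) { acc += w[k]; if (u < acc) break; }
    if (k >= K) continue;                  // numerical tail guard
    cls[p] = k + 1;
    cnt[ci] -= 1;
    cnt[k] += 1;
    ++changed;
  }
  return List::create(_["classes"] = cls, _["counts"] = cnt,
                      _["changed"] = changed);
}
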