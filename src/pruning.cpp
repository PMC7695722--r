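#include <Rcpp.h>
using namespace Rcpp;

// Scaled Felsenstein pruning over compressed site patterns.
//
// parent: 1-based parent id per node (0 at the root); tips are nodes
//   1..ntip. ages: node ages (ka BP). brates: per-branch rate multiplier
//   indexed by child node (root entry ignored). The expected-substitution
//   length of the branch above node i is
//   (ages[parent[i]] - ages[i]) * brates[i] * clock_rate * cat_rate.
// tipp: nstate x (npattern * ntip) tip partials, tip-major
//   (columns [p + npattern*(tip-1)]).
// V, d, Vinv: eigensystem of the generator, P(t) = V diag(exp(d t)) Vinv.
// rootfreq: stationary distribution weighting the root states.
// Returns npattern per-pattern log-likelihoods.
// [[Rcpp::export]]
NumericVector prune_loglik_cpp(IntegerVector parent, int root,
                               NumericVector ages, NumericVector brates,
                               double clock_rate, double cat_rate, int ntip,
                               NumericMatrix tipp,
                               NumericMatrix V, NumericVector d,
                               NumericMatrix Vinv, NumericVector rootfreq) {
  const int ns = V.nrow();
  const int ntot = parent.size();
  const int np = tipp.ncol() / ntip;

  // postorder over nodes (children before parents) via DFS from the root
  std::vector<int> kid0(ntot, -1), kid1(ntot, -1);
  for (int i = 0; i < ntot; ++i) {
    int pa = parent[i] - 1;
    if (pa < 0) continue;
    if (kid0[pa] < 0) kid0[pa] = i; else kid1[pa] = i;
  }
  std::vector<int> order; order.reserve(ntot);
  std::vector<int> stack; stack.reserve(ntot);
  stack.push_back(root - 1);
  while (!stack.empty()) {
    int nd = stack.back(); stack.pop_back();
    order.push_back(nd);
    if (kid0[nd] >= 0) { stack.push_back(kid0[nd]); stack.push_back(kid1[nd]); }
  }

  std::vector<double> part((size_t)ns * np * ntot);
  std::vector<double> scal(np, 0.0);
  const double *tp = REAL(tipp);
  for (int t = 0; t < ntip; ++t) {
    std::copy(tp + (size_t)ns * np * t, tp + (size_t)ns * np * (t + 1),
              part.begin() + (size_t)ns * np * t);
  }
  for (int nd = ntip; nd < ntot; ++nd) {
    std::fill(part.begin() + (size_t)ns * np * nd,
              part.begin() + (size_t)ns * np * (nd + 1), 1.0);
  }

  const double *Vp = REAL(V), *Vip = REAL(Vinv), *dp = REAL(d);
  std::vector<double> P(ns * ns), ed(ns), tmp(ns);
  bool impossible = false;
  // process edges child-to-parent in reverse DFS order
  for (int k = (int)order.size() - 1; k >= 0; --k) {
    const int ch = order[k];
    const int pa = parent[ch] - 1;
    if (pa < 0) continue;
    const double t = (ages[pa] - ages[ch]) * brates[ch] * clock_rate * cat_rate;
    for (int s = 0; s < ns; ++s) ed[s] = std::exp(dp[s] * t);
    // P = V diag(ed) Vinv (matrices column-major); row-major P[i*ns+j]
    for (int i = 0; i < ns; ++i)
      for (int j = 0; j < ns; ++j) {
        double acc = 0.0;
        for (int s = 0; s < ns; ++s)
          acc += Vp[i + ns * s] * ed[s] * Vip[s + ns * j];
        P[i * ns + j] = acc > 0.0 ? acc : 0.0;
      }
    const double *pc = &part[(size_t)ns * np * ch];
    double *pp = &part[(size_t)ns * np * pa];
    for (int p = 0; p < np; ++p) {
      const double *c = pc + (size_t)ns * p;
      double *q = pp + (size_t)ns * p;
      double mx = 0.0;
      for (int i = 0; i < ns; ++i) {
        double acc = 0.0;
        const double *Pi = &P[i * ns];
        for (int j = 0; j < ns; ++j) acc += Pi[j] * c[j];
        tmp[i] = acc;
        if (acc > mx) mx = acc;
      }
      if (mx <= 0.0) {
        impossible = true;
        for (int i = 0; i < ns; ++i) q[i] = 0.0;
        scal[p] = R_NegInf;
        continue;
      }
      double qmx = 0.0;
      for (int i = 0; i < ns; ++i) {
        q[i] *= tmp[i];
        if (q[i] > qmx) qmx = q[i];
      }
      if (qmx < 1e-120 && qmx > 0.0) {
        // rescale only when underflow threatens; keeps log() calls rare
        for (int i = 0; i < ns; ++i) q[i] /= qmx;
        scal[p] += std::log(qmx);
      }
    }
  }

  NumericVector out(np);
  const double *pr = &part[(size_t)ns * np * (root - 1)];
  const double *rf = REAL(rootfreq);
  for (int p = 0; p < np; ++p) {
    double acc = 0.0;
    for (int s = 0; s < ns; ++s) acc += rf[s] * pr[(size_t)ns * p + s];
    out[p] = (acc > 0.0 && R_finite(scal[p])) ? std::log(acc) + scal[p]
                                              : R_NegInf;
  }
  (void)impossible;
  return out;
}
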