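#include <Rcpp.h>
using namespace Rcpp;

// Window log-affinity scores of one motif (given as a 4 x L matrix of
// log(f/fmax)) over an integer-encoded read matrix (A=1..T=4).
// Fills a pre-allocated n x nw block; helper for the single entry
// point below.
static void window_scores(const IntegerMatrix &m, const NumericMatrix &lw,
                          NumericMatrix &out) {
  const int n = m.nrow();
  const int L = lw.ncol();
  const int nw = m.ncol() - L + 1;
  // column-major friendly: accumulate one motif column at a time
  for (int w = 0; w < nw; ++w) {
    double *o = &out(0, w);
    for (int j = 0; j < L; ++j) {
      const int *mc = &m(0, w + j);
      const double *lj = &lw(0, j);
      if (j == 0)
        for (int i = 0; i < n; ++i) o[i] = lj[mc[i] - 1];
      else
        for (int i = 0; i < n; ++i) o[i] += lj[mc[i] - 1];
    }
  }
}

// Per-read affinity components of a selection model.
//
// lwAf/lwAr: log(f/fmax) matrices of motif A, forward and reverse
// complement; lwBf/lwBr likewise for motif B (0 x 0 matrices when there
// is no second motif). gap/orientation define the planted paired
// arrangement ("orient" encodes strands: 0=ff, 1=fr, 2=rf, 3=rr).
// Returns a list with max single-site log scores for A and B and the
// best paired-configuration log score (both the arrangement and its
// reverse complement are scanned); -Inf where not applicable.
// [[Rcpp::export(name = ".cpp_affinity_components")]]
List cpp_affinity_components(IntegerMatrix m, NumericMatrix lwAf,
                             NumericMatrix lwAr, NumericMatrix lwBf,
                             NumericMatrix lwBr, int gap, int orient) {
  const int n = m.nrow();
  const bool hasB = lwBf.ncol() > 0;
  NumericMatrix wAf(n, m.ncol() - lwAf.ncol() + 1);
  NumericMatrix wAr(n, wAf.ncol());
  window_scores(m, lwAf, wAf);
  window_scores(m, lwAr, wAr);
  NumericVector bestA(n, R_NegInf), bestB(n, R_NegInf), bestP(n, R_NegInf);
  for (int w = 0; w < wAf.ncol(); ++w) {
    const double *f = &wAf(0, w), *r = &wAr(0, w);
    for (int i = 0; i < n; ++i) {
      double v = std::max(f[i], r[i]);
      if (v > bestA[i]) bestA[i] = v;
    }
  }
  if (hasB) {
    NumericMatrix wBf(n, m.ncol() - lwBf.ncol() + 1);
    NumericMatrix wBr(n, wBf.ncol());
    window_scores(m, lwBf, wBf);
    window_scores(m, lwBr, wBr);
    for (int w = 0; w < wBf.ncol(); ++w) {
      const double *f = &wBf(0, w), *r = &wBr(0, w);
      for (int i = 0; i < n; ++i) {
        double v = std::max(f[i], r[i]);
        if (v > bestB[i]) bestB[i] = v;
      }
    }
    const int LA = lwAf.ncol(), LB = lwBf.ncol();
    const bool aFwd = (orient == 0 || orient == 1);
    const bool bFwd = (orient == 0 || orient == 2);
    const NumericMatrix &pA = aFwd ? wAf : wAr;
    const NumericMatrix &pB = bFwd ? wBf : wBr;
    // opposite-strand reading of the arrangement: B' left, A' right
    const NumericMatrix &oB = bFwd ? wBr : wBf;
    const NumericMatrix &oA = aFwd ? wAr : wAf;
    const int shiftAB = LA + gap, shiftBA = LB + gap;
    for (int w = 0; w < pA.ncol() && w + shiftAB < pB.ncol(); ++w) {
      if (w + shiftAB < 0) continue;
      const double *x = &pA(0, w), *y = &pB(0, w + shiftAB);
      for (int i = 0; i < n; ++i) {
        double v = x[i] + y[i];
        if (v > bestP[i]) bestP[i] = v;
      }
    }
    for (int w = 0; w < oB.ncol() && w + shiftBA < oA.ncol(); ++w) {
      if (w + shiftBA < 0) continue;
      const double *x = &oB(0, w), *y = &oA(0, w + shiftBA);
      for (int i = 0; i < n; ++i) {
        double v = x[i] + y[i];
        if (v > bestP[i]) bestP[i] = v;
      }
    }
  }
  return List::create(_["logA"] = bestA, _["logB"] = bestB,
                      _["logPaired"] = bestP);
}

// Integer 4-mer (or k-mer) codes of every window; shared scanning
// primitive used by the k-mer counting layer.
// [[Rcpp::export(name = ".cpp_kmer_codes")]]
IntegerMatrix cpp_kmer_codes(IntegerMatrix m, int k) {
  const int n = m.nrow();
  const int nw = m.ncol() - k + 1;
  IntegerMatrix out(n, nw);
  for (int i = 0; i < n; ++i) {
    int code = 0;
    const int mask = (int)std::pow(4.0, k - 1);
    for (int j = 0; j < k; ++j) code = code * 4 + (m(i, j) - 1);
    out(i, 0) = code + 1;
    for (int w = 1; w < nw; ++w) {
      code = (code % (mask)) * 4 + (m(i, w + k - 1) - 1);
      out(i, w) = code + 1;
    }
  }
  return out;
}
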