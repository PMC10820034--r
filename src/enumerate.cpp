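#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Bounded depth-first enumeration of element-count vectors whose summed
// monoisotopic mass falls inside [lo, hi]. Elements are expected in
// descending-mass order so that the per-level feasible-count window
// (computed from suffix min/max achievable masses) prunes aggressively.
// 'cap' bounds the number of count assignments visited; exceeding it is a
// resource error and the caller should tighten constraints.

namespace {

struct Enum {
  const NumericVector &masses;
  const IntegerVector &cmin, &cmax;
  double lo, hi, cap, visited = 0.0;
  int ne;
  std::vector<double> sufMin, sufMax;
  std::vector<int> cur;
  std::vector<std::vector<int>> out;

  Enum(const NumericVector &m, const IntegerVector &lo_, const IntegerVector &hi_,
       double l, double h, double c)
      : masses(m), cmin(lo_), cmax(hi_), lo(l), hi(h), cap(c), ne(m.size()),
        sufMin(ne + 1, 0.0), sufMax(ne + 1, 0.0), cur(ne, 0) {
    for (int i = ne - 1; i >= 0; --i) {
      sufMin[i] = sufMin[i + 1] + masses[i] * cmin[i];
      sufMax[i] = sufMax[i + 1] + masses[i] * cmax[i];
    }
  }

  void rec(int depth, double mass) {
    if (depth == ne) {
      if (mass >= lo && mass <= hi) out.push_back(cur);
      return;
    }
    const double m = masses[depth];
    int cLo = cmin[depth], cHi = cmax[depth];
    if (m > 0) {
      // counts outside this window cannot reach [lo, hi] with any suffix
      int l = (int)std::ceil((lo - mass - sufMax[depth + 1]) / m - 1e-12);
      int h = (int)std::floor((hi - mass - sufMin[depth + 1]) / m + 1e-12);
      if (l > cLo) cLo = l;
      if (h < cHi) cHi = h;
    }
    for (int c = cLo; c <= cHi; ++c) {
      visited += 1.0;
      if (visited > cap)
        stop("formula enumeration visit cap exceeded; tighten the element "
             "constraints or reduce the ppm tolerance");
      cur[depth] = c;
      rec(depth + 1, mass + m * c);
    }
    cur[depth] = 0;
  }
};

} // namespace

// [[Rcpp::export(name = ".enumerateCpp")]]
IntegerMatrix enumerateCpp(NumericVector masses, IntegerVector cmin,
                           IntegerVector cmax, double lo, double hi,
                           double cap) {
  const int ne = masses.size();
  if (ne == 0 || lo > hi) return IntegerMatrix(0, std::max(ne, 0));
  Enum e(masses, cmin, cmax, lo, hi, cap);
  e.rec(0, 0.0);
  IntegerMatrix res(e.out.size(), ne);
  for (size_t r = 0; r < e.out.size(); ++r)
    for (int c = 0; c < ne; ++c) res(r, c) = e.out[r][c];
  return res;
}
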