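// Gamma-index search kernel.
//
// Reference-point-driven: for every reference point above the dose cutoff,
// minimise sqrt((Ddiff/dd)^2 + (r/dta)^2) over evaluated-dose positions on a
// fine sub-grid (bilinear interpolation) within a fixed search radius.
// Offsets are visited in order of increasing distance so the search can stop
// as soon as the spatial term alone exceeds the current minimum.

#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

struct Offset {
  double dr, dc, dist2;  // mm, mm, mm^2
};

static inline double bilinear(const NumericMatrix& m, double r, double c) {
  const int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  const int r1 = std::min(r0 + 1, m.nrow() - 1);
  const int c1 = std::min(c0 + 1, m.ncol() - 1);
  const double fr = r - r0, fc = c - c0;
  return m(r0, c0) * (1 - fr) * (1 - fc) + m(r1, c0) * fr * (1 - fc) +
         m(r0, c1) * (1 - fr) * fc + m(r1, c1) * fr * fc;
}

// [[Rcpp::export(name = ".gammaMapC")]]
NumericMatrix gamma_map_c(NumericMatrix ref, NumericMatrix ev, double sr,
                          double sc, double ddAbs, double dta,
                          double cutoffAbs, double radiusMm, double stepMm) {
  const int H = ref.nrow(), W = ref.ncol();
  if (ev.nrow() != H || ev.ncol() != W) stop("grid shape mismatch");

  std::vector<Offset> offs;
  const int nStep = (int)std::floor(radiusMm / stepMm + 1e-9);
  offs.reserve((2 * nStep + 1) * (2 * nStep + 1));
  for (int a = -nStep; a <= nStep; ++a)
    for (int b = -nStep; b <= nStep; ++b) {
      const double dr = a * stepMm, dc = b * stepMm;
      const double d2 = dr * dr + dc * dc;
      if (d2 <= radiusMm * radiusMm + 1e-9) offs.push_back({dr, dc, d2});
    }
  std::sort(offs.begin(), offs.end(),
            [](const Offset& a, const Offset& b) { return a.dist2 < b.dist2; });

  const double dta2 = dta * dta, dd2 = ddAbs * ddAbs;
  NumericMatrix g(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      const double dref = ref(r, c);
      if (dref < cutoffAbs) { g(r, c) = NA_REAL; continue; }
      double best = R_PosInf;
      for (const Offset& o : offs) {
        const double spatial = o.dist2 / dta2;
        if (spatial >= best) break;  // sorted: nothing further can win
        const double rr = r + o.dr / sr, cc = c + o.dc / sc;
        if (rr < 0 || rr > H - 1 || cc < 0 || cc > W - 1) continue;
        const double dd = bilinear(ev, rr, cc) - dref;
        const double g2 = dd * dd / dd2 + spatial;
        if (g2 < best) best = g2;
      }
      g(r, c) = std::sqrt(best);
    }
  return g;
}
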