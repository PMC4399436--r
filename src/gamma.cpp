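// 3D gamma-index search. Both entry points minimize over a dense lattice of
// spatial offsets (sorted by distance, with the admissible early stop "the
// geometric term alone exceeds the current best"), so the shell search and
// the brute-force oracle differ only in lattice step.
#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Off {
  double x, y, z, r2norm;  // r2norm = (|r| / dist_crit)^2
};

inline double trilinear3(const double* v, int nx, int ny, int nz, double fx,
                         double fy, double fz, bool& ok) {
  if (fx < 0 || fy < 0 || fz < 0 || fx > nx - 1 || fy > ny - 1 || fz > nz - 1) {
    ok = false;
    return 0.0;
  }
  ok = true;
  int x0 = std::min((int)fx, nx - 2), y0 = std::min((int)fy, ny - 2),
      z0 = std::min((int)fz, nz - 2);
  if (nx == 1) x0 = 0;
  if (ny == 1) y0 = 0;
  if (nz == 1) z0 = 0;
  double wx = fx - x0, wy = fy - y0, wz = fz - z0;
  auto at = [&](int i, int j, int k) {
    return v[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
  };
  double c00 = at(x0, y0, z0) * (1 - wx) + at(x0 + 1, y0, z0) * wx;
  double c10 = at(x0, y0 + 1, z0) * (1 - wx) + at(x0 + 1, y0 + 1, z0) * wx;
  double c01 = at(x0, y0, z0 + 1) * (1 - wx) + at(x0 + 1, y0, z0 + 1) * wx;
  double c11 = at(x0, y0 + 1, z0 + 1) * (1 - wx) + at(x0 + 1, y0 + 1, z0 + 1) * wx;
  double c0 = c00 * (1 - wy) + c10 * wy;
  double c1 = c01 * (1 - wy) + c11 * wy;
  return c0 * (1 - wz) + c1 * wz;
}

} // namespace

// [[Rcpp::export(name = ".gamma_search_cpp")]]
NumericVector gamma_search_cpp(NumericVector ref, NumericVector eval,
                               NumericVector spacing_mm, double dose_crit,
                               double dist_crit_mm, double threshold,
                               double cap, double step_mm, double refine_mm) {
  IntegerVector d = ref.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  const double* rv = REAL(ref);
  const double* ev = REAL(eval);
  NumericVector out(ref.size());
  out.attr("dim") = ref.attr("dim");
  double radius = cap * dist_crit_mm;
  int nmax = (int)std::floor(radius / step_mm);
  std::vector<Off> offs;
  offs.reserve((2 * nmax + 1) * (2 * nmax + 1) * (2 * nmax + 1) / 2);
  for (int iz = -nmax; iz <= nmax; ++iz)
    for (int iy = -nmax; iy <= nmax; ++iy)
      for (int ix = -nmax; ix <= nmax; ++ix) {
        double x = ix * step_mm, y = iy * step_mm, z = iz * step_mm;
        double r2 = x * x + y * y + z * z;
        if (r2 > radius * radius + 1e-12) continue;
        offs.push_back({x, y, z, r2 / (dist_crit_mm * dist_crit_mm)});
      }
  std::sort(offs.begin(), offs.end(),
            [](const Off& a, const Off& b) { return a.r2norm < b.r2norm; });
  double cap2 = cap * cap;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t lin = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        double Dref = rv[lin];
        if (Dref <= threshold) {
          out[lin] = NA_REAL;
          continue;
        }
        double best = cap2;
        double bx = 0, by = 0, bz = 0;
        for (const Off& o : offs) {
          if (o.r2norm >= best) break;
          bool ok;
          double val = trilinear3(ev, nx, ny, nz, i + o.x / spacing_mm[0],
                                  j + o.y / spacing_mm[1],
                                  k + o.z / spacing_mm[2], ok);
          if (!ok) continue;
          double dd = (val - Dref) / dose_crit;
          double term = o.r2norm + dd * dd;
          if (term < best) {
            best = term;
            bx = o.x; by = o.y; bz = o.z;
          }
        }
        if (refine_mm > 0) {
          // local sub-lattice refinement around the best coarse offset
          int nref = (int)std::floor(step_mm / refine_mm);
          for (int rz = -nref; rz <= nref; ++rz)
            for (int ry = -nref; ry <= nref; ++ry)
              for (int rx = -nref; rx <= nref; ++rx) {
                double x = bx + rx * refine_mm, y = by + ry * refine_mm,
                       z = bz + rz * refine_mm;
                double r2n = (x * x + y * y + z * z) /
                             (dist_crit_mm * dist_crit_mm);
                if (r2n >= best) continue;
                bool ok;
                double val = trilinear3(ev, nx, ny, nz,
                                        i + x / spacing_mm[0],
                                        j + y / spacing_mm[1],
                                        k + z / spacing_mm[2], ok);
                if (!ok) continue;
                double dd = (val - Dref) / dose_crit;
                double term = r2n + dd * dd;
                if (term < best) best = term;
              }
        }
        out[lin] = std::sqrt(best);
      }
  return out;
}
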