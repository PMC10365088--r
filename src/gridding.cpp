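#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Kaiser-Bessel interpolation kernel, tabulated once per call with linear
// interpolation (table resolution keeps the lookup error well below the
// aliasing error of the gridding approximation itself).
struct KBTable {
  std::vector<double> tab;
  double half_width, scale;
  int n;
  KBTable(double W, double beta, int n_ = 65536) : n(n_) {
    tab.resize(n + 2);
    const double i0 = R::bessel_i(beta, 0.0, 1.0);
    half_width = W / 2.0;
    scale = (n - 1) / half_width;
    for (int i = 0; i < n; ++i) {
      double t = i / scale;
      double a = 1.0 - (t / half_width) * (t / half_width);
      tab[i] = a <= 0.0 ? 0.0 : R::bessel_i(beta * std::sqrt(a), 0.0, 1.0) / i0;
    }
    tab[n] = 0.0;
    tab[n + 1] = 0.0;
  }
  inline double operator()(double t) const {
    double a = std::fabs(t);
    if (a >= half_width) return 0.0;
    double x = a * scale;
    int i = static_cast<int>(x);
    double f = x - i;
    return tab[i] * (1.0 - f) + tab[i + 1] * f;
  }
};

static inline int wrap_idx(int g, int G) {
  int r = g % G;
  return r < 0 ? r + G : r;
}

// Evaluate the periodic Cartesian k-space grid at non-integer frequencies u
// (grid units). grid is a G1 x G2 x G3 complex array stored column-major with
// index g equal to frequency g modulo G (i.e. raw fft ordering).
// [[Rcpp::export]]
ComplexVector cpp_kb_interp(const ComplexVector& grid, const IntegerVector& gdim,
                            const NumericMatrix& u, double width, double beta) {
  const int G1 = gdim[0], G2 = gdim[1], G3 = gdim[2];
  const int ns = u.nrow();
  KBTable kb(width, beta);
  ComplexVector out(ns);
  const Rcomplex* g = grid.begin();
  const double hw = width / 2.0;
  double wx[24], wy[24], wz[24];
  int ix[24], iy[24], iz[24];

  for (int s = 0; s < ns; ++s) {
    const double ux = u(s, 0), uy = u(s, 1), uz = u(s, 2);
    int nx = 0, ny = 0, nz = 0;
    for (int j = (int)std::ceil(ux - hw); j <= (int)std::floor(ux + hw); ++j) {
      wx[nx] = kb(ux - j); ix[nx] = wrap_idx(j, G1); ++nx;
    }
    for (int j = (int)std::ceil(uy - hw); j <= (int)std::floor(uy + hw); ++j) {
      wy[ny] = kb(uy - j); iy[ny] = wrap_idx(j, G2); ++ny;
    }
    for (int j = (int)std::ceil(uz - hw); j <= (int)std::floor(uz + hw); ++j) {
      wz[nz] = kb(uz - j); iz[nz] = wrap_idx(j, G3); ++nz;
    }
    double re = 0.0, im = 0.0;
    for (int c = 0; c < nz; ++c) {
      const double wc = wz[c];
      const int offc = iz[c] * G2;
      for (int b = 0; b < ny; ++b) {
        const double wbc = wy[b] * wc;
        const int offb = (offc + iy[b]) * G1;
        for (int a = 0; a < nx; ++a) {
          const Rcomplex v = g[offb + ix[a]];
          const double w = wx[a] * wbc;
          re += w * v.r;
          im += w * v.i;
        }
      }
    }
    out[s].r = re;
    out[s].i = im;
  }
  return out;
}

// Exact transpose of cpp_kb_interp: spread samples onto the periodic grid.
// [[Rcpp::export]]
ComplexVector cpp_kb_spread(const ComplexVector& samples, const NumericMatrix& u,
                            const IntegerVector& gdim, double width, double beta) {
  const int G1 = gdim[0], G2 = gdim[1], G3 = gdim[2];
  const int ns = u.nrow();
  KBTable kb(width, beta);
  ComplexVector out(G1 * G2 * G3);
  Rcomplex* g = out.begin();
  for (int i = 0; i < G1 * G2 * G3; ++i) { g[i].r = 0.0; g[i].i = 0.0; }
  const double hw = width / 2.0;
  double wx[24], wy[24], wz[24];
  int ix[24], iy[24], iz[24];

  for (int s = 0; s < ns; ++s) {
    const double ux = u(s, 0), uy = u(s, 1), uz = u(s, 2);
    int nx = 0, ny = 0, nz = 0;
    for (int j = (int)std::ceil(ux - hw); j <= (int)std::floor(ux + hw); ++j) {
      wx[nx] = kb(ux - j); ix[nx] = wrap_idx(j, G1); ++nx;
    }
    for (int j = (int)std::ceil(uy - hw); j <= (int)std::floor(uy + hw); ++j) {
      wy[ny] = kb(uy - j); iy[ny] = wrap_idx(j, G2); ++ny;
    }
    for (int j = (int)std::ceil(uz - hw); j <= (int)std::floor(uz + hw); ++j) {
      wz[nz] = kb(uz - j); iz[nz] = wrap_idx(j, G3); ++nz;
    }
    const double sr = samples[s].r, si = samples[s].i;
    for (int c = 0; c < nz; ++c) {
      const double wc = wz[c];
      const int offc = iz[c] * G2;
      for (int b = 0; b < ny; ++b) {
        const double wbc = wy[b] * wc;
        const int offb = (offc + iy[b]) * G1;
        for (int a = 0; a < nx; ++a) {
          const double w = wx[a] * wbc;
          g[offb + ix[a]].r += w * sr;
          g[offb + ix[a]].i += w * si;
        }
      }
    }
  }
  return out;
}

// 6-connected flood fill from a 1-based voxel seed within a logical mask.
// [[Rcpp::export]]
LogicalVector cpp_flood_fill(const LogicalVector& mask, const IntegerVector& dim,
                             const IntegerVector& seed) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  LogicalVector out(mask.size());
  std::fill(out.begin(), out.end(), FALSE);
  const int s1 = seed[0] - 1, s2 = seed[1] - 1, s3 = seed[2] - 1;
  auto at = [&](int i, int j, int k) { return i + n1 * (j + n2 * k); };
  if (s1 < 0 || s1 >= n1 || s2 < 0 || s2 >= n2 || s3 < 0 || s3 >= n3)
    stop("seed outside volume");
  if (!mask[at(s1, s2, s3)]) return out;
  std::vector<int> stack;
  stack.push_back(at(s1, s2, s3));
  out[at(s1, s2, s3)] = TRUE;
  while (!stack.empty()) {
    int idx = stack.back();
    stack.pop_back();
    int i = idx % n1, rest = idx / n1;
    int j = rest % n2, k = rest / n2;
    const int di[6] = {-1, 1, 0, 0, 0, 0};
    const int dj[6] = {0, 0, -1, 1, 0, 0};
    const int dk[6] = {0, 0, 0, 0, -1, 1};
    for (int q = 0; q < 6; ++q) {
      int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
      if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3) continue;
      int nidx = at(ii, jj, kk);
      if (mask[nidx] && !out[nidx]) {
        out[nidx] = TRUE;
        stack.push_back(nidx);
      }
    }
  }
  return out;
}
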