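// Low-level numerical kernels: 3^3 convolution (forward/backward), 2x pooling
// and up-sampling, trilinear sampling with analytic position gradients, exact
// Euclidean distance transform, and brute-force nearest-vertex distances.
// Feature maps are (Nvox x C) matrices; voxel p = x + nx*(y + ny*z), 0-based.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Shifted copy with zero fill: S(x,y,z) = X(x+ox, y+oy, z+oz) when in bounds.
static arma::mat shift3(const arma::mat& X, int nx, int ny, int nz,
                        int ox, int oy, int oz) {
  const int C = X.n_cols;
  arma::mat S(X.n_rows, C, arma::fill::zeros);
  const int x0 = std::max(0, -ox), x1 = std::min(nx, nx - ox);
  if (x1 <= x0) return S;
  const size_t len = (size_t)(x1 - x0);
  for (int c = 0; c < C; ++c) {
    const double* src = X.colptr(c);
    double* dst = S.colptr(c);
    for (int z = 0; z < nz; ++z) {
      const int zi = z + oz;
      if (zi < 0 || zi >= nz) continue;
      for (int y = 0; y < ny; ++y) {
        const int yi = y + oy;
        if (yi < 0 || yi >= ny) continue;
        std::memcpy(dst + x0 + (size_t)nx * (y + (size_t)ny * z),
                    src + (x0 + ox) + (size_t)nx * (yi + (size_t)ny * zi),
                    len * sizeof(double));
      }
    }
  }
  return S;
}

// Build the im2col block for output z-slices [z0, z1): rows are slab
// voxels (x fastest, then y, then z), column (t*Cin + c) holds channel c
// shifted by offset t (t = (ox+1)+3*((oy+1)+3*(oz+1))), zero-padded.
// Single precision: the conv compute path runs in float32 (standard for
// this kind of network; parameters and gradients stay double outside).
static void im2col_slab(const arma::fmat& X, int nx, int ny, int nz,
                        int z0, int z1, arma::fmat& Col) {
  const int Cin = X.n_cols;
  const size_t plane = (size_t)nx * ny;
  Col.zeros();
  int t = 0;
  for (int oz = -1; oz <= 1; ++oz)
    for (int oy = -1; oy <= 1; ++oy)
      for (int ox = -1; ox <= 1; ++ox, ++t) {
        const int x0 = std::max(0, -ox), x1 = std::min(nx, nx - ox);
        if (x1 <= x0) continue;
        const size_t len = (size_t)(x1 - x0);
        for (int c = 0; c < Cin; ++c) {
          const float* src = X.colptr(c);
          float* dst = Col.colptr(t * Cin + c);
          for (int z = z0; z < z1; ++z) {
            const int zi = z + oz;
            if (zi < 0 || zi >= nz) continue;
            for (int y = 0; y < ny; ++y) {
              const int yi = y + oy;
              if (yi < 0 || yi >= ny) continue;
              std::memcpy(dst + x0 + (size_t)nx * y + plane * (z - z0),
                          src + (x0 + ox) + (size_t)nx * yi + plane * zi,
                          len * sizeof(float));
            }
          }
        }
      }
}

// choose a z-slab height keeping the im2col block under ~128 MB
static int slab_height(int nx, int ny, int nz, int cols) {
  const double bytes_per_slice = (double)nx * ny * cols * 8.0;
  int h = (int)std::floor(128.0 * 1024 * 1024 / std::max(bytes_per_slice, 1.0));
  return std::max(1, std::min(nz, h));
}

// W rows are blocked per offset: block t holds (Cin x Cout) tap weights.
// [[Rcpp::export]]
arma::mat cpp_conv3(const arma::mat& X, const arma::mat& W,
                    const arma::rowvec& b, int nx, int ny, int nz) {
  const int Cin = X.n_cols;
  if ((int)W.n_rows != 27 * Cin) stop("weight shape mismatch");
  const size_t plane = (size_t)nx * ny;
  const arma::fmat Xf = arma::conv_to<arma::fmat>::from(X);
  const arma::fmat Wf = arma::conv_to<arma::fmat>::from(W);
  arma::fmat Y(X.n_rows, W.n_cols);
  const int h = slab_height(nx, ny, nz, 27 * Cin);
  arma::fmat Col(plane * h, 27 * Cin);
  for (int z0 = 0; z0 < nz; z0 += h) {
    const int z1 = std::min(nz, z0 + h);
    const size_t rows = plane * (z1 - z0);
    if ((size_t)Col.n_rows != rows) Col.set_size(rows, 27 * Cin);
    im2col_slab(Xf, nx, ny, nz, z0, z1, Col);
    Y.rows(plane * z0, plane * z0 + rows - 1) = Col * Wf;
  }
  arma::mat Yd = arma::conv_to<arma::mat>::from(Y);
  Yd.each_row() += b;
  return Yd;
}

// [[Rcpp::export]]
List cpp_conv3_backward(const arma::mat& X, const arma::mat& W,
                        const arma::mat& dY, int nx, int ny, int nz) {
  const int Cin = X.n_cols;
  const size_t plane = (size_t)nx * ny;
  const arma::fmat Xf = arma::conv_to<arma::fmat>::from(X);
  const arma::fmat Wf = arma::conv_to<arma::fmat>::from(W);
  const arma::fmat dYf = arma::conv_to<arma::fmat>::from(dY);
  arma::fmat dX(X.n_rows, Cin, arma::fill::zeros);
  arma::fmat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  const int h = slab_height(nx, ny, nz, 27 * Cin);
  arma::fmat Col(plane * h, 27 * Cin);
  for (int z0 = 0; z0 < nz; z0 += h) {
    const int z1 = std::min(nz, z0 + h);
    const size_t rows = plane * (z1 - z0);
    if ((size_t)Col.n_rows != rows) Col.set_size(rows, 27 * Cin);
    im2col_slab(Xf, nx, ny, nz, z0, z1, Col);
    const arma::fmat dYs = dYf.rows(plane * z0, plane * z0 + rows - 1);
    dW += Col.t() * dYs;
    const arma::fmat G = dYs * Wf.t();  // rows x 27Cin
    // col2im scatter: G(p, t*Cin + c) adds into dX(p + offset_t, c)
    int t = 0;
    for (int oz = -1; oz <= 1; ++oz)
      for (int oy = -1; oy <= 1; ++oy)
        for (int ox = -1; ox <= 1; ++ox, ++t) {
          const int x0 = std::max(0, -ox), x1 = std::min(nx, nx - ox);
          if (x1 <= x0) continue;
          const int len = x1 - x0;
          for (int c = 0; c < Cin; ++c) {
            const float* src = G.colptr(t * Cin + c);
            float* dst = dX.colptr(c);
            for (int z = z0; z < z1; ++z) {
              const int zi = z + oz;
              if (zi < 0 || zi >= nz) continue;
              for (int y = 0; y < ny; ++y) {
                const int yi = y + oy;
                if (yi < 0 || yi >= ny) continue;
                float* d = dst + (x0 + ox) + (size_t)nx * yi + plane * zi;
                const float* s = src + x0 + (size_t)nx * y + plane * (z - z0);
                for (int i = 0; i < len; ++i) d[i] += s[i];
              }
            }
          }
        }
  }
  arma::rowvec db = arma::sum(dY, 0);
  return List::create(_["dX"] = arma::conv_to<arma::mat>::from(dX),
                      _["dW"] = arma::conv_to<arma::mat>::from(dW),
                      _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool(const arma::mat& X, int nx, int ny, int nz) {
  const int C = X.n_cols, mx = nx / 2, my = ny / 2, mz = nz / 2;
  arma::mat Y((size_t)mx * my * mz, C);
  arma::umat idx((size_t)mx * my * mz, C);
  for (int c = 0; c < C; ++c) {
    const double* xp = X.colptr(c);
    for (int z = 0; z < mz; ++z)
      for (int y = 0; y < my; ++y)
        for (int x = 0; x < mx; ++x) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bi = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const size_t p = (2 * x + dx) +
                                 (size_t)nx * ((2 * y + dy) +
                                 (size_t)ny * (2 * z + dz));
                if (xp[p] > best) { best = xp[p]; bi = p; }
              }
          const size_t q = x + (size_t)mx * (y + (size_t)my * z);
          Y(q, c) = best;
          idx(q, c) = bi;
        }
  }
  return List::create(_["Y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool_backward(const arma::umat& idx, const arma::mat& dY,
                               size_t n_in) {
  arma::mat dX(n_in, dY.n_cols, arma::fill::zeros);
  for (size_t c = 0; c < dY.n_cols; ++c)
    for (size_t q = 0; q < dY.n_rows; ++q)
      dX(idx(q, c), c) += dY(q, c);
  return dX;
}

// Trilinear 2x up-sampling (half-voxel aligned: output j samples input at
// j/2 - 1/4, clamped); input dims are (nx, ny, nz).
struct UpAxis {
  std::vector<int> i0, i1;
  std::vector<double> w1;
};

static UpAxis up_axis(int n) {
  UpAxis a;
  const int un = 2 * n;
  a.i0.resize(un); a.i1.resize(un); a.w1.resize(un);
  for (int j = 0; j < un; ++j) {
    double x = 0.5 * j - 0.25;
    if (x < 0) x = 0;
    if (x > n - 1) x = n - 1;
    int i0 = (int)std::floor(x);
    if (i0 > n - 2) i0 = std::max(0, n - 2);
    a.i0[j] = i0;
    a.i1[j] = std::min(i0 + 1, n - 1);
    a.w1[j] = x - i0;
  }
  return a;
}

// [[Rcpp::export]]
arma::mat cpp_upsample_tri(const arma::mat& X, int nx, int ny, int nz) {
  const int C = X.n_cols, ux = 2 * nx, uy = 2 * ny, uz = 2 * nz;
  const UpAxis ax = up_axis(nx), ay = up_axis(ny), az = up_axis(nz);
  arma::mat Y((size_t)ux * uy * uz, C);
  for (int c = 0; c < C; ++c) {
    const double* xp = X.colptr(c);
    double* yp = Y.colptr(c);
    for (int z = 0; z < uz; ++z) {
      const double wz = az.w1[z];
      for (int y = 0; y < uy; ++y) {
        const double wy = ay.w1[y];
        const size_t b00 = (size_t)nx * (ay.i0[y] + (size_t)ny * az.i0[z]);
        const size_t b10 = (size_t)nx * (ay.i1[y] + (size_t)ny * az.i0[z]);
        const size_t b01 = (size_t)nx * (ay.i0[y] + (size_t)ny * az.i1[z]);
        const size_t b11 = (size_t)nx * (ay.i1[y] + (size_t)ny * az.i1[z]);
        double* out = yp + (size_t)ux * (y + (size_t)uy * z);
        for (int x = 0; x < ux; ++x) {
          const double wx = ax.w1[x];
          const int i0 = ax.i0[x], i1 = ax.i1[x];
          const double v00 = (1 - wx) * xp[b00 + i0] + wx * xp[b00 + i1];
          const double v10 = (1 - wx) * xp[b10 + i0] + wx * xp[b10 + i1];
          const double v01 = (1 - wx) * xp[b01 + i0] + wx * xp[b01 + i1];
          const double v11 = (1 - wx) * xp[b11 + i0] + wx * xp[b11 + i1];
          out[x] = (1 - wz) * ((1 - wy) * v00 + wy * v10) +
                   wz * ((1 - wy) * v01 + wy * v11);
        }
      }
    }
  }
  return Y;
}

// exact adjoint of cpp_upsample_tri
// [[Rcpp::export]]
arma::mat cpp_upsample_tri_backward(const arma::mat& dY, int nx, int ny,
                                    int nz) {
  const int C = dY.n_cols, ux = 2 * nx, uy = 2 * ny, uz = 2 * nz;
  const UpAxis ax = up_axis(nx), ay = up_axis(ny), az = up_axis(nz);
  arma::mat dX((size_t)nx * ny * nz, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* gp = dY.colptr(c);
    double* dp = dX.colptr(c);
    for (int z = 0; z < uz; ++z) {
      const double wz = az.w1[z];
      for (int y = 0; y < uy; ++y) {
        const double wy = ay.w1[y];
        const size_t b00 = (size_t)nx * (ay.i0[y] + (size_t)ny * az.i0[z]);
        const size_t b10 = (size_t)nx * (ay.i1[y] + (size_t)ny * az.i0[z]);
        const size_t b01 = (size_t)nx * (ay.i0[y] + (size_t)ny * az.i1[z]);
        const size_t b11 = (size_t)nx * (ay.i1[y] + (size_t)ny * az.i1[z]);
        const double* g = gp + (size_t)ux * (y + (size_t)uy * z);
        for (int x = 0; x < ux; ++x) {
          const double wx = ax.w1[x];
          const int i0 = ax.i0[x], i1 = ax.i1[x];
          const double gv = g[x];
          const double w00 = (1 - wz) * (1 - wy), w10 = (1 - wz) * wy;
          const double w01 = wz * (1 - wy), w11 = wz * wy;
          dp[b00 + i0] += gv * w00 * (1 - wx);
          dp[b00 + i1] += gv * w00 * wx;
          dp[b10 + i0] += gv * w10 * (1 - wx);
          dp[b10 + i1] += gv * w10 * wx;
          dp[b01 + i0] += gv * w01 * (1 - wx);
          dp[b01 + i1] += gv * w01 * wx;
          dp[b11 + i0] += gv * w11 * (1 - wx);
          dp[b11 + i1] += gv * w11 * wx;
        }
      }
    }
  }
  return dX;
}

// Nearest-neighbour 2x up-sampling; input dims are (nx, ny, nz).
// [[Rcpp::export]]
arma::mat cpp_upsample(const arma::mat& X, int nx, int ny, int nz) {
  const int C = X.n_cols, ux = 2 * nx, uy = 2 * ny, uz = 2 * nz;
  arma::mat Y((size_t)ux * uy * uz, C);
  for (int c = 0; c < C; ++c) {
    const double* xp = X.colptr(c);
    double* yp = Y.colptr(c);
    for (int z = 0; z < uz; ++z)
      for (int y = 0; y < uy; ++y)
        for (int x = 0; x < ux; ++x)
          yp[x + (size_t)ux * (y + (size_t)uy * z)] =
              xp[(x / 2) + (size_t)nx * ((y / 2) + (size_t)ny * (z / 2))];
  }
  return Y;
}

// [[Rcpp::export]]
arma::mat cpp_upsample_backward(const arma::mat& dY, int nx, int ny, int nz) {
  // nx, ny, nz are the *input* (coarse) dims of the forward op
  const int C = dY.n_cols, ux = 2 * nx, uy = 2 * ny;
  const int uz = 2 * nz;
  arma::mat dX((size_t)nx * ny * nz, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* gp = dY.colptr(c);
    double* dp = dX.colptr(c);
    for (int z = 0; z < uz; ++z)
      for (int y = 0; y < uy; ++y)
        for (int x = 0; x < ux; ++x)
          dp[(x / 2) + (size_t)nx * ((y / 2) + (size_t)ny * (z / 2))] +=
              gp[x + (size_t)ux * (y + (size_t)uy * z)];
  }
  return dX;
}

struct TriSample {
  double val, dx, dy, dz;
};

static TriSample tri_at(const double* v, int nx, int ny, int nz,
                        double px, double py, double pz) {
  const bool inx = (px >= 0 && px <= nx - 1);
  const bool iny = (py >= 0 && py <= ny - 1);
  const bool inz = (pz >= 0 && pz <= nz - 1);
  const double cx = clampd(px, 0, nx - 1);
  const double cy = clampd(py, 0, ny - 1);
  const double cz = clampd(pz, 0, nz - 1);
  int i0 = std::min((int)std::floor(cx), nx - 2);
  int j0 = std::min((int)std::floor(cy), ny - 2);
  int k0 = std::min((int)std::floor(cz), nz - 2);
  const double fx = cx - i0, fy = cy - j0, fz = cz - k0;
  double val = 0, dx = 0, dy = 0, dz = 0;
  for (int a = 0; a < 2; ++a)
    for (int b = 0; b < 2; ++b)
      for (int c = 0; c < 2; ++c) {
        const double vv =
            v[(i0 + a) + (size_t)nx * ((j0 + b) + (size_t)ny * (k0 + c))];
        const double wx = a ? fx : 1 - fx;
        const double wy = b ? fy : 1 - fy;
        const double wz = c ? fz : 1 - fz;
        val += vv * wx * wy * wz;
        dx += vv * (a ? 1.0 : -1.0) * wy * wz;
        dy += vv * wx * (b ? 1.0 : -1.0) * wz;
        dz += vv * wx * wy * (c ? 1.0 : -1.0);
      }
  TriSample s;
  s.val = val;
  s.dx = inx ? dx : 0.0;
  s.dy = iny ? dy : 0.0;
  s.dz = inz ? dz : 0.0;
  return s;
}

// mode 0: clamp to border; mode 1: NA outside the grid.
// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(const NumericVector& vol,
                                   const IntegerVector& dim,
                                   const NumericMatrix& pts, int mode) {
  const int nx = dim[0], ny = dim[1], nz = dim[2], n = pts.nrow();
  const double* v = REAL(vol);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    if (mode == 1 && (px < 0 || px > nx - 1 || py < 0 || py > ny - 1 ||
                      pz < 0 || pz > nz - 1)) {
      out[i] = NA_REAL;
      continue;
    }
    out[i] = tri_at(v, nx, ny, nz, px, py, pz).val;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sample_nearest(const NumericVector& vol,
                                 const IntegerVector& dim,
                                 const NumericMatrix& pts, int mode) {
  const int nx = dim[0], ny = dim[1], nz = dim[2], n = pts.nrow();
  const double* v = REAL(vol);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    if (mode == 1 && (px < -0.5 || px > nx - 0.5 || py < -0.5 ||
                      py > ny - 0.5 || pz < -0.5 || pz > nz - 0.5)) {
      out[i] = NA_REAL;
      continue;
    }
    const int x = (int)clampd(std::round(px), 0, nx - 1);
    const int y = (int)clampd(std::round(py), 0, ny - 1);
    const int z = (int)clampd(std::round(pz), 0, nz - 1);
    out[i] = v[x + (size_t)nx * (y + (size_t)ny * z)];
  }
  return out;
}

// out(x) = T(x + U(x)), border-replicated trilinear sampling.
// [[Rcpp::export]]
NumericVector cpp_pull_back(const NumericVector& vol, const IntegerVector& dim,
                            const NumericMatrix& U) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* v = REAL(vol);
  const size_t N = (size_t)nx * ny * nz;
  NumericVector out(N);
  size_t p = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++p)
        out[p] = tri_at(v, nx, ny, nz, x + U(p, 0), y + U(p, 1),
                        z + U(p, 2)).val;
  return out;
}

// d(sum_x g(x) * out(x)) / dU: analytic trilinear position derivative.
// [[Rcpp::export]]
NumericMatrix cpp_pull_back_grad(const NumericVector& vol,
                                 const IntegerVector& dim,
                                 const NumericMatrix& U,
                                 const NumericVector& g) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* v = REAL(vol);
  const size_t N = (size_t)nx * ny * nz;
  NumericMatrix dU(N, 3);
  size_t p = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++p) {
        const TriSample s =
            tri_at(v, nx, ny, nz, x + U(p, 0), y + U(p, 1), z + U(p, 2));
        dU(p, 0) = g[p] * s.dx;
        dU(p, 1) = g[p] * s.dy;
        dU(p, 2) = g[p] * s.dz;
      }
  return dU;
}

static void edt1d(std::vector<double>& f, std::vector<double>& d,
                  std::vector<int>& vtx, std::vector<double>& zbd,
                  int n, double step) {
  // Felzenszwalb & Huttenlocher lower envelope of parabolas, scaled axis
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  vtx[0] = 0;
  zbd[0] = -INF;
  zbd[1] = INF;
  const double s2 = step * step;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    while (true) {
      if (f[vtx[k]] == INF) {
        if (k == 0) { vtx[0] = q; zbd[0] = -INF; zbd[1] = INF; break; }
        --k;
        continue;
      }
      double s = ((f[q] + s2 * q * q) - (f[vtx[k]] + s2 * vtx[k] * vtx[k])) /
                 (2.0 * s2 * (q - vtx[k]));
      if (s <= zbd[k]) { --k; continue; }
      ++k;
      vtx[k] = q;
      zbd[k] = s;
      zbd[k + 1] = INF;
      break;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zbd[k + 1] < q) ++k;
    d[q] = (f[vtx[k]] == INF)
               ? INF
               : s2 * (q - vtx[k]) * (q - vtx[k]) + f[vtx[k]];
  }
}

// Squared-Euclidean distance (mm) from every voxel to the nearest "on"
// voxel centre; INF if no voxel is on.
// [[Rcpp::export]]
NumericVector cpp_edt(const LogicalVector& on, const IntegerVector& dim,
                      const NumericVector& spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double INF = std::numeric_limits<double>::infinity();
  const size_t N = (size_t)nx * ny * nz;
  std::vector<double> D(N);
  for (size_t p = 0; p < N; ++p) D[p] = on[p] ? 0.0 : INF;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zbd(nmax + 1);
  std::vector<int> vtx(nmax);
  // x pass
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      const size_t base = (size_t)nx * (y + (size_t)ny * z);
      for (int x = 0; x < nx; ++x) f[x] = D[base + x];
      edt1d(f, d, vtx, zbd, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) D[base + x] = d[x];
    }
  // y pass
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = D[x + (size_t)nx * (y + (size_t)ny * z)];
      edt1d(f, d, vtx, zbd, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) D[x + (size_t)nx * (y + (size_t)ny * z)] = d[y];
    }
  // z pass
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = D[x + (size_t)nx * (y + (size_t)ny * z)];
      edt1d(f, d, vtx, zbd, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) D[x + (size_t)nx * (y + (size_t)ny * z)] = d[z];
    }
  NumericVector out(N);
  for (size_t p = 0; p < N; ++p) out[p] = std::sqrt(D[p]);
  return out;
}

// For each row of A, Euclidean distance to the nearest row of B.
// [[Rcpp::export]]
NumericVector cpp_nn_min_dists(const NumericMatrix& A, const NumericMatrix& B) {
  const int n = A.nrow(), m = B.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    double best = std::numeric_limits<double>::infinity();
    for (int j = 0; j < m; ++j) {
      const double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
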