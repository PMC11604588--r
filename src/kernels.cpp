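// Low-level compute kernels for the 3D segmentation network and metrics.
//
// Tensor layout everywhere: column-major R arrays with dim (X, Y, Z, C, N),
// i.e. linear index x + X*(y + Y*(z + Z*(c + C*n))), all 0-based here.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static inline R_xlen_t idx5(int x, int y, int z, int c, int n,
                            int X, int Y, int Z, int C) {
  return x + (R_xlen_t)X * (y + (R_xlen_t)Y * (z + (R_xlen_t)Z * (c + (R_xlen_t)C * n)));
}

// ---------------------------------------------------------------------------
// 3D convolution, stride 1, zero padding k/2 (odd k), output same spatial size
// weights layout: (k, k, k, Cin, Cout)
// ---------------------------------------------------------------------------

// Loops put the kernel taps outside and the x axis innermost, so the hot
// loop is a contiguous shifted axpy the compiler can vectorize.

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector xd,
                             NumericVector w, IntegerVector wd,
                             NumericVector bias) {
  const int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3], N = xd[4];
  const int K = wd[0], Co = wd[4];
  const int P = K / 2;
  if (wd[3] != Ci) stop("conv3d: weight Cin (%d) != input channels (%d)", wd[3], Ci);
  NumericVector y((R_xlen_t)X * Y * Z * Co * N);
  const double* px = x.begin();
  const double* pw = w.begin();
  double* py = y.begin();

  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      double* out = py + idx5(0, 0, 0, co, n, X, Y, Z, Co);
      const double b = bias[co];
      for (R_xlen_t i = 0; i < (R_xlen_t)X * Y * Z; ++i) out[i] = b;
      for (int ci = 0; ci < Ci; ++ci) {
        const double* in = px + idx5(0, 0, 0, ci, n, X, Y, Z, Ci);
        for (int kz = 0; kz < K; ++kz)
          for (int ky = 0; ky < K; ++ky)
            for (int kx = 0; kx < K; ++kx) {
              const double wv = pw[kx + (R_xlen_t)K * (ky + (R_xlen_t)K * (kz + (R_xlen_t)K * (ci + (R_xlen_t)Ci * co)))];
              if (wv == 0.0) continue;
              const int dx = kx - P, dy = ky - P, dz = kz - P;
              const int z0 = std::max(0, -dz), z1 = std::min(Z, Z - dz);
              const int y0 = std::max(0, -dy), y1 = std::min(Y, Y - dy);
              const int x0 = std::max(0, -dx), x1 = std::min(X, X - dx);
              for (int zz = z0; zz < z1; ++zz)
                for (int yy = y0; yy < y1; ++yy) {
                  double* orow = out + ((R_xlen_t)zz * Y + yy) * X;
                  const double* irow = in + ((R_xlen_t)(zz + dz) * Y + (yy + dy)) * X + dx;
                  for (int xx = x0; xx < x1; ++xx)
                    orow[xx] += wv * irow[xx];
                }
            }
      }
    }
  y.attr("dim") = IntegerVector::create(X, Y, Z, Co, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector xd,
                    NumericVector w, IntegerVector wd,
                    NumericVector gy) {
  const int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3], N = xd[4];
  const int K = wd[0], Co = wd[4];
  const int P = K / 2;
  NumericVector gx((R_xlen_t)X * Y * Z * Ci * N);
  NumericVector gw(w.size());
  NumericVector gb(Co);
  const double* px = x.begin();
  const double* pw = w.begin();
  const double* pgy = gy.begin();
  double* pgx = gx.begin();
  double* pgw = gw.begin();

  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      const double* g = pgy + idx5(0, 0, 0, co, n, X, Y, Z, Co);
      double accb = 0.0;
      for (R_xlen_t i = 0; i < (R_xlen_t)X * Y * Z; ++i) accb += g[i];
      gb[co] += accb;
      for (int ci = 0; ci < Ci; ++ci) {
        const double* in = px + idx5(0, 0, 0, ci, n, X, Y, Z, Ci);
        double* gi = pgx + idx5(0, 0, 0, ci, n, X, Y, Z, Ci);
        for (int kz = 0; kz < K; ++kz)
          for (int ky = 0; ky < K; ++ky)
            for (int kx = 0; kx < K; ++kx) {
              const R_xlen_t wo = kx + (R_xlen_t)K * (ky + (R_xlen_t)K * (kz + (R_xlen_t)K * (ci + (R_xlen_t)Ci * co)));
              const double wv = pw[wo];
              const int dx = kx - P, dy = ky - P, dz = kz - P;
              const int z0 = std::max(0, -dz), z1 = std::min(Z, Z - dz);
              const int y0 = std::max(0, -dy), y1 = std::min(Y, Y - dy);
              const int x0 = std::max(0, -dx), x1 = std::min(X, X - dx);
              double accw = 0.0;
              for (int zz = z0; zz < z1; ++zz)
                for (int yy = y0; yy < y1; ++yy) {
                  const double* grow = g + ((R_xlen_t)zz * Y + yy) * X;
                  const double* irow = in + ((R_xlen_t)(zz + dz) * Y + (yy + dy)) * X + dx;
                  double* girow = gi + ((R_xlen_t)(zz + dz) * Y + (yy + dy)) * X + dx;
                  for (int xx = x0; xx < x1; ++xx) {
                    const double gg = grow[xx];
                    accw += irow[xx] * gg;
                    girow[xx] += wv * gg;
                  }
                }
              pgw[wo] += accw;
            }
      }
    }
  gx.attr("dim") = IntegerVector::create(X, Y, Z, Ci, N);
  gw.attr("dim") = w.attr("dim");
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// 2x max pooling with argmax indices (0-based absolute indices into the input)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x, IntegerVector xd) {
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3], N = xd[4];
  if (X % 2 || Y % 2 || Z % 2) stop("maxpool: spatial dims must be even");
  const int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  NumericVector y((R_xlen_t)Xo * Yo * Zo * C * N);
  NumericVector ind(y.size());  // double storage: indices can exceed 2^31
  const double* px = x.begin();
  double* py = y.begin();
  double* pi = ind.begin();

  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int zz = 0; zz < Zo; ++zz)
        for (int yy = 0; yy < Yo; ++yy)
          for (int xx = 0; xx < Xo; ++xx, ++o) {
            double best = -std::numeric_limits<double>::infinity();
            R_xlen_t besti = -1;
            for (int dz = 0; dz < 2; ++dz)
              for (int dy = 0; dy < 2; ++dy)
                for (int dx = 0; dx < 2; ++dx) {
                  R_xlen_t j = idx5(2 * xx + dx, 2 * yy + dy, 2 * zz + dz, c, n, X, Y, Z, C);
                  if (px[j] > best) { best = px[j]; besti = j; }
                }
            py[o] = best;
            pi[o] = (double)besti;
          }
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C, N);
  ind.attr("dim") = y.attr("dim");
  return List::create(_["y"] = y, _["ind"] = ind);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector gy, NumericVector ind,
                               IntegerVector xd) {
  NumericVector gx((R_xlen_t)xd[0] * xd[1] * xd[2] * xd[3] * xd[4]);
  const double* pgy = gy.begin();
  const double* pi = ind.begin();
  double* pgx = gx.begin();
  for (R_xlen_t o = 0; o < gy.size(); ++o)
    pgx[(R_xlen_t)pi[o]] += pgy[o];
  gx.attr("dim") = xd;
  return gx;
}

// max-unpooling: scatter values to the recorded argmax positions, zeros
// elsewhere. Validates that each index lies inside its own 2x2x2 window.

// [[Rcpp::export]]
NumericVector cpp_unpool2_fwd(NumericVector x, NumericVector ind,
                              IntegerVector xd) {
  const int Xo = xd[0], Yo = xd[1], Zo = xd[2], C = xd[3], N = xd[4];
  const int X = 2 * Xo, Y = 2 * Yo, Z = 2 * Zo;
  NumericVector y((R_xlen_t)X * Y * Z * C * N);
  const double* px = x.begin();
  const double* pi = ind.begin();
  double* py = y.begin();
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int zz = 0; zz < Zo; ++zz)
        for (int yy = 0; yy < Yo; ++yy)
          for (int xx = 0; xx < Xo; ++xx, ++o) {
            R_xlen_t j = (R_xlen_t)pi[o];
            if (j < 0 || j >= y.size()) stop("unpool: index out of range");
            R_xlen_t rem = j;
            int tx = rem % X; rem /= X;
            int ty = rem % Y; rem /= Y;
            int tz = rem % Z; rem /= Z;
            int tc = rem % C; rem /= C;
            int tn = (int)rem;
            if (tx / 2 != xx || ty / 2 != yy || tz / 2 != zz || tc != c || tn != n)
              stop("unpool: index outside its pooling window (corrupted state)");
            py[j] = px[o];
          }
  y.attr("dim") = IntegerVector::create(X, Y, Z, C, N);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_unpool2_bwd(NumericVector gy, NumericVector ind,
                              IntegerVector xd) {
  NumericVector gx((R_xlen_t)xd[0] * xd[1] * xd[2] * xd[3] * xd[4]);
  const double* pgy = gy.begin();
  const double* pi = ind.begin();
  for (R_xlen_t o = 0; o < gx.size(); ++o)
    gx[o] = pgy[(R_xlen_t)pi[o]];
  gx.attr("dim") = xd;
  return gx;
}

// ---------------------------------------------------------------------------
// trilinear 2x upsampling (align_corners = false) and its adjoint
// ---------------------------------------------------------------------------

static void lin_weights(int n_in, std::vector<int>& i0, std::vector<int>& i1,
                        std::vector<double>& w1) {
  int n_out = 2 * n_in;
  i0.resize(n_out); i1.resize(n_out); w1.resize(n_out);
  for (int o = 0; o < n_out; ++o) {
    double src = (o + 0.5) / 2.0 - 0.5;
    int lo = (int)std::floor(src);
    double f = src - lo;
    int hi = lo + 1;
    if (lo < 0) { lo = 0; hi = 0; f = 0.0; }
    if (hi > n_in - 1) { hi = n_in - 1; lo = n_in - 1; f = 0.0; }
    i0[o] = lo; i1[o] = hi; w1[o] = f;
  }
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(NumericVector x, IntegerVector xd) {
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3], N = xd[4];
  std::vector<int> xi0, xi1, yi0, yi1, zi0, zi1;
  std::vector<double> xw, yw, zw;
  lin_weights(X, xi0, xi1, xw);
  lin_weights(Y, yi0, yi1, yw);
  lin_weights(Z, zi0, zi1, zw);
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  NumericVector y((R_xlen_t)Xo * Yo * Zo * C * N);
  const double* px = x.begin();
  double* py = y.begin();
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int zz = 0; zz < Zo; ++zz)
        for (int yy = 0; yy < Yo; ++yy)
          for (int xx = 0; xx < Xo; ++xx, ++o) {
            double wz = zw[zz], wy = yw[yy], wx = xw[xx];
            double v = 0.0;
            for (int dz = 0; dz < 2; ++dz) {
              int sz = dz ? zi1[zz] : zi0[zz];
              double fz = dz ? wz : 1.0 - wz;
              if (fz == 0.0) continue;
              for (int dy = 0; dy < 2; ++dy) {
                int sy = dy ? yi1[yy] : yi0[yy];
                double fy = dy ? wy : 1.0 - wy;
                if (fy == 0.0) continue;
                for (int dx = 0; dx < 2; ++dx) {
                  int sx = dx ? xi1[xx] : xi0[xx];
                  double fx = dx ? wx : 1.0 - wx;
                  if (fx == 0.0) continue;
                  v += fz * fy * fx * px[idx5(sx, sy, sz, c, n, X, Y, Z, C)];
                }
              }
            }
            py[o] = v;
          }
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C, N);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector gy, IntegerVector xd) {
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3], N = xd[4];
  std::vector<int> xi0, xi1, yi0, yi1, zi0, zi1;
  std::vector<double> xw, yw, zw;
  lin_weights(X, xi0, xi1, xw);
  lin_weights(Y, yi0, yi1, yw);
  lin_weights(Z, zi0, zi1, zw);
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  NumericVector gx((R_xlen_t)X * Y * Z * C * N);
  const double* pgy = gy.begin();
  double* pgx = gx.begin();
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int zz = 0; zz < Zo; ++zz)
        for (int yy = 0; yy < Yo; ++yy)
          for (int xx = 0; xx < Xo; ++xx, ++o) {
            double g = pgy[o];
            if (g == 0.0) continue;
            double wz = zw[zz], wy = yw[yy], wx = xw[xx];
            for (int dz = 0; dz < 2; ++dz) {
              int sz = dz ? zi1[zz] : zi0[zz];
              double fz = dz ? wz : 1.0 - wz;
              if (fz == 0.0) continue;
              for (int dy = 0; dy < 2; ++dy) {
                int sy = dy ? yi1[yy] : yi0[yy];
                double fy = dy ? wy : 1.0 - wy;
                if (fy == 0.0) continue;
                for (int dx = 0; dx < 2; ++dx) {
                  int sx = dx ? xi1[xx] : xi0[xx];
                  double fx = dx ? wx : 1.0 - wx;
                  if (fx == 0.0) continue;
                  pgx[idx5(sx, sy, sz, c, n, X, Y, Z, C)] += fz * fy * fx * g;
                }
              }
            }
          }
  gx.attr("dim") = xd;
  return gx;
}

// ---------------------------------------------------------------------------
// nearest-neighbour distances between surface point sets, uniform-grid index
// ---------------------------------------------------------------------------

// For each row of `a` (m x 3), the Euclidean distance to the nearest row of
// `b` (n x 3). Points are binned into a uniform grid over b's bounding box;
// the query expands cell shells until the best found distance beats the
// shell's lower bound.

// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericMatrix a, NumericMatrix b) {
  const int m = a.nrow(), n = b.nrow();
  if (n == 0) stop("nn_dist: empty reference point set");
  NumericVector out(m);

  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) {
    lo[d] = hi[d] = b(0, d);
    for (int i = 1; i < n; ++i) {
      if (b(i, d) < lo[d]) lo[d] = b(i, d);
      if (b(i, d) > hi[d]) hi[d] = b(i, d);
    }
  }
  double vol = 1.0;
  for (int d = 0; d < 3; ++d) vol *= std::max(hi[d] - lo[d], 1e-9);
  double h = std::cbrt(vol / n);
  if (!(h > 0)) h = 1.0;
  int G[3];
  for (int d = 0; d < 3; ++d) {
    G[d] = std::max(1, std::min(64, (int)std::ceil((hi[d] - lo[d]) / h)));
  }
  std::vector<std::vector<int>> cells((size_t)G[0] * G[1] * G[2]);
  double cw[3];
  for (int d = 0; d < 3; ++d) cw[d] = std::max((hi[d] - lo[d]) / G[d], 1e-12);
  auto cell_of = [&](double v, int d) {
    int c = (int)((v - lo[d]) / cw[d]);
    if (c < 0) c = 0;
    if (c >= G[d]) c = G[d] - 1;
    return c;
  };
  for (int i = 0; i < n; ++i) {
    int cx = cell_of(b(i, 0), 0), cy = cell_of(b(i, 1), 1), cz = cell_of(b(i, 2), 2);
    cells[cx + (size_t)G[0] * (cy + (size_t)G[1] * cz)].push_back(i);
  }
  double minw = std::min(cw[0], std::min(cw[1], cw[2]));
  int max_shell = G[0] + G[1] + G[2] + 2;

  for (int q = 0; q < m; ++q) {
    double qx = a(q, 0), qy = a(q, 1), qz = a(q, 2);
    int cx = cell_of(qx, 0), cy = cell_of(qy, 1), cz = cell_of(qz, 2);
    double best = std::numeric_limits<double>::infinity();
    for (int s = 0; s <= max_shell; ++s) {
      // lower bound on distance to any point in shell s (in cells)
      if (s > 0 && best < (s - 1) * minw) break;
      bool any = false;
      for (int dz = -s; dz <= s; ++dz) {
        int z = cz + dz;
        if (z < 0 || z >= G[2]) continue;
        for (int dy = -s; dy <= s; ++dy) {
          int y = cy + dy;
          if (y < 0 || y >= G[1]) continue;
          for (int dx = -s; dx <= s; ++dx) {
            if (std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz))) != s)
              continue;  // only the shell surface
            int x = cx + dx;
            if (x < 0 || x >= G[0]) continue;
            any = true;
            const std::vector<int>& cell = cells[x + (size_t)G[0] * (y + (size_t)G[1] * z)];
            for (int i : cell) {
              double ddx = b(i, 0) - qx, ddy = b(i, 1) - qy, ddz = b(i, 2) - qz;
              double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
              if (d2 < best * best) best = std::sqrt(d2);
            }
          }
        }
      }
      if (!any && s > max_shell) break;
    }
    out[q] = best;
  }
  return out;
}
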