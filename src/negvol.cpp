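// Compiled kernels: 3D convolution (im2col + GEMM), pooling, exact Euclidean
// distance transform, connected components, marching tetrahedra, mesh
// voxelization by ray parity, Hausdorff distance, nearest neighbours, and a
// slice-wise median filter.  All grids are column-major R arrays indexed
// (x, y, z[, c]); meshes are N x 3 coordinate matrices in mm.

#include <RcppArmadillo.h>
#include <unordered_map>
#include <queue>
#include <cstdint>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline R_xlen_t idx3(int x, int y, int z, int X, int Y) {
  return (R_xlen_t)x + (R_xlen_t)X * ((R_xlen_t)y + (R_xlen_t)Y * (R_xlen_t)z);
}

// ---------------------------------------------------------------------------
// 3D convolution, stride 1, odd kernel, zero ("same") padding.
// x: (X,Y,Z,Ci), w: (k,k,k,Ci,Co), bias: Co.  Cross-correlation convention.
// ---------------------------------------------------------------------------

static void im2col_slice(const double* x, int X, int Y, int Z, int Ci,
                         int k, int z0, arma::mat& M) {
  const int h = k / 2;
  const R_xlen_t plane = (R_xlen_t)X * Y;
  const R_xlen_t volsz = plane * Z;
  // rows: kx + k*(ky + k*(kz + k*ci)); cols: x + X*y
  for (int ci = 0; ci < Ci; ++ci) {
    const double* xc = x + (R_xlen_t)ci * volsz;
    for (int kz = 0; kz < k; ++kz) {
      int z = z0 + kz - h;
      bool zok = (z >= 0 && z < Z);
      for (int ky = 0; ky < k; ++ky) {
        for (int kx = 0; kx < k; ++kx) {
          int row = kx + k * (ky + k * (kz + k * ci));
          double* Mrow = M.memptr() + row; // stride = n_rows
          const int nr = M.n_rows;
          for (int y = 0; y < Y; ++y) {
            int yy = y + ky - h;
            bool yok = zok && (yy >= 0 && yy < Y);
            R_xlen_t base = yok ? (R_xlen_t)X * yy + plane * z : 0;
            for (int xctr = 0; xctr < X; ++xctr) {
              int xx = xctr + kx - h;
              double v = 0.0;
              if (yok && xx >= 0 && xx < X) v = xc[base + xx];
              Mrow[(R_xlen_t)(xctr + X * y) * nr] = v;
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_same(NumericVector x, NumericVector w, NumericVector bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3];
  int k = wd[0], Co = wd[4];
  if (wd[3] != Ci) stop("conv3d: channel mismatch");
  NumericVector y(  (R_xlen_t)X * Y * Z * Co );
  y.attr("dim") = IntegerVector::create(X, Y, Z, Co);
  arma::mat Wm(w.begin(), (arma::uword)k * k * k * Ci, Co, false, true);
  arma::mat M((arma::uword)k * k * k * Ci, (arma::uword)X * Y);
  const R_xlen_t plane = (R_xlen_t)X * Y, volo = plane * Z;
  for (int z = 0; z < Z; ++z) {
    im2col_slice(x.begin(), X, Y, Z, Ci, k, z, M);
    arma::mat Yz = Wm.t() * M; // Co x (X*Y)
    for (int co = 0; co < Co; ++co) {
      double b = bias[co];
      double* dst = y.begin() + (R_xlen_t)co * volo + plane * z;
      const double* src = Yz.memptr() + co; // row co, stride Co
      for (R_xlen_t i = 0; i < plane; ++i) dst[i] = src[i * Co] + b;
    }
  }
  return y;
}

// gradient of conv3d_same w.r.t. weights: dW = sum_z im2col(x, z) * dY_z^T
// [[Rcpp::export]]
NumericVector cpp_conv3d_same_gradw(NumericVector x, NumericVector dy, int k) {
  IntegerVector xd = x.attr("dim"), yd = dy.attr("dim");
  int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3], Co = yd[3];
  arma::mat dW((arma::uword)k * k * k * Ci, Co, arma::fill::zeros);
  arma::mat M((arma::uword)k * k * k * Ci, (arma::uword)X * Y);
  const R_xlen_t plane = (R_xlen_t)X * Y, volo = plane * Z;
  arma::mat dYz((arma::uword)X * Y, Co);
  for (int z = 0; z < Z; ++z) {
    im2col_slice(x.begin(), X, Y, Z, Ci, k, z, M);
    for (int co = 0; co < Co; ++co) {
      const double* src = dy.begin() + (R_xlen_t)co * volo + plane * z;
      std::copy(src, src + plane, dYz.colptr(co));
    }
    dW += M * dYz;
  }
  NumericVector out(dW.begin(), dW.end());
  out.attr("dim") = IntegerVector::create(k, k, k, Ci, Co);
  return out;
}

// ---------------------------------------------------------------------------
// Strided 2x2x2 down-convolution (stride 2) and its transpose (upsampling).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_conv3d_down2(NumericVector x, NumericVector w, NumericVector bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3], Co = wd[4];
  int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  NumericVector y((R_xlen_t)Xo * Yo * Zo * Co);
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, Co);
  const R_xlen_t voli = (R_xlen_t)X * Y * Z, volo = (R_xlen_t)Xo * Yo * Zo;
  for (int co = 0; co < Co; ++co) {
    double* yc = y.begin() + volo * co;
    for (int zo = 0; zo < Zo; ++zo) for (int yo = 0; yo < Yo; ++yo) for (int xo = 0; xo < Xo; ++xo) {
      double acc = bias[co];
      for (int ci = 0; ci < Ci; ++ci) {
        const double* xc = x.begin() + voli * ci;
        const double* wp = w.begin() + 8 * ((R_xlen_t)ci + (R_xlen_t)Ci * co);
        for (int dz = 0; dz < 2; ++dz) for (int dyy = 0; dyy < 2; ++dyy) for (int dx = 0; dx < 2; ++dx)
          acc += wp[dx + 2 * (dyy + 2 * dz)] * xc[idx3(2 * xo + dx, 2 * yo + dyy, 2 * zo + dz, X, Y)];
      }
      yc[idx3(xo, yo, zo, Xo, Yo)] = acc;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_down2_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3], Co = wd[4];
  int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  NumericVector dx((R_xlen_t)X * Y * Z * Ci), dw(w.size()), db(Co);
  dx.attr("dim") = xd; dw.attr("dim") = wd;
  const R_xlen_t voli = (R_xlen_t)X * Y * Z, volo = (R_xlen_t)Xo * Yo * Zo;
  for (int co = 0; co < Co; ++co) {
    const double* dyc = dy.begin() + volo * co;
    double bacc = 0.0;
    for (R_xlen_t i = 0; i < volo; ++i) bacc += dyc[i];
    db[co] = bacc;
    for (int ci = 0; ci < Ci; ++ci) {
      const double* xc = x.begin() + voli * ci;
      double* dxc = dx.begin() + voli * ci;
      const double* wp = w.begin() + 8 * ((R_xlen_t)ci + (R_xlen_t)Ci * co);
      double* dwp = dw.begin() + 8 * ((R_xlen_t)ci + (R_xlen_t)Ci * co);
      for (int zo = 0; zo < Zo; ++zo) for (int yo = 0; yo < Yo; ++yo) for (int xo = 0; xo < Xo; ++xo) {
        double g = dyc[idx3(xo, yo, zo, Xo, Yo)];
        for (int dz = 0; dz < 2; ++dz) for (int dyy = 0; dyy < 2; ++dyy) for (int dxo = 0; dxo < 2; ++dxo) {
          R_xlen_t xi = idx3(2 * xo + dxo, 2 * yo + dyy, 2 * zo + dz, X, Y);
          dwp[dxo + 2 * (dyy + 2 * dz)] += g * xc[xi];
          dxc[xi] += g * wp[dxo + 2 * (dyy + 2 * dz)];
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// transposed convolution, kernel 2, stride 2 (non-overlapping upsampling)
// [[Rcpp::export]]
NumericVector cpp_conv3d_up2(NumericVector x, NumericVector w, NumericVector bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3], Co = wd[4];
  int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  NumericVector y((R_xlen_t)Xo * Yo * Zo * Co);
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, Co);
  const R_xlen_t voli = (R_xlen_t)X * Y * Z, volo = (R_xlen_t)Xo * Yo * Zo;
  for (int co = 0; co < Co; ++co) {
    double* yc = y.begin() + volo * co;
    for (R_xlen_t i = 0; i < volo; ++i) yc[i] = bias[co];
    for (int ci = 0; ci < Ci; ++ci) {
      const double* xc = x.begin() + voli * ci;
      const double* wp = w.begin() + 8 * ((R_xlen_t)ci + (R_xlen_t)Ci * co);
      for (int z = 0; z < Z; ++z) for (int yy = 0; yy < Y; ++yy) for (int xx = 0; xx < X; ++xx) {
        double v = xc[idx3(xx, yy, z, X, Y)];
        for (int dz = 0; dz < 2; ++dz) for (int dyy = 0; dyy < 2; ++dyy) for (int dx = 0; dx < 2; ++dx)
          yc[idx3(2 * xx + dx, 2 * yy + dyy, 2 * z + dz, Xo, Yo)] += v * wp[dx + 2 * (dyy + 2 * dz)];
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_up2_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3], Co = wd[4];
  int Xo = 2 * X, Yo = 2 * Y;
  NumericVector dx(x.size()), dw(w.size()), db(Co);
  dx.attr("dim") = xd; dw.attr("dim") = wd;
  const R_xlen_t voli = (R_xlen_t)X * Y * Z, volo = voli * 8;
  for (int co = 0; co < Co; ++co) {
    const double* dyc = dy.begin() + volo * co;
    double bacc = 0.0;
    for (R_xlen_t i = 0; i < volo; ++i) bacc += dyc[i];
    db[co] = bacc;
    for (int ci = 0; ci < Ci; ++ci) {
      const double* xc = x.begin() + voli * ci;
      double* dxc = dx.begin() + voli * ci;
      const double* wp = w.begin() + 8 * ((R_xlen_t)ci + (R_xlen_t)Ci * co);
      double* dwp = dw.begin() + 8 * ((R_xlen_t)ci + (R_xlen_t)Ci * co);
      for (int z = 0; z < Z; ++z) for (int yy = 0; yy < Y; ++yy) for (int xx = 0; xx < X; ++xx) {
        R_xlen_t xi = idx3(xx, yy, z, X, Y);
        double v = xc[xi], acc = 0.0;
        for (int dz = 0; dz < 2; ++dz) for (int dyy = 0; dyy < 2; ++dyy) for (int dxo = 0; dxo < 2; ++dxo) {
          double g = dyc[idx3(2 * xx + dxo, 2 * yy + dyy, 2 * z + dz, Xo, Yo)];
          acc += g * wp[dxo + 2 * (dyy + 2 * dz)];
          dwp[dxo + 2 * (dyy + 2 * dz)] += g * v;
        }
        dxc[xi] += acc;
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ---------------------------------------------------------------------------
// 2x2x2 max pooling, stride 2
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_maxpool2(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  NumericVector y((R_xlen_t)Xo * Yo * Zo * C);
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C);
  NumericVector idx(y.size()); // linear 0-based index into x of the max
  const R_xlen_t voli = (R_xlen_t)X * Y * Z, volo = (R_xlen_t)Xo * Yo * Zo;
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + voli * c;
    double* yc = y.begin() + volo * c;
    double* ic = idx.begin() + volo * c;
    for (int zo = 0; zo < Zo; ++zo) for (int yo = 0; yo < Yo; ++yo) for (int xo = 0; xo < Xo; ++xo) {
      double best = -HUGE_VAL; R_xlen_t bi = 0;
      for (int dz = 0; dz < 2; ++dz) for (int dyy = 0; dyy < 2; ++dyy) for (int dx = 0; dx < 2; ++dx) {
        R_xlen_t xi = idx3(2 * xo + dx, 2 * yo + dyy, 2 * zo + dz, X, Y);
        if (xc[xi] > best) { best = xc[xi]; bi = xi; }
      }
      yc[idx3(xo, yo, zo, Xo, Yo)] = best;
      ic[idx3(xo, yo, zo, Xo, Yo)] = (double)(bi + voli * c);
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector dy, NumericVector idx, IntegerVector xdim) {
  NumericVector dx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[(R_xlen_t)idx[i]] += dy[i];
  return dx;
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher), 3 passes.
// Returns distance in mm from every voxel centre to the nearest TRUE voxel.
// ---------------------------------------------------------------------------

static void edt1d(const double* f, double* d, int n, double h) {
  std::vector<int> v(n); std::vector<double> z(n + 1);
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == HUGE_VAL) continue; // +inf parabolas never win
    double s = 0.0;
    while (k >= 0) {
      double xq = q * h, xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) --k; else break;
    }
    if (k < 0) { k = 0; v[0] = q; z[0] = -HUGE_VAL; z[1] = HUGE_VAL; }
    else { ++k; v[k] = q; z[k] = s; z[k + 1] = HUGE_VAL; }
  }
  if (k < 0) { for (int q = 0; q < n; ++q) d[q] = HUGE_VAL; return; }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[j + 1] < xq) ++j;
    double dx = xq - v[j] * h;
    d[q] = f[v[j]] + dx * dx;
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  int X = dims[0], Y = dims[1], Z = dims[2];
  R_xlen_t n = (R_xlen_t)X * Y * Z;
  std::vector<double> D(n);
  for (R_xlen_t i = 0; i < n; ++i) D[i] = mask[i] ? 0.0 : HUGE_VAL;
  std::vector<double> f(std::max(X, std::max(Y, Z))), d(f.size());
  // x pass
  for (int z = 0; z < Z; ++z) for (int y = 0; y < Y; ++y) {
    R_xlen_t base = idx3(0, y, z, X, Y);
    for (int x = 0; x < X; ++x) f[x] = D[base + x];
    edt1d(f.data(), d.data(), X, spacing[0]);
    for (int x = 0; x < X; ++x) D[base + x] = d[x];
  }
  // y pass
  for (int z = 0; z < Z; ++z) for (int x = 0; x < X; ++x) {
    for (int y = 0; y < Y; ++y) f[y] = D[idx3(x, y, z, X, Y)];
    edt1d(f.data(), d.data(), Y, spacing[1]);
    for (int y = 0; y < Y; ++y) D[idx3(x, y, z, X, Y)] = d[y];
  }
  // z pass
  for (int y = 0; y < Y; ++y) for (int x = 0; x < X; ++x) {
    for (int z = 0; z < Z; ++z) f[z] = D[idx3(x, y, z, X, Y)];
    edt1d(f.data(), d.data(), Z, spacing[2]);
    for (int z = 0; z < Z; ++z) D[idx3(x, y, z, X, Y)] = d[z];
  }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = (D[i] == HUGE_VAL) ? R_PosInf : std::sqrt(D[i]);
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Connected components (6- or 26-connectivity), BFS labelling.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  int X = dims[0], Y = dims[1], Z = dims[2];
  R_xlen_t n = (R_xlen_t)X * Y * Z;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;
  std::vector<std::array<int,3>> nbr;
  for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx) {
    if (dx == 0 && dy == 0 && dz == 0) continue;
    int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
    if (connectivity == 6 && manh != 1) continue;
    nbr.push_back({dx, dy, dz});
  }
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    lab[s] = ++next; q.push(s);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int z = cur / ((R_xlen_t)X * Y);
      int rem = cur - (R_xlen_t)z * X * Y;
      int y = rem / X, x = rem % X;
      for (auto& d : nbr) {
        int nx = x + d[0], ny = y + d[1], nz = z + d[2];
        if (nx < 0 || nx >= X || ny < 0 || ny >= Y || nz < 0 || nz >= Z) continue;
        R_xlen_t ni = idx3(nx, ny, nz, X, Y);
        if (mask[ni] && lab[ni] == 0) { lab[ni] = next; q.push(ni); }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra on a scalar grid: watertight isosurface of field > level.
// The 6-tetrahedra cube decomposition shares face diagonals between
// neighbouring cubes, so the triangulation is consistent and manifold.
// Triangles are oriented with outward normals (pointing towards field < level).
// ---------------------------------------------------------------------------

struct VKey {
  uint64_t a, b;
  bool operator==(const VKey& o) const { return a == o.a && b == o.b; }
};
struct VKeyHash {
  size_t operator()(const VKey& k) const {
    return std::hash<uint64_t>()(k.a * 1000003ULL ^ k.b);
  }
};

// [[Rcpp::export]]
List cpp_march_tets(NumericVector field, IntegerVector dims, double level,
                    NumericVector spacing, NumericVector origin) {
  int X = dims[0], Y = dims[1], Z = dims[2];
  const int tets[6][4] = {
    {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}
  };
  const int cx[8] = {0,1,1,0,0,1,1,0};
  const int cy[8] = {0,0,1,1,0,0,1,1};
  const int cz[8] = {0,0,0,0,1,1,1,1};
  std::unordered_map<VKey,int,VKeyHash> vmap;
  std::vector<double> verts; // xyz triples
  std::vector<int> faces;    // 0-based triples

  auto gid = [&](int x, int y, int z) -> uint64_t {
    return (uint64_t)x + (uint64_t)X * ((uint64_t)y + (uint64_t)Y * (uint64_t)z);
  };
  auto edge_vertex = [&](int x0, int y0, int z0, double f0,
                         int x1, int y1, int z1, double f1) -> int {
    uint64_t a = gid(x0, y0, z0), b = gid(x1, y1, z1);
    if (a > b) { std::swap(a, b); std::swap(f0, f1); std::swap(x0, x1); std::swap(y0, y1); std::swap(z0, z1); }
    VKey key{a, b};
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double t = (level - f0) / (f1 - f0);
    if (t < 1e-6) t = 1e-6; if (t > 1 - 1e-6) t = 1 - 1e-6;
    double px = origin[0] + spacing[0] * (x0 + t * (x1 - x0));
    double py = origin[1] + spacing[1] * (y0 + t * (y1 - y0));
    double pz = origin[2] + spacing[2] * (z0 + t * (z1 - z0));
    int id = (int)(verts.size() / 3);
    verts.push_back(px); verts.push_back(py); verts.push_back(pz);
    vmap.emplace(key, id);
    return id;
  };
  auto emit = [&](int v0, int v1, int v2,
                  double rx, double ry, double rz) {
    // orient so the normal points away from the positive-side reference point
    const double* p0 = &verts[3 * v0];
    const double* p1 = &verts[3 * v1];
    const double* p2 = &verts[3 * v2];
    double ux = p1[0]-p0[0], uy = p1[1]-p0[1], uz = p1[2]-p0[2];
    double vx = p2[0]-p0[0], vy = p2[1]-p0[1], vz = p2[2]-p0[2];
    double nx = uy*vz - uz*vy, ny = uz*vx - ux*vz, nz = ux*vy - uy*vx;
    double cxp = (p0[0]+p1[0]+p2[0])/3.0, cyp = (p0[1]+p1[1]+p2[1])/3.0, czp = (p0[2]+p1[2]+p2[2])/3.0;
    double d = nx*(rx-cxp) + ny*(ry-cyp) + nz*(rz-czp);
    if (d > 0) { faces.push_back(v0); faces.push_back(v2); faces.push_back(v1); }
    else       { faces.push_back(v0); faces.push_back(v1); faces.push_back(v2); }
  };

  int vi[8]; double fv[8]; int px[8], py[8], pz[8];
  for (int z = 0; z < Z - 1; ++z) for (int y = 0; y < Y - 1; ++y) for (int x = 0; x < X - 1; ++x) {
    for (int c = 0; c < 8; ++c) {
      px[c] = x + cx[c]; py[c] = y + cy[c]; pz[c] = z + cz[c];
      fv[c] = field[idx3(px[c], py[c], pz[c], X, Y)];
    }
    (void)vi;
    for (int t = 0; t < 6; ++t) {
      int a = tets[t][0], b = tets[t][1], c = tets[t][2], d = tets[t][3];
      int id[4] = {a, b, c, d};
      bool pos[4]; int npos = 0;
      for (int j = 0; j < 4; ++j) { pos[j] = fv[id[j]] > level; if (pos[j]) ++npos; }
      if (npos == 0 || npos == 4) continue;
      // reference point: centroid of positive corners (in mm)
      double rx = 0, ry = 0, rz = 0;
      for (int j = 0; j < 4; ++j) if (pos[j]) {
        rx += origin[0] + spacing[0] * px[id[j]];
        ry += origin[1] + spacing[1] * py[id[j]];
        rz += origin[2] + spacing[2] * pz[id[j]];
      }
      rx /= npos; ry /= npos; rz /= npos;
      auto EV = [&](int i, int j) {
        return edge_vertex(px[id[i]], py[id[i]], pz[id[i]], fv[id[i]],
                           px[id[j]], py[id[j]], pz[id[j]], fv[id[j]]);
      };
      if (npos == 1 || npos == 3) {
        int lone = -1;
        for (int j = 0; j < 4; ++j) if (pos[j] == (npos == 1)) lone = j;
        int o[3], m = 0;
        for (int j = 0; j < 4; ++j) if (j != lone) o[m++] = j;
        int e0 = EV(lone, o[0]), e1 = EV(lone, o[1]), e2 = EV(lone, o[2]);
        emit(e0, e1, e2, rx, ry, rz);
      } else {
        int p[2], nn[2], mp = 0, mn = 0;
        for (int j = 0; j < 4; ++j) { if (pos[j]) p[mp++] = j; else nn[mn++] = j; }
        int e00 = EV(p[0], nn[0]), e01 = EV(p[0], nn[1]);
        int e11 = EV(p[1], nn[1]), e10 = EV(p[1], nn[0]);
        emit(e00, e01, e11, rx, ry, rz);
        emit(e00, e11, e10, rx, ry, rz);
      }
    }
  }
  int nv = (int)(verts.size() / 3), nf = (int)(faces.size() / 3);
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) { V(i,0) = verts[3*i]; V(i,1) = verts[3*i+1]; V(i,2) = verts[3*i+2]; }
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) { F(i,0) = faces[3*i] + 1; F(i,1) = faces[3*i+1] + 1; F(i,2) = faces[3*i+2] + 1; }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---------------------------------------------------------------------------
// Mesh voxelization by ray parity: voxel centre is inside iff a +x ray
// crosses the surface an odd number of times.  Triangles are binned on a
// (y,z) grid so each ray only tests nearby triangles.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_voxelize(NumericMatrix V, IntegerMatrix F, IntegerVector dims,
                           NumericVector spacing, NumericVector origin) {
  int X = dims[0], Y = dims[1], Z = dims[2];
  int nf = F.nrow();
  LogicalVector out((R_xlen_t)X * Y * Z);
  out.attr("dim") = dims;
  // deterministic sub-voxel jitter avoids rays through edges/vertices
  const double jy = 0.5 * 1e-3 * spacing[1], jz = 0.5 * 1.7e-3 * spacing[2];
  std::vector<std::vector<int>> bins((size_t)Y * Z);
  for (int f = 0; f < nf; ++f) {
    double ys[3], zs[3];
    for (int j = 0; j < 3; ++j) { ys[j] = V(F(f,j)-1, 1); zs[j] = V(F(f,j)-1, 2); }
    double ymin = std::min({ys[0],ys[1],ys[2]}), ymax = std::max({ys[0],ys[1],ys[2]});
    double zmin = std::min({zs[0],zs[1],zs[2]}), zmax = std::max({zs[0],zs[1],zs[2]});
    int jy0 = std::max(0, (int)std::floor((ymin - origin[1] - jy) / spacing[1]));
    int jy1 = std::min(Y - 1, (int)std::ceil((ymax - origin[1] - jy) / spacing[1]));
    int jz0 = std::max(0, (int)std::floor((zmin - origin[2] - jz) / spacing[2]));
    int jz1 = std::min(Z - 1, (int)std::ceil((zmax - origin[2] - jz) / spacing[2]));
    for (int zz = jz0; zz <= jz1; ++zz) for (int yy = jy0; yy <= jy1; ++yy)
      bins[(size_t)yy + (size_t)Y * zz].push_back(f);
  }
  std::vector<double> xs;
  for (int z = 0; z < Z; ++z) for (int y = 0; y < Y; ++y) {
    const std::vector<int>& cand = bins[(size_t)y + (size_t)Y * z];
    if (cand.empty()) continue;
    double ry = origin[1] + spacing[1] * y + jy;
    double rz = origin[2] + spacing[2] * z + jz;
    xs.clear();
    for (int f : cand) {
      double p[3][3];
      for (int j = 0; j < 3; ++j) for (int k = 0; k < 3; ++k) p[j][k] = V(F(f,j)-1, k);
      // 2D point-in-triangle in (y,z); then x of the intersection
      double d = (p[1][1]-p[0][1])*(p[2][2]-p[0][2]) - (p[2][1]-p[0][1])*(p[1][2]-p[0][2]);
      if (d == 0) continue;
      double l1 = ((ry-p[0][1])*(p[2][2]-p[0][2]) - (p[2][1]-p[0][1])*(rz-p[0][2])) / d;
      double l2 = ((p[1][1]-p[0][1])*(rz-p[0][2]) - (ry-p[0][1])*(p[1][2]-p[0][2])) / d;
      if (l1 < 0 || l2 < 0 || l1 + l2 > 1) continue;
      xs.push_back(p[0][0] + l1*(p[1][0]-p[0][0]) + l2*(p[2][0]-p[0][0]));
    }
    if (xs.empty()) continue;
    std::sort(xs.begin(), xs.end());
    // walk voxel centres; inside between odd/even crossings
    size_t k = 0; bool inside = false;
    for (int x = 0; x < X; ++x) {
      double rx = origin[0] + spacing[0] * x;
      while (k < xs.size() && xs[k] < rx) { inside = !inside; ++k; }
      if (inside) out[idx3(x, y, z, X, Y)] = true;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Point-set distances
// ---------------------------------------------------------------------------

// directed Hausdorff sup_a inf_b ||a-b|| with early termination
// [[Rcpp::export]]
double cpp_hausdorff_directed(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nb = B.nrow();
  double best = 0.0;
  for (int i = 0; i < na; ++i) {
    double ax = A(i,0), ay = A(i,1), az = A(i,2);
    double mind = HUGE_VAL;
    for (int j = 0; j < nb; ++j) {
      double dx = ax - B(j,0), dy = ay - B(j,1), dz = az - B(j,2);
      double d = dx*dx + dy*dy + dz*dz;
      if (d < mind) { mind = d; if (mind <= best) break; }
    }
    if (mind > best) best = mind;
  }
  return std::sqrt(best);
}

// index (1-based) of the nearest point in B for every point of A
// [[Rcpp::export]]
IntegerVector cpp_nn_index(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nb = B.nrow();
  IntegerVector out(na);
  for (int i = 0; i < na; ++i) {
    double ax = A(i,0), ay = A(i,1), az = A(i,2);
    double mind = HUGE_VAL; int bi = 1;
    for (int j = 0; j < nb; ++j) {
      double dx = ax - B(j,0), dy = ay - B(j,1), dz = az - B(j,2);
      double d = dx*dx + dy*dy + dz*dz;
      if (d < mind) { mind = d; bi = j + 1; }
    }
    out[i] = bi;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Slice-wise 2D median filter with square window (2r+1)^2, border clamped.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_median2d_stack(NumericVector x, IntegerVector dims, int r) {
  int X = dims[0], Y = dims[1], Z = dims[2];
  NumericVector out(x.size());
  out.attr("dim") = dims;
  std::vector<double> buf((2*r+1)*(2*r+1));
  for (int z = 0; z < Z; ++z) {
    const double* xz = x.begin() + (R_xlen_t)X * Y * z;
    double* oz = out.begin() + (R_xlen_t)X * Y * z;
    for (int y = 0; y < Y; ++y) for (int xx = 0; xx < X; ++xx) {
      int m = 0;
      for (int dy = -r; dy <= r; ++dy) for (int dx = -r; dx <= r; ++dx) {
        int nx = std::min(std::max(xx + dx, 0), X - 1);
        int ny = std::min(std::max(y + dy, 0), Y - 1);
        buf[m++] = xz[nx + (R_xlen_t)X * ny];
      }
      std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
      double med = buf[m / 2];
      if (m % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + m / 2 - 1, buf.begin() + m);
        med = 0.5 * (med + buf[m / 2 - 1]);
      }
      oz[xx + (R_xlen_t)X * y] = med;
    }
  }
  return out;
}
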