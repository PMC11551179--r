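// Voxel kernels: exact Euclidean distance transform (separable parabolic
// envelopes), distance-ordered homotopic thinning to a curve skeleton, and
// 26-connected component labelling.  Arrays are [z, x, y] column-major as
// passed from R; indices here are 0-based.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// large finite sentinel keeps the parabola envelope well defined
static const double INF = 1e20;

// 1-d squared distance transform (Felzenszwalb & Huttenlocher) with
// sample spacing h.
static void dt1d(std::vector<double>& f, std::vector<double>& d, double h) {
  int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  double h2 = h * h;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double fq = f[q], fv = f[v[k]];
      s = ((fq + h2 * q * q) - (fv + h2 * v[k] * v[k])) /
          (2.0 * h2 * (q - v[k]));
      if (s <= z[k] && k > 0) { --k; } else break;
    }
    if (s <= z[k]) { v[k] = q; z[k + 1] = INF; }
    else { ++k; v[k] = q; z[k] = s; z[k + 1] = INF; }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = h2 * dq * dq + f[v[k]];
  }
  f = d;
}

// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector mask, IntegerVector dim,
                    NumericVector spacing) {
  int nz = dim[0], nx = dim[1], ny = dim[2];
  R_xlen_t n = (R_xlen_t)nz * nx * ny;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? INF : 0.0;
  std::vector<double> f, d;
  // along z
  f.resize(nz); d.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)nz * (x + (R_xlen_t)nx * y);
      for (int z = 0; z < nz; ++z) f[z] = out[base + z];
      dt1d(f, d, spacing[0]);
      for (int z = 0; z < nz; ++z) out[base + z] = f[z];
    }
  // along x
  f.resize(nx); d.resize(nx);
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      for (int x = 0; x < nx; ++x)
        f[x] = out[z + (R_xlen_t)nz * (x + (R_xlen_t)nx * y)];
      dt1d(f, d, spacing[1]);
      for (int x = 0; x < nx; ++x)
        out[z + (R_xlen_t)nz * (x + (R_xlen_t)nx * y)] = f[x];
    }
  // along y
  f.resize(ny); d.resize(ny);
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y)
        f[y] = out[z + (R_xlen_t)nz * (x + (R_xlen_t)nx * y)];
      dt1d(f, d, spacing[2]);
      for (int y = 0; y < ny; ++y)
        out[z + (R_xlen_t)nz * (x + (R_xlen_t)nx * y)] = std::sqrt(f[y]);
    }
  return out;
}

struct Vol {
  const int nz, nx, ny;
  std::vector<char> v;
  Vol(int nz_, int nx_, int ny_) : nz(nz_), nx(nx_), ny(ny_),
    v((size_t)nz_ * nx_ * ny_, 0) {}
  inline bool get(int z, int x, int y) const {
    if (z < 0 || x < 0 || y < 0 || z >= nz || x >= nx || y >= ny)
      return false;
    return v[(size_t)z + (size_t)nz * (x + (size_t)nx * y)] != 0;
  }
  inline void set(int z, int x, int y, bool b) {
    v[(size_t)z + (size_t)nz * (x + (size_t)nx * y)] = b ? 1 : 0;
  }
};

// number of foreground 26-neighbours
static int n26(const Vol& V, int z, int x, int y) {
  int c = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        if (!dz && !dx && !dy) continue;
        if (V.get(z + dz, x + dx, y + dy)) ++c;
      }
  return c;
}

// topological characterization (Bertrand & Malandain): a voxel is simple
// iff it has exactly one 26-connected foreground component in its
// 26-neighbourhood and exactly one 6-connected background component in
// its 18-neighbourhood that is 6-adjacent to the voxel.
static bool isSimple(const Vol& V, int z, int x, int y) {
  // local 3x3x3 snapshot, center removed
  bool fg[3][3][3];
  for (int dz = -1; dz <= 1; ++dz)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        fg[dz + 1][dx + 1][dy + 1] = V.get(z + dz, x + dx, y + dy);
  fg[1][1][1] = false;

  // count 26-components of foreground among the 26 neighbours
  bool seen[3][3][3] = {{{false}}};
  int ncomp = 0;
  for (int i = 0; i < 27; ++i) {
    int dz = i % 3, dx = (i / 3) % 3, dy = i / 9;
    if (!fg[dz][dx][dy] || seen[dz][dx][dy]) continue;
    ++ncomp;
    if (ncomp > 1) return false;
    std::queue<int> q; q.push(i); seen[dz][dx][dy] = true;
    while (!q.empty()) {
      int j = q.front(); q.pop();
      int jz = j % 3, jx = (j / 3) % 3, jy = j / 9;
      for (int az = -1; az <= 1; ++az)
        for (int ax = -1; ax <= 1; ++ax)
          for (int ay = -1; ay <= 1; ++ay) {
            int kz = jz + az, kx = jx + ax, ky = jy + ay;
            if (kz < 0 || kx < 0 || ky < 0 || kz > 2 || kx > 2 || ky > 2)
              continue;
            if (fg[kz][kx][ky] && !seen[kz][kx][ky]) {
              seen[kz][kx][ky] = true;
              q.push(kz + 3 * (kx + 3 * ky));
            }
          }
    }
  }
  if (ncomp != 1) return false;

  // 6-components of background within the 18-neighbourhood (face + edge
  // neighbours), counted only if they contain a face neighbour of the
  // center; 6-connectivity is evaluated inside the 18-set.
  auto in18 = [](int dz, int dx, int dy) {
    int a = std::abs(dz - 1) + std::abs(dx - 1) + std::abs(dy - 1);
    return a >= 1 && a <= 2;
  };
  bool seen6[3][3][3] = {{{false}}};
  int nbg = 0;
  static const int F[6][3] = {{1,1,0},{1,1,2},{1,0,1},{1,2,1},{0,1,1},{2,1,1}};
  for (int fi = 0; fi < 6; ++fi) {
    int dz = F[fi][0], dx = F[fi][1], dy = F[fi][2];
    if (fg[dz][dx][dy] || seen6[dz][dx][dy]) continue;
    ++nbg;
    if (nbg > 1) return false;
    std::queue<int> q; q.push(dz + 3 * (dx + 3 * dy));
    seen6[dz][dx][dy] = true;
    while (!q.empty()) {
      int j = q.front(); q.pop();
      int jz = j % 3, jx = (j / 3) % 3, jy = j / 9;
      static const int D[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},
                                  {0,0,1},{0,0,-1}};
      for (int a = 0; a < 6; ++a) {
        int kz = jz + D[a][0], kx = jx + D[a][1], ky = jy + D[a][2];
        if (kz < 0 || kx < 0 || ky < 0 || kz > 2 || kx > 2 || ky > 2)
          continue;
        if (!in18(kz, kx, ky)) continue;
        if (!fg[kz][kx][ky] && !seen6[kz][kx][ky]) {
          seen6[kz][kx][ky] = true;
          q.push(kz + 3 * (kx + 3 * ky));
        }
      }
    }
  }
  return nbg == 1;
}

// [[Rcpp::export(name = ".thin3d")]]
LogicalVector thin3d(LogicalVector mask, IntegerVector dim,
                     NumericVector priority) {
  int nz = dim[0], nx = dim[1], ny = dim[2];
  Vol V(nz, nx, ny);
  R_xlen_t n = (R_xlen_t)nz * nx * ny;
  std::vector<R_xlen_t> idx;
  for (R_xlen_t i = 0; i < n; ++i)
    if (mask[i]) { V.v[i] = 1; idx.push_back(i); }
  // deterministic processing order: ascending priority, ties by index
  std::stable_sort(idx.begin(), idx.end(), [&](R_xlen_t a, R_xlen_t b) {
    return priority[a] < priority[b];
  });
  bool changed = true;
  while (changed) {
    changed = false;
    for (R_xlen_t i : idx) {
      if (!V.v[i]) continue;
      int z = (int)(i % nz);
      int x = (int)((i / nz) % nx);
      int y = (int)(i / ((R_xlen_t)nz * nx));
      int nb = n26(V, z, x, y);
      if (nb <= 1) continue;               // endpoint: preserve curve ends
      if (isSimple(V, z, x, y)) {
        V.v[i] = 0;
        changed = true;
      }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = V.v[i] != 0;
  return out;
}

// [[Rcpp::export(name = ".cc26")]]
IntegerVector cc26(LogicalVector mask, IntegerVector dim) {
  int nz = dim[0], nx = dim[1], ny = dim[2];
  R_xlen_t n = (R_xlen_t)nz * nx * ny;
  IntegerVector lab(n, 0);
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++cur;
    stack.push_back(i); lab[i] = cur;
    while (!stack.empty()) {
      R_xlen_t j = stack.back(); stack.pop_back();
      int z = (int)(j % nz);
      int x = (int)((j / nz) % nx);
      int y = (int)(j / ((R_xlen_t)nz * nx));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy) {
            if (!dz && !dx && !dy) continue;
            int zz = z + dz, xx = x + dx, yy = y + dy;
            if (zz < 0 || xx < 0 || yy < 0 || zz >= nz || xx >= nx ||
                yy >= ny) continue;
            R_xlen_t k = zz + (R_xlen_t)nz * (xx + (R_xlen_t)nx * yy);
            if (mask[k] && !lab[k]) { lab[k] = cur; stack.push_back(k); }
          }
    }
  }
  return lab;
}

// count of foreground 26-neighbours for every voxel of a mask, used to
// classify skeleton voxels into endpoints / chain / junction voxels.
// [[Rcpp::export(name = ".neighborCount26")]]
IntegerVector neighborCount26(LogicalVector mask, IntegerVector dim) {
  int nz = dim[0], nx = dim[1], ny = dim[2];
  Vol V(nz, nx, ny);
  R_xlen_t n = (R_xlen_t)nz * nx * ny;
  for (R_xlen_t i = 0; i < n; ++i) if (mask[i]) V.v[i] = 1;
  IntegerVector out(n, 0);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int z = (int)(i % nz);
    int x = (int)((i / nz) % nx);
    int y = (int)(i / ((R_xlen_t)nz * nx));
    out[i] = n26(V, z, x, y);
  }
  return out;
}
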