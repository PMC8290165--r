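#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Volumes are R arrays with dim = c(nx, ny, nz), x fastest (column-major).
// All kernels below use 0-based linear index i = x + nx*(y + ny*z).

static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * (long)z);
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur, reflecting boundary. sigma in voxels.
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur3d(NumericVector vol, IntegerVector dim,
                                  double sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  if (sigma <= 0) return clone(vol);
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &w : k) w /= s;

  std::vector<double> a(vol.begin(), vol.end()), b(a.size());

  // reflect index into [0, n-1]
  auto refl = [](int i, int n) {
    while (i < 0 || i >= n) {
      if (i < 0) i = -i - 1;
      if (i >= n) i = 2 * n - i - 1;
    }
    return i;
  };

  // pass along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double acc = 0;
        for (int i = -r; i <= r; ++i)
          acc += k[i + r] * a[lin(refl(x + i, nx), y, z, nx, ny)];
        b[lin(x, y, z, nx, ny)] = acc;
      }
  std::swap(a, b);
  // pass along y
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double acc = 0;
        for (int i = -r; i <= r; ++i)
          acc += k[i + r] * a[lin(x, refl(y + i, ny), z, nx, ny)];
        b[lin(x, y, z, nx, ny)] = acc;
      }
  std::swap(a, b);
  // pass along z
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double acc = 0;
        for (int i = -r; i <= r; ++i)
          acc += k[i + r] * a[lin(x, y, refl(z + i, nz), nx, ny)];
        b[lin(x, y, z, nx, ny)] = acc;
      }

  NumericVector out(vol.size());
  std::copy(b.begin(), b.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labeling; connectivity 6 or 26. 0 = background.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim,
                          int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = mask.size();
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<int> q;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || lab[start]) continue;
    lab[start] = ++next;
    q.push((int)start);
    while (!q.empty()) {
      int cur = q.front();
      q.pop();
      int x = cur % nx, y = (cur / nx) % ny, z = cur / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
            if (connectivity == 6 && man != 1) continue;
            int X = x + dx, Y = y + dy, Z = z + dz;
            if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz)
              continue;
            int idx = lin(X, Y, Z, nx, ny);
            if (mask[idx] && !lab[idx]) {
              lab[idx] = next;
              q.push(idx);
            }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// ---------------------------------------------------------------------------
// Binary dilation with the full 26-neighborhood structuring element, iterated.
// [[Rcpp::export]]
LogicalVector cpp_dilate3d(LogicalVector mask, IntegerVector dim, int iters) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<char> a(mask.begin(), mask.end()), b(a.size());
  for (int it = 0; it < iters; ++it) {
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          char v = a[lin(x, y, z, nx, ny)];
          if (!v) {
            for (int dz = -1; dz <= 1 && !v; ++dz)
              for (int dy = -1; dy <= 1 && !v; ++dy)
                for (int dx = -1; dx <= 1 && !v; ++dx) {
                  int X = x + dx, Y = y + dy, Z = z + dz;
                  if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 ||
                      Z >= nz)
                    continue;
                  if (a[lin(X, Y, Z, nx, ny)]) v = 1;
                }
          }
          b[lin(x, y, z, nx, ny)] = v;
        }
    std::swap(a, b);
  }
  LogicalVector out(mask.size());
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Count foreground 26-neighbors of every voxel.
// [[Rcpp::export]]
IntegerVector cpp_count_neighbors26(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector out(mask.size(), 0);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int X = x + dx, Y = y + dy, Z = z + dz;
              if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz)
                continue;
              if (mask[lin(X, Y, Z, nx, ny)]) ++cnt;
            }
        out[lin(x, y, z, nx, ny)] = cnt;
      }
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Simple-point test for (26, 6) digital topology.
// nb: 27 flags of the 3x3x3 cube, index dx+1 + 3*(dy+1) + 9*(dz+1); center 13.
// Condition A: exactly one 26-component of foreground among the 26 neighbors.
// Condition B: exactly one 6-component of background within the
//              18-neighborhood that touches a face neighbor of the center.
static bool simple_point(const char nb[27]) {
  // A: 26-components of foreground in the 26-neighborhood
  {
    char seen[27] = {0};
    int ncomp = 0;
    for (int i = 0; i < 27; ++i) {
      if (i == 13 || !nb[i] || seen[i]) continue;
      ++ncomp;
      if (ncomp > 1) return false;
      // BFS over cube positions
      int stack[27], top = 0;
      stack[top++] = i;
      seen[i] = 1;
      while (top) {
        int cur = stack[--top];
        int cx = cur % 3, cy = (cur / 3) % 3, cz = cur / 9;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int X = cx + dx, Y = cy + dy, Z = cz + dz;
              if (X < 0 || X > 2 || Y < 0 || Y > 2 || Z < 0 || Z > 2) continue;
              int j = X + 3 * Y + 9 * Z;
              if (j == 13 || !nb[j] || seen[j]) continue;
              seen[j] = 1;
              stack[top++] = j;
            }
      }
    }
    if (ncomp != 1) return false; // isolated point is not simple
  }
  // B: 6-components of background in the 18-neighborhood adjacent to center
  {
    // 18-neighborhood: |dx|+|dy|+|dz| in {1,2} excluding the 8 corners
    char seen[27] = {0};
    int ncomp = 0;
    for (int i = 0; i < 27; ++i) {
      int cx = i % 3 - 1, cy = (i / 3) % 3 - 1, cz = i / 9 - 1;
      int man = std::abs(cx) + std::abs(cy) + std::abs(cz);
      if (man != 1) continue; // start BFS only from face neighbors
      if (nb[i] || seen[i]) continue;
      ++ncomp;
      if (ncomp > 1) return false;
      int stack[27], top = 0;
      stack[top++] = i;
      seen[i] = 1;
      while (top) {
        int cur = stack[--top];
        int px = cur % 3 - 1, py = (cur / 3) % 3 - 1, pz = cur / 9 - 1;
        const int d6[6][3] = {{1, 0, 0}, {-1, 0, 0}, {0, 1, 0},
                              {0, -1, 0}, {0, 0, 1}, {0, 0, -1}};
        for (auto &d : d6) {
          int X = px + d[0], Y = py + d[1], Z = pz + d[2];
          if (X < -1 || X > 1 || Y < -1 || Y > 1 || Z < -1 || Z > 1) continue;
          int man2 = std::abs(X) + std::abs(Y) + std::abs(Z);
          if (man2 == 0 || man2 == 3) continue; // center or corner: not in N18
          int j = (X + 1) + 3 * (Y + 1) + 9 * (Z + 1);
          if (nb[j] || seen[j]) continue;
          seen[j] = 1;
          stack[top++] = j;
        }
      }
    }
    if (ncomp != 1) return false;
  }
  return true;
}

static inline void fill_nb(const std::vector<char> &a, int x, int y, int z,
                           int nx, int ny, int nz, char nb[27]) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int X = x + dx, Y = y + dy, Z = z + dz;
        char v = 0;
        if (X >= 0 && X < nx && Y >= 0 && Y < ny && Z >= 0 && Z < nz)
          v = a[lin(X, Y, Z, nx, ny)];
        nb[(dx + 1) + 3 * (dy + 1) + 9 * (dz + 1)] = v;
      }
}

static inline int count26(const char nb[27]) {
  int c = 0;
  for (int i = 0; i < 27; ++i)
    if (i != 13 && nb[i]) ++c;
  return c;
}

// ---------------------------------------------------------------------------
// Topology-preserving curve thinning for (26, 6) connectivity.
// Six directional subiterations; border points that are simple and not curve
// endpoints (<= 1 foreground 26-neighbor) are deleted sequentially, with the
// simple-point test re-evaluated at deletion time, until a fixed point.
// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<char> a(mask.begin(), mask.end());
  // active voxel list to avoid full scans
  std::vector<int> fg;
  for (R_xlen_t i = 0; i < mask.size(); ++i)
    if (a[i]) fg.push_back((int)i);

  const int dirs[6][3] = {{0, 0, -1}, {0, 0, 1}, {0, -1, 0},
                          {0, 1, 0},  {-1, 0, 0}, {1, 0, 0}};
  char nb[27];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      std::vector<int> cand;
      for (int idx : fg) {
        if (!a[idx]) continue;
        int x = idx % nx, y = (idx / nx) % ny, z = idx / (nx * ny);
        int X = x + dirs[d][0], Y = y + dirs[d][1], Z = z + dirs[d][2];
        bool border = true;
        if (X >= 0 && X < nx && Y >= 0 && Y < ny && Z >= 0 && Z < nz)
          border = !a[lin(X, Y, Z, nx, ny)];
        else
          border = false; // volume faces are not deletion borders
        if (!border) continue;
        fill_nb(a, x, y, z, nx, ny, nz, nb);
        if (count26(nb) <= 1) continue; // endpoint or isolated
        if (simple_point(nb)) cand.push_back(idx);
      }
      for (int idx : cand) {
        int x = idx % nx, y = (idx / nx) % ny, z = idx / (nx * ny);
        fill_nb(a, x, y, z, nx, ny, nz, nb);
        if (count26(nb) <= 1) continue;
        if (!simple_point(nb)) continue;
        a[idx] = 0;
        changed = true;
      }
    }
    if (changed) {
      // compact the active list
      std::vector<int> keep;
      keep.reserve(fg.size());
      for (int idx : fg)
        if (a[idx]) keep.push_back(idx);
      fg.swap(keep);
    }
  }
  LogicalVector out(mask.size());
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Seeded region growing with a running-mean homogeneity criterion.
// Accepts a voxel iff allowed[i] and |vol[i] - running_mean| <= tol, searching
// the 26-neighborhood from the seeds; the mean is updated as voxels join.
// seeds0: 0-based linear indices.
// [[Rcpp::export]]
LogicalVector cpp_region_grow(NumericVector vol, LogicalVector allowed,
                              IntegerVector dim, IntegerVector seeds0,
                              double tol) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(vol.size(), false);
  std::queue<int> q;
  double sum = 0;
  long cnt = 0;
  for (int s : seeds0) {
    if (s < 0 || s >= (int)vol.size() || out[s]) continue;
    out[s] = true;
    sum += vol[s];
    ++cnt;
    q.push(s);
  }
  while (!q.empty()) {
    int cur = q.front();
    q.pop();
    int x = cur % nx, y = (cur / nx) % ny, z = cur / (nx * ny);
    double mean = sum / cnt;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int X = x + dx, Y = y + dy, Z = z + dz;
          if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz)
            continue;
          int idx = lin(X, Y, Z, nx, ny);
          if (out[idx] || !allowed[idx]) continue;
          if (std::fabs(vol[idx] - mean) <= tol) {
            out[idx] = true;
            sum += vol[idx];
            ++cnt;
            q.push(idx);
          }
        }
  }
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Eigenvalues of a symmetric 3x3 matrix field, sorted by |lambda| ascending.
// [[Rcpp::export]]
List cpp_hessian_eigen(NumericVector xx, NumericVector yy, NumericVector zz,
                       NumericVector xy, NumericVector xz, NumericVector yz) {
  const R_xlen_t n = xx.size();
  NumericVector l1(n), l2(n), l3(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double a11 = xx[i], a22 = yy[i], a33 = zz[i];
    double a12 = xy[i], a13 = xz[i], a23 = yz[i];
    double q = (a11 + a22 + a33) / 3.0;
    double b11 = a11 - q, b22 = a22 - q, b33 = a33 - q;
    double p2 = (b11 * b11 + b22 * b22 + b33 * b33 +
                 2.0 * (a12 * a12 + a13 * a13 + a23 * a23)) / 6.0;
    double e[3];
    if (p2 < 1e-300) {
      e[0] = e[1] = e[2] = q;
    } else {
      double p = std::sqrt(p2);
      double detB = b11 * (b22 * b33 - a23 * a23) -
                    a12 * (a12 * b33 - a23 * a13) +
                    a13 * (a12 * a23 - b22 * a13);
      double r = detB / (2.0 * p * p * p);
      r = std::max(-1.0, std::min(1.0, r));
      double phi = std::acos(r) / 3.0;
      e[0] = q + 2.0 * p * std::cos(phi);
      e[2] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
      e[1] = 3.0 * q - e[0] - e[2];
    }
    // sort by |.| ascending
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2 - a; ++b)
        if (std::fabs(e[b]) > std::fabs(e[b + 1])) std::swap(e[b], e[b + 1]);
    l1[i] = e[0]; l2[i] = e[1]; l3[i] = e[2];
  }
  return List::create(_["l1"] = l1, _["l2"] = l2, _["l3"] = l3);
}
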