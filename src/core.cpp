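#include <Rcpp.h>
#include <vector>
#include <map>
#include <tuple>
#include <functional>
#include <cmath>
using namespace Rcpp;

// Arrays follow R's column-major layout with dim = (nz, ny, nx):
// linear index i = z + nz * (y + ny * x).

static inline int reflect_index(int i, int n) {
  // half-sample symmetric reflection: ... b a | a b c | c b ...
  if (n == 1) return 0;
  int period = 2 * n;
  i = ((i % period) + period) % period;
  return (i < n) ? i : (period - 1 - i);
}

// Convolve along one axis (0 = z, 1 = y, 2 = x) with reflective padding.
// Kernel is centered; length must be odd. Axes 1/2 use an axpy layout so
// the inner loop runs stride-1 along z.
static void conv_axis(const std::vector<double>& in, std::vector<double>& out,
                      int nz, int ny, int nx, const NumericVector& k, int axis) {
  int kl = k.size();
  int kc = kl / 2;
  int n = (axis == 0) ? nz : (axis == 1) ? ny : nx;
  // source-position table: src[pos * kl + t]
  std::vector<int> src((size_t)n * kl);
  for (int pos = 0; pos < n; ++pos)
    for (int t = 0; t < kl; ++t)
      src[(size_t)pos * kl + t] = reflect_index(pos + t - kc, n);
  if (axis == 0) {
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        size_t base = (size_t)nz * (y + (size_t)ny * x);
        for (int z = 0; z < nz; ++z) {
          const int* s = &src[(size_t)z * kl];
          double acc = 0.0;
          for (int t = 0; t < kl; ++t) acc += k[t] * in[base + s[t]];
          out[base + z] = acc;
        }
      }
  } else {
    std::fill(out.begin(), out.end(), 0.0);
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        int pos = (axis == 1) ? y : x;
        size_t obase = (size_t)nz * (y + (size_t)ny * x);
        const int* s = &src[(size_t)pos * kl];
        for (int t = 0; t < kl; ++t) {
          size_t ibase = (axis == 1)
            ? (size_t)nz * (s[t] + (size_t)ny * x)
            : (size_t)nz * (y + (size_t)ny * s[t]);
          double w = k[t];
          for (int z = 0; z < nz; ++z) out[obase + z] += w * in[ibase + z];
        }
      }
  }
}

// [[Rcpp::export(name = ".conv_sep_reflect")]]
NumericVector conv_sep_reflect(NumericVector x, IntegerVector dims, List kernels) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  size_t n = (size_t)nz * ny * nx;
  std::vector<double> a(x.begin(), x.end()), b(n);
  for (int axis = 0; axis < 3; ++axis) {
    NumericVector k = kernels[axis];
    if (k.size() == 1) {
      for (size_t i = 0; i < n; ++i) a[i] *= k[0];
      continue;
    }
    conv_axis(a, b, nz, ny, nx, k, axis);
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}

// Dense 3D convolution with a small centered kernel, reflective padding.
// [[Rcpp::export(name = ".conv3d_reflect")]]
NumericVector conv3d_reflect(NumericVector x, IntegerVector dims,
                             NumericVector kern, IntegerVector kdims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  int kz = kdims[0], ky = kdims[1], kx = kdims[2];
  int cz = kz / 2, cy = ky / 2, cx = kx / 2;
  NumericVector out((size_t)nz * ny * nx);
  for (int X = 0; X < nx; ++X)
    for (int Y = 0; Y < ny; ++Y)
      for (int Z = 0; Z < nz; ++Z) {
        double acc = 0.0;
        for (int a = 0; a < kx; ++a) {
          int xx = reflect_index(X + a - cx, nx);
          for (int b = 0; b < ky; ++b) {
            int yy = reflect_index(Y + b - cy, ny);
            for (int c = 0; c < kz; ++c) {
              int zz = reflect_index(Z + c - cz, nz);
              acc += kern[c + (size_t)kz * (b + (size_t)ky * a)] *
                     x[zz + (size_t)nz * (yy + (size_t)ny * xx)];
            }
          }
        }
        out[Z + (size_t)nz * (Y + (size_t)ny * X)] = acc;
      }
  out.attr("dim") = dims;
  return out;
}

// Connected-component labelling of a logical mask, 6- or 26-connectivity.
// Returns integer labels (0 = background), BFS with an explicit queue.
// [[Rcpp::export(name = ".cc_label3d")]]
IntegerVector cc_label3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  size_t n = (size_t)nz * ny * nx;
  IntegerVector labels(n, 0);
  std::vector<int> offs_z, offs_y, offs_x;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs_z.push_back(dz); offs_y.push_back(dy); offs_x.push_back(dx);
      }
  int nb = offs_z.size();
  std::vector<size_t> queue;
  int next_label = 0;
  for (size_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++next_label;
    labels[start] = next_label;
    queue.clear();
    queue.push_back(start);
    while (!queue.empty()) {
      size_t cur = queue.back();
      queue.pop_back();
      int z = cur % nz;
      int y = (cur / nz) % ny;
      int x = cur / ((size_t)nz * ny);
      for (int j = 0; j < nb; ++j) {
        int zz = z + offs_z[j], yy = y + offs_y[j], xx = x + offs_x[j];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        size_t idx = zz + (size_t)nz * (yy + (size_t)ny * xx);
        if (mask[idx] && labels[idx] == 0) {
          labels[idx] = next_label;
          queue.push_back(idx);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}

// Per-label voxel counts and centroid sums (0-based voxel indices).
// Returns a matrix [nlabel x 4]: count, sum_z, sum_y, sum_x.
// [[Rcpp::export(name = ".region_stats")]]
NumericMatrix region_stats(IntegerVector labels, IntegerVector dims, int nlabel) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  NumericMatrix out(nlabel, 4);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int l = labels[z + (size_t)nz * (y + (size_t)ny * x)];
        if (l > 0) {
          out(l - 1, 0) += 1.0;
          out(l - 1, 1) += z;
          out(l - 1, 2) += y;
          out(l - 1, 3) += x;
        }
      }
  return out;
}

// Single-linkage grouping of 3D points: edge iff distance < link (strict).
// Cell-grid accelerated union-find; returns 1-based component ids.
// [[Rcpp::export(name = ".link_components")]]
IntegerVector link_components(NumericMatrix pts, double link) {
  int n = pts.nrow();
  IntegerVector comp(n);
  if (n == 0) return comp;
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int i) {
    while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
    return i;
  };
  // hash points into cells of side `link`
  double minz = R_PosInf, miny = R_PosInf, minx = R_PosInf;
  for (int i = 0; i < n; ++i) {
    minz = std::min(minz, pts(i, 0));
    miny = std::min(miny, pts(i, 1));
    minx = std::min(minx, pts(i, 2));
  }
  double cell = (link > 0) ? link : 1.0;
  std::map<std::tuple<int,int,int>, std::vector<int> > grid;
  std::vector<std::tuple<int,int,int> > key(n);
  for (int i = 0; i < n; ++i) {
    key[i] = std::make_tuple((int)std::floor((pts(i,0) - minz) / cell),
                             (int)std::floor((pts(i,1) - miny) / cell),
                             (int)std::floor((pts(i,2) - minx) / cell));
    grid[key[i]].push_back(i);
  }
  double link2 = link * link;
  for (int i = 0; i < n; ++i) {
    int kz = std::get<0>(key[i]), ky = std::get<1>(key[i]), kx = std::get<2>(key[i]);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          auto it = grid.find(std::make_tuple(kz + dz, ky + dy, kx + dx));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            if (j <= i) continue;
            double a = pts(i,0) - pts(j,0), b = pts(i,1) - pts(j,1),
                   c = pts(i,2) - pts(j,2);
            if (a*a + b*b + c*c < link2) {
              int ri = find(i), rj = find(j);
              if (ri != rj) parent[ri] = rj;
            }
          }
        }
  }
  std::map<int,int> relabel;
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    auto it = relabel.find(r);
    if (it == relabel.end()) { int id = relabel.size() + 1; relabel[r] = id; }
  }
  for (int i = 0; i < n; ++i) comp[i] = relabel[find(i)];
  return comp;
}

// Hard-core (minimum-separation) sequential sampling inside a box.
// Uses R's RNG so set.seed() governs reproducibility. Returns an
// n_placed x 3 matrix; stops early and signals via attr "failed" when the
// retry cap is exhausted.
// [[Rcpp::export(name = ".hardcore_sample")]]
NumericMatrix hardcore_sample(int n_target, NumericVector lo, NumericVector hi,
                              double min_sep, int max_tries) {
  RNGScope scope;
  std::vector<double> pz, py, px;
  pz.reserve(n_target); py.reserve(n_target); px.reserve(n_target);
  double cell = (min_sep > 0) ? min_sep : (hi[0] - lo[0] + 1.0);
  std::map<std::tuple<int,int,int>, std::vector<int> > grid;
  double sep2 = min_sep * min_sep;
  int tries = 0;
  bool failed = false;
  while ((int)pz.size() < n_target) {
    if (tries++ >= max_tries) { failed = true; break; }
    double z = lo[0] + unif_rand() * (hi[0] - lo[0]);
    double y = lo[1] + unif_rand() * (hi[1] - lo[1]);
    double x = lo[2] + unif_rand() * (hi[2] - lo[2]);
    bool ok = true;
    if (min_sep > 0) {
      int kz = (int)std::floor((z - lo[0]) / cell);
      int ky = (int)std::floor((y - lo[1]) / cell);
      int kx = (int)std::floor((x - lo[2]) / cell);
      for (int dz = -1; dz <= 1 && ok; ++dz)
        for (int dy = -1; dy <= 1 && ok; ++dy)
          for (int dx = -1; dx <= 1 && ok; ++dx) {
            auto it = grid.find(std::make_tuple(kz + dz, ky + dy, kx + dx));
            if (it == grid.end()) continue;
            for (int j : it->second) {
              double a = z - pz[j], b = y - py[j], c = x - px[j];
              if (a*a + b*b + c*c < sep2) { ok = false; break; }
            }
          }
      if (ok) grid[std::make_tuple(kz, ky, kx)].push_back(pz.size());
    }
    if (ok) { pz.push_back(z); py.push_back(y); px.push_back(x); }
  }
  int n = pz.size();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) { out(i,0) = pz[i]; out(i,1) = py[i]; out(i,2) = px[i]; }
  out.attr("failed") = failed;
  return out;
}

// Trilinear resampling from spacing src (dz,dy,dx) to spacing dst.
// Voxel centers sit at (i + 0.5) * spacing; output extent matches input.
// [[Rcpp::export(name = ".trilinear_resample")]]
NumericVector trilinear_resample(NumericVector x, IntegerVector dims,
                                 NumericVector src, NumericVector dst) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  int mz = std::max(1, (int)std::round(nz * src[0] / dst[0]));
  int my = std::max(1, (int)std::round(ny * src[1] / dst[1]));
  int mx = std::max(1, (int)std::round(nx * src[2] / dst[2]));
  NumericVector out((size_t)mz * my * mx);
  for (int X = 0; X < mx; ++X) {
    double fx = ((X + 0.5) * dst[2]) / src[2] - 0.5;
    int x0 = (int)std::floor(fx);
    double wx = fx - x0;
    int xa = std::min(std::max(x0, 0), nx - 1);
    int xb = std::min(std::max(x0 + 1, 0), nx - 1);
    for (int Y = 0; Y < my; ++Y) {
      double fy = ((Y + 0.5) * dst[1]) / src[1] - 0.5;
      int y0 = (int)std::floor(fy);
      double wy = fy - y0;
      int ya = std::min(std::max(y0, 0), ny - 1);
      int yb = std::min(std::max(y0 + 1, 0), ny - 1);
      for (int Z = 0; Z < mz; ++Z) {
        double fz = ((Z + 0.5) * dst[0]) / src[0] - 0.5;
        int z0 = (int)std::floor(fz);
        double wz = fz - z0;
        int za = std::min(std::max(z0, 0), nz - 1);
        int zb = std::min(std::max(z0 + 1, 0), nz - 1);
        #define V(zz, yy, xx) x[(zz) + (size_t)nz * ((yy) + (size_t)ny * (xx))]
        double c00 = V(za, ya, xa) * (1 - wz) + V(zb, ya, xa) * wz;
        double c10 = V(za, yb, xa) * (1 - wz) + V(zb, yb, xa) * wz;
        double c01 = V(za, ya, xb) * (1 - wz) + V(zb, ya, xb) * wz;
        double c11 = V(za, yb, xb) * (1 - wz) + V(zb, yb, xb) * wz;
        #undef V
        double c0 = c00 * (1 - wy) + c10 * wy;
        double c1 = c01 * (1 - wy) + c11 * wy;
        out[Z + (size_t)mz * (Y + (size_t)my * X)] = c0 * (1 - wx) + c1 * wx;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(mz, my, mx);
  return out;
}
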