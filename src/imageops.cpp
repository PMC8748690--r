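// 3D voxel-grid primitives for spheroid segmentation.
// Volumes are passed as numeric/logical vectors in R array order
// (x fastest, then y, then z) with dims = c(nx, ny, nz).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Connected-component labeling, connectivity = 6 or 26.
// [[Rcpp::export(name = ".cpp_label")]]
IntegerVector cpp_label(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  IntegerVector labels(n, 0);
  std::vector<int> stack;
  int next_label = 0;

  for (int start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++next_label;
    labels[start] = next_label;
    stack.push_back(start);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int z = v / (nx * ny), rem = v % (nx * ny);
      int y = rem / nx, x = rem % nx;
      for (int dz = -1; dz <= 1; ++dz) {
        for (int dy = -1; dy <= 1; ++dy) {
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            if (connectivity == 6 && (std::abs(dx) + std::abs(dy) + std::abs(dz)) != 1)
              continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
            int w = idx3(xx, yy, zz, nx, ny);
            if (mask[w] && labels[w] == 0) {
              labels[w] = next_label;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  labels.attr("n_labels") = next_label;
  return labels;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher 2012),
// f in units of squared physical distance, sample spacing `step`.
static void dt1d(std::vector<double>& f, double step) {
  const int n = (int)f.size();
  if (n == 0) return;
  std::vector<int> v(n);
  std::vector<double> zpt(n + 1);
  std::vector<double> d(n);
  int k = 0;
  v[0] = 0;
  zpt[0] = -std::numeric_limits<double>::infinity();
  zpt[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    for (;;) {
      double qq = (double)q * step, vv = (double)v[k] * step;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * qq - 2.0 * vv);
      if (s <= zpt[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zpt[k] = s;
    zpt[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = (double)q * step;
    while (zpt[k + 1] < qq) ++k;
    double diff = qq - (double)v[k] * step;
    d[q] = diff * diff + f[v[k]];
  }
  f = d;
}

// Anisotropic Euclidean distance transform: distance (physical units) from
// each foreground voxel to the nearest background voxel. Background gets 0.
// [[Rcpp::export(name = ".cpp_edt")]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dims, NumericVector voxel_size) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  const double dx = voxel_size[0], dy = voxel_size[1], dz = voxel_size[2];
  const double INF = 1e30;

  std::vector<double> g(n);
  for (int i = 0; i < n; ++i) g[i] = mask[i] ? INF : 0.0;

  std::vector<double> line;
  // along x
  line.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) line[x] = g[idx3(x, y, z, nx, ny)];
      dt1d(line, dx);
      for (int x = 0; x < nx; ++x) g[idx3(x, y, z, nx, ny)] = line[x];
    }
  // along y
  line.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) line[y] = g[idx3(x, y, z, nx, ny)];
      dt1d(line, dy);
      for (int y = 0; y < ny; ++y) g[idx3(x, y, z, nx, ny)] = line[y];
    }
  // along z
  line.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) line[z] = g[idx3(x, y, z, nx, ny)];
      dt1d(line, dz);
      for (int z = 0; z < nz; ++z) g[idx3(x, y, z, nx, ny)] = line[z];
    }

  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  return out;
}

// Marker-based watershed by priority flood on -priority (descending priority),
// restricted to mask. markers: 0 = unassigned, >0 = seed label. 6-connected
// growth so fronts cannot leak diagonally between touching objects.
// [[Rcpp::export(name = ".cpp_watershed")]]
IntegerVector cpp_watershed(NumericVector priority, LogicalVector mask,
                            IntegerVector markers, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  if (priority.size() != n || mask.size() != n || markers.size() != n)
    stop("inputs do not match dims");

  IntegerVector labels(n, 0);
  typedef std::pair<double, int> Node; // (-priority, voxel)
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;

  for (int i = 0; i < n; ++i)
    if (markers[i] > 0 && mask[i]) {
      labels[i] = markers[i];
      pq.push(Node(-priority[i], i));
    }

  const int dxs[6] = { 1, -1, 0, 0, 0, 0 };
  const int dys[6] = { 0, 0, 1, -1, 0, 0 };
  const int dzs[6] = { 0, 0, 0, 0, 1, -1 };

  while (!pq.empty()) {
    int v = pq.top().second; pq.pop();
    int z = v / (nx * ny), rem = v % (nx * ny);
    int y = rem / nx, x = rem % nx;
    for (int k = 0; k < 6; ++k) {
      int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
      int w = idx3(xx, yy, zz, nx, ny);
      if (!mask[w] || labels[w] != 0) continue;
      labels[w] = labels[v];
      pq.push(Node(-priority[w], w));
    }
  }
  return labels;
}

// Separable Gaussian blur with reflective boundaries; sigma per axis in voxels.
// [[Rcpp::export(name = ".cpp_gauss3d")]]
NumericVector cpp_gauss3d(NumericVector vol, IntegerVector dims, NumericVector sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  if (vol.size() != n) stop("vol length does not match dims");

  std::vector<double> a(vol.begin(), vol.end()), b(n);
  const int nax[3] = { nx, ny, nz };

  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int radius = (int)std::ceil(3.0 * s);
    std::vector<double> ker(2 * radius + 1);
    double ksum = 0.0;
    for (int i = -radius; i <= radius; ++i) {
      ker[i + radius] = std::exp(-0.5 * (double)i * i / (s * s));
      ksum += ker[i + radius];
    }
    for (size_t i = 0; i < ker.size(); ++i) ker[i] /= ksum;

    int len = nax[axis];
    for (int z = 0; z < (axis == 2 ? 1 : nz); ++z)
      for (int y = 0; y < (axis == 1 ? 1 : ny); ++y)
        for (int x = 0; x < (axis == 0 ? 1 : nx); ++x) {
          for (int t = 0; t < len; ++t) {
            double acc = 0.0;
            for (int k = -radius; k <= radius; ++k) {
              int tt = t + k;
              if (tt < 0) tt = -tt;                 // reflect
              if (tt >= len) tt = 2 * len - 2 - tt;
              if (tt < 0) tt = 0;
              int xi = axis == 0 ? tt : x, yi = axis == 1 ? tt : y,
                  zi = axis == 2 ? tt : z;
              acc += ker[k + radius] * a[idx3(xi, yi, zi, nx, ny)];
            }
            int xo = axis == 0 ? t : x, yo = axis == 1 ? t : y, zo = axis == 2 ? t : z;
            b[idx3(xo, yo, zo, nx, ny)] = acc;
          }
        }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}
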