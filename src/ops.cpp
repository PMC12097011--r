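// Low-level voxel operations on 3D arrays stored in R's column-major layout:
// linear index = i + nx*(j + ny*k), 0-based here.  All physical distances are
// in micrometres; spacing is (sx, sy, sz) per axis.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline int lin(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher), squared
// distances propagated axis by axis with per-axis weights spacing^2.
// Returns, for every voxel, the distance (um) to the nearest TRUE voxel.
// ---------------------------------------------------------------------------
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double w2) {
  const double INF = std::numeric_limits<double>::infinity();
  // lower envelope of parabolas f[q] + w2*(x-q)^2 over sites with finite f
  static thread_local std::vector<int> sites;
  sites.clear();
  for (int q = 0; q < n; ++q)
    if (f[q] != INF) sites.push_back(q);
  if (sites.empty()) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  std::vector<int> v(sites.size());
  std::vector<double> z(sites.size() + 1);
  int k = 0;
  v[0] = sites[0];
  z[0] = -INF;
  z[1] = INF;
  for (size_t si = 1; si < sites.size(); ++si) {
    int q = sites[si];
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) /
          (2.0 * w2 * (q - p));
      if (s <= z[k]) { --k; } else break; // z[0] = -INF guarantees exit
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    d[q] = f[p] + w2 * (q - p) * (q - p);
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  const double INF = std::numeric_limits<double>::infinity();
  for (R_xlen_t t = 0; t < n; ++t) out[t] = mask[t] ? 0.0 : INF;

  // x pass
  {
    std::vector<double> f(nx), d(nx);
    double w2 = spacing[0] * spacing[0];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) f[i] = out[lin(i, j, k, nx, ny)];
        dt1d(f, d, nx, w2);
        for (int i = 0; i < nx; ++i) out[lin(i, j, k, nx, ny)] = d[i];
      }
  }
  // y pass
  {
    std::vector<double> f(ny), d(ny);
    double w2 = spacing[1] * spacing[1];
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) {
        for (int j = 0; j < ny; ++j) f[j] = out[lin(i, j, k, nx, ny)];
        dt1d(f, d, ny, w2);
        for (int j = 0; j < ny; ++j) out[lin(i, j, k, nx, ny)] = d[j];
      }
  }
  // z pass
  {
    std::vector<double> f(nz), d(nz);
    double w2 = spacing[2] * spacing[2];
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        for (int k = 0; k < nz; ++k) f[k] = out[lin(i, j, k, nx, ny)];
        dt1d(f, d, nz, w2);
        for (int k = 0; k < nz; ++k) out[lin(i, j, k, nx, ny)] = d[k];
      }
  }
  for (R_xlen_t t = 0; t < n; ++t)
    if (out[t] != INF) out[t] = std::sqrt(out[t]);
  return out;
}

// ---------------------------------------------------------------------------
// Neighborhood offset tables
// ---------------------------------------------------------------------------
static void neighbor_offsets(int connectivity, std::vector<int>& dx,
                             std::vector<int>& dy, std::vector<int>& dz) {
  dx.clear(); dy.clear(); dz.clear();
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
}

// ---------------------------------------------------------------------------
// Seeded region growing: sequential BFS per seed; voxels reachable from more
// than one seed keep the label of the first seed in list order.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_region_grow(NumericVector gray, IntegerVector dim,
                              IntegerMatrix seeds, double low, double high,
                              int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> dx, dy, dz;
  neighbor_offsets(connectivity, dx, dy, dz);
  int nn = (int)dx.size();
  std::vector<int> qx, qy, qz; // BFS stack (order within a seed is irrelevant)
  for (int s = 0; s < seeds.nrow(); ++s) {
    int si = seeds(s, 0), sj = seeds(s, 1), sk = seeds(s, 2);
    int sl = lin(si, sj, sk, nx, ny);
    double g = gray[sl];
    if (g < low || g > high)
      stop("seed %d has intensity %g outside [%g, %g]", s + 1, g, low, high);
    if (lab[sl] != 0) continue; // absorbed by an earlier seed's component
    lab[sl] = s + 1;
    qx.assign(1, si); qy.assign(1, sj); qz.assign(1, sk);
    while (!qx.empty()) {
      int i = qx.back(), j = qy.back(), k = qz.back();
      qx.pop_back(); qy.pop_back(); qz.pop_back();
      for (int t = 0; t < nn; ++t) {
        int ii = i + dx[t], jj = j + dy[t], kk = k + dz[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        int l = lin(ii, jj, kk, nx, ny);
        if (lab[l] != 0) continue;
        double v = gray[l];
        if (v < low || v > high) continue;
        lab[l] = s + 1;
        qx.push_back(ii); qy.push_back(jj); qz.push_back(kk);
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Connected component labelling, deterministic by scan order.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> dx, dy, dz;
  neighbor_offsets(connectivity, dx, dy, dz);
  int nn = (int)dx.size();
  std::vector<int> qx, qy, qz;
  int next = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int l = lin(i, j, k, nx, ny);
        if (!mask[l] || lab[l] != 0) continue;
        ++next;
        lab[l] = next;
        qx.assign(1, i); qy.assign(1, j); qz.assign(1, k);
        while (!qx.empty()) {
          int ci = qx.back(), cj = qy.back(), ck = qz.back();
          qx.pop_back(); qy.pop_back(); qz.pop_back();
          for (int t = 0; t < nn; ++t) {
            int ii = ci + dx[t], jj = cj + dy[t], kk = ck + dz[t];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
            int l2 = lin(ii, jj, kk, nx, ny);
            if (!mask[l2] || lab[l2] != 0) continue;
            lab[l2] = next;
            qx.push_back(ii); qy.push_back(jj); qz.push_back(kk);
          }
        }
      }
  return lab;
}

// ---------------------------------------------------------------------------
// Simple-point test (Malandain & Bertrand): a foreground voxel is simple iff
//   (a) its foreground 26-neighbours form exactly one 26-connected component,
//   (b) the background voxels of its 18-neighbourhood form exactly one
//       6-connected component that is 6-adjacent to the centre.
// ---------------------------------------------------------------------------
static bool is_simple(const std::vector<unsigned char>& fg, int i, int j, int k,
                      int nx, int ny, int nz) {
  unsigned char cube[27]; // local 3x3x3, index (a+1) + 3*(b+1) + 9*(c+1)
  for (int c = -1; c <= 1; ++c)
    for (int b = -1; b <= 1; ++b)
      for (int a = -1; a <= 1; ++a) {
        int ii = i + a, jj = j + b, kk = k + c;
        int ci = (a + 1) + 3 * (b + 1) + 9 * (c + 1);
        cube[ci] = (ii >= 0 && jj >= 0 && kk >= 0 && ii < nx && jj < ny && kk < nz)
          ? fg[lin(ii, jj, kk, nx, ny)] : 0;
      }
  const int center = 13;

  // (a) one 26-component of foreground among the 26 neighbours
  {
    int seen[27] = {0};
    int ncomp = 0;
    for (int s = 0; s < 27; ++s) {
      if (s == center || !cube[s] || seen[s]) continue;
      ++ncomp;
      if (ncomp > 1) return false;
      std::vector<int> st(1, s);
      seen[s] = 1;
      while (!st.empty()) {
        int cur = st.back(); st.pop_back();
        int ca = cur % 3, cb = (cur / 3) % 3, cc = cur / 9;
        for (int c2 = -1; c2 <= 1; ++c2)
          for (int b2 = -1; b2 <= 1; ++b2)
            for (int a2 = -1; a2 <= 1; ++a2) {
              int na = ca + a2, nb = cb + b2, nc = cc + c2;
              if (na < 0 || nb < 0 || nc < 0 || na > 2 || nb > 2 || nc > 2) continue;
              int t = na + 3 * nb + 9 * nc;
              if (t == center || t == cur || !cube[t] || seen[t]) continue;
              seen[t] = 1;
              st.push_back(t);
            }
      }
    }
    if (ncomp != 1) return false;
  }

  // (b) background 6-components within the 18-neighbourhood, counted only if
  // 6-adjacent to the centre; adjacency is 6-connectivity restricted to N18
  {
    bool in18[27];
    for (int s = 0; s < 27; ++s) {
      int ca = s % 3 - 1, cb = (s / 3) % 3 - 1, cc = s / 9 - 1;
      int m = std::abs(ca) + std::abs(cb) + std::abs(cc);
      in18[s] = (m >= 1 && m <= 2);
    }
    int seen[27] = {0};
    int ncomp = 0;
    for (int s = 0; s < 27; ++s) {
      if (!in18[s] || cube[s] || seen[s]) continue;
      // flood this background component (6-adjacency within N18)
      std::vector<int> st(1, s);
      seen[s] = 1;
      bool touches_center = false;
      while (!st.empty()) {
        int cur = st.back(); st.pop_back();
        int ca = cur % 3 - 1, cb = (cur / 3) % 3 - 1, cc = cur / 9 - 1;
        if (std::abs(ca) + std::abs(cb) + std::abs(cc) == 1) touches_center = true;
        const int steps[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
        for (int t2 = 0; t2 < 6; ++t2) {
          int na = ca + steps[t2][0], nb = cb + steps[t2][1], nc = cc + steps[t2][2];
          if (na < -1 || nb < -1 || nc < -1 || na > 1 || nb > 1 || nc > 1) continue;
          int t = (na + 1) + 3 * (nb + 1) + 9 * (nc + 1);
          if (!in18[t] || cube[t] || seen[t]) continue;
          seen[t] = 1;
          st.push_back(t);
        }
      }
      if (touches_center) ++ncomp;
      if (ncomp > 1) return false;
    }
    if (ncomp != 1) return false;
  }
  return true;
}

// ---------------------------------------------------------------------------
// Distance-ordered homotopic thinning: peel simple points from the boundary
// inwards (ordered by distance to background) while preserving curve
// endpoints (voxels with at most one foreground 26-neighbour).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
LogicalVector cpp_skeletonize(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<unsigned char> fg(n);
  for (R_xlen_t t = 0; t < n; ++t) fg[t] = mask[t] ? 1 : 0;

  // distance to background (voxel units): EDT of the complement
  LogicalVector bg(n);
  for (R_xlen_t t = 0; t < n; ++t) bg[t] = !fg[t];
  NumericVector spacing = NumericVector::create(1.0, 1.0, 1.0);
  NumericVector D = cpp_edt(bg, dim, spacing);
  // border voxels of the volume: outside counts as background at distance 0;
  // account for it so peeling starts at the true boundary
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int edge = std::min({i + 1, j + 1, k + 1, nx - i, ny - j, nz - k});
        int l = lin(i, j, k, nx, ny);
        if (fg[l] && edge < D[l]) D[l] = edge;
      }

  std::vector<int> dx, dy, dz;
  neighbor_offsets(26, dx, dy, dz);

  typedef std::pair<double, int> QE; // (distance, linear index)
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int l = lin(i, j, k, nx, ny);
        if (fg[l]) pq.push(QE(D[l], l));
      }

  while (!pq.empty()) {
    int l = pq.top().second;
    pq.pop();
    if (!fg[l]) continue;
    int i = l % nx, j = (l / nx) % ny, k = l / (nx * ny);
    // endpoint protection
    int cnt = 0;
    for (size_t t = 0; t < dx.size(); ++t) {
      int ii = i + dx[t], jj = j + dy[t], kk = k + dz[t];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      if (fg[lin(ii, jj, kk, nx, ny)]) ++cnt;
    }
    if (cnt <= 1) continue;
    if (!is_simple(fg, i, j, k, nx, ny, nz)) continue;
    fg[l] = 0;
    for (size_t t = 0; t < dx.size(); ++t) {
      int ii = i + dx[t], jj = j + dy[t], kk = k + dz[t];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      int l2 = lin(ii, jj, kk, nx, ny);
      if (fg[l2]) pq.push(QE(D[l2], l2));
    }
  }

  LogicalVector out(n);
  for (R_xlen_t t = 0; t < n; ++t) out[t] = fg[t] != 0;
  return out;
}

// ---------------------------------------------------------------------------
// Cube-window median filter (radius in voxels).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_median_filter(NumericVector img, IntegerVector dim, int radius) {
  if (radius <= 0) return clone(img);
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  std::vector<double> w;
  w.reserve((2 * radius + 1) * (2 * radius + 1) * (2 * radius + 1));
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        w.clear();
        for (int c = std::max(0, k - radius); c <= std::min(nz - 1, k + radius); ++c)
          for (int b = std::max(0, j - radius); b <= std::min(ny - 1, j + radius); ++b)
            for (int a = std::max(0, i - radius); a <= std::min(nx - 1, i + radius); ++a)
              w.push_back(img[lin(a, b, c, nx, ny)]);
        size_t m = w.size() / 2;
        std::nth_element(w.begin(), w.begin() + m, w.end());
        double med = w[m];
        if (w.size() % 2 == 0) {
          std::nth_element(w.begin(), w.begin() + m - 1, w.begin() + m);
          med = 0.5 * (med + w[m - 1]);
        }
        out[lin(i, j, k, nx, ny)] = med;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing, reflected boundary; sigma per axis in voxels.
// ---------------------------------------------------------------------------
static void conv1(std::vector<double>& line, const std::vector<double>& kern) {
  int n = (int)line.size();
  int r = ((int)kern.size() - 1) / 2;
  std::vector<double> out(n, 0.0);
  for (int x = 0; x < n; ++x) {
    double s = 0.0;
    for (int t = -r; t <= r; ++t) {
      int q = x + t;
      while (q < 0 || q >= n) { // repeated reflection for wide kernels
        if (q < 0) q = -q - 1;
        if (q >= n) q = 2 * n - q - 1;
      }
      s += line[q] * kern[t + r];
    }
    out[x] = s;
  }
  line.swap(out);
}

static std::vector<double> gauss_kernel(double sigma) {
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int t = -r; t <= r; ++t) {
    k[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += k[t + r];
  }
  for (size_t t = 0; t < k.size(); ++t) k[t] /= s;
  return k;
}

// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector img, IntegerVector dim,
                               NumericVector sigma_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out = clone(img);
  if (sigma_vox[0] > 0) {
    std::vector<double> kern = gauss_kernel(sigma_vox[0]);
    std::vector<double> line(nx);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) line[i] = out[lin(i, j, k, nx, ny)];
        conv1(line, kern);
        for (int i = 0; i < nx; ++i) out[lin(i, j, k, nx, ny)] = line[i];
      }
  }
  if (sigma_vox[1] > 0) {
    std::vector<double> kern = gauss_kernel(sigma_vox[1]);
    std::vector<double> line(ny);
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) {
        for (int j = 0; j < ny; ++j) line[j] = out[lin(i, j, k, nx, ny)];
        conv1(line, kern);
        for (int j = 0; j < ny; ++j) out[lin(i, j, k, nx, ny)] = line[j];
      }
  }
  if (sigma_vox[2] > 0) {
    std::vector<double> kern = gauss_kernel(sigma_vox[2]);
    std::vector<double> line(nz);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        for (int k = 0; k < nz; ++k) line[k] = out[lin(i, j, k, nx, ny)];
        conv1(line, kern);
        for (int k = 0; k < nz; ++k) out[lin(i, j, k, nx, ny)] = line[k];
      }
  }
  (void)n;
  return out;
}

// ---------------------------------------------------------------------------
// Separable cube min/max filter (radius in voxels).
// ---------------------------------------------------------------------------
static void runminmax1(std::vector<double>& line, int r, bool want_max) {
  int n = (int)line.size();
  std::vector<double> out(n);
  for (int x = 0; x < n; ++x) {
    double v = line[x];
    for (int t = std::max(0, x - r); t <= std::min(n - 1, x + r); ++t)
      v = want_max ? std::max(v, line[t]) : std::min(v, line[t]);
    out[x] = v;
  }
  line.swap(out);
}

// [[Rcpp::export]]
NumericVector cpp_minmax_filter(NumericVector img, IntegerVector dim,
                                int radius, bool want_max) {
  if (radius <= 0) return clone(img);
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out = clone(img);
  std::vector<double> line;
  line.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) line[i] = out[lin(i, j, k, nx, ny)];
      runminmax1(line, radius, want_max);
      for (int i = 0; i < nx; ++i) out[lin(i, j, k, nx, ny)] = line[i];
    }
  line.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) line[j] = out[lin(i, j, k, nx, ny)];
      runminmax1(line, radius, want_max);
      for (int j = 0; j < ny; ++j) out[lin(i, j, k, nx, ny)] = line[j];
    }
  line.resize(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) line[k] = out[lin(i, j, k, nx, ny)];
      runminmax1(line, radius, want_max);
      for (int k = 0; k < nz; ++k) out[lin(i, j, k, nx, ny)] = line[k];
    }
  return out;
}

// ---------------------------------------------------------------------------
// Resampling.  Voxel centres sit at index * spacing (0-based).  Trilinear for
// grayscale, nearest-neighbour for labels; edges clamped.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector img, IntegerVector dim,
                           NumericVector spacing, IntegerVector outdim,
                           NumericVector outspacing, bool nearest) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ox = outdim[0], oy = outdim[1], oz = outdim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  for (int k = 0; k < oz; ++k) {
    double zf = k * outspacing[2] / spacing[2];
    for (int j = 0; j < oy; ++j) {
      double yf = j * outspacing[1] / spacing[1];
      for (int i = 0; i < ox; ++i) {
        double xf = i * outspacing[0] / spacing[0];
        double v;
        if (nearest) {
          int ii = std::min(nx - 1, std::max(0, (int)std::lround(xf)));
          int jj = std::min(ny - 1, std::max(0, (int)std::lround(yf)));
          int kk = std::min(nz - 1, std::max(0, (int)std::lround(zf)));
          v = img[lin(ii, jj, kk, nx, ny)];
        } else {
          double xc = std::min((double)(nx - 1), std::max(0.0, xf));
          double yc = std::min((double)(ny - 1), std::max(0.0, yf));
          double zc = std::min((double)(nz - 1), std::max(0.0, zf));
          int x0 = (int)std::floor(xc), y0 = (int)std::floor(yc), z0 = (int)std::floor(zc);
          int x1 = std::min(nx - 1, x0 + 1), y1 = std::min(ny - 1, y0 + 1), z1 = std::min(nz - 1, z0 + 1);
          double fx = xc - x0, fy = yc - y0, fz = zc - z0;
          double c00 = img[lin(x0, y0, z0, nx, ny)] * (1 - fx) + img[lin(x1, y0, z0, nx, ny)] * fx;
          double c10 = img[lin(x0, y1, z0, nx, ny)] * (1 - fx) + img[lin(x1, y1, z0, nx, ny)] * fx;
          double c01 = img[lin(x0, y0, z1, nx, ny)] * (1 - fx) + img[lin(x1, y0, z1, nx, ny)] * fx;
          double c11 = img[lin(x0, y1, z1, nx, ny)] * (1 - fx) + img[lin(x1, y1, z1, nx, ny)] * fx;
          double c0 = c00 * (1 - fy) + c10 * fy;
          double c1 = c01 * (1 - fy) + c11 * fy;
          v = c0 * (1 - fz) + c1 * fz;
        }
        out[lin(i, j, k, ox, oy)] = v;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Rasterize tube segments (flat-capped cones with linearly varying radius).
// segs columns: x1 y1 z1 x2 y2 z2 r1 r2 (um).  A zero-length segment is a
// sphere of radius r1.  Voxel centre at index * spacing; membership is
// centre-in-tube with the axial coordinate half-open in [0, L) so butted
// segments do not double-count caps.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
LogicalVector cpp_rasterize_tubes(NumericMatrix segs, IntegerVector dim,
                                  NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  for (int s = 0; s < segs.nrow(); ++s) {
    double x1 = segs(s, 0), y1 = segs(s, 1), z1 = segs(s, 2);
    double x2 = segs(s, 3), y2 = segs(s, 4), z2 = segs(s, 5);
    double r1 = segs(s, 6), r2 = segs(s, 7);
    double rmax = std::max(r1, r2);
    double ux = x2 - x1, uy = y2 - y1, uz = z2 - z1;
    double L2 = ux * ux + uy * uy + uz * uz;
    double L = std::sqrt(L2);
    int i0 = std::max(0, (int)std::floor((std::min(x1, x2) - rmax) / sx));
    int i1 = std::min(nx - 1, (int)std::ceil((std::max(x1, x2) + rmax) / sx));
    int j0 = std::max(0, (int)std::floor((std::min(y1, y2) - rmax) / sy));
    int j1 = std::min(ny - 1, (int)std::ceil((std::max(y1, y2) + rmax) / sy));
    int k0 = std::max(0, (int)std::floor((std::min(z1, z2) - rmax) / sz));
    int k1 = std::min(nz - 1, (int)std::ceil((std::max(z1, z2) + rmax) / sz));
    for (int k = k0; k <= k1; ++k) {
      double pz = k * sz;
      for (int j = j0; j <= j1; ++j) {
        double py = j * sy;
        for (int i = i0; i <= i1; ++i) {
          double px = i * sx;
          double wx = px - x1, wy = py - y1, wz = pz - z1;
          bool inside;
          if (L < 1e-9) { // sphere
            inside = wx * wx + wy * wy + wz * wz <= r1 * r1;
          } else {
            double t = (wx * ux + wy * uy + wz * uz) / L2;
            if (t < 0.0 || t >= 1.0) { inside = false; }
            else {
              double r = r1 + t * (r2 - r1);
              double qx = wx - t * ux, qy = wy - t * uy, qz = wz - t * uz;
              inside = qx * qx + qy * qy + qz * qz <= r * r;
            }
          }
          if (inside) out[lin(i, j, k, nx, ny)] = true;
        }
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Per-voxel count of TRUE 26-neighbours (used by the skeleton graph builder).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_neighbor_count(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector out(n, 0);
  std::vector<int> dx, dy, dz;
  neighbor_offsets(26, dx, dy, dz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int l = lin(i, j, k, nx, ny);
        if (!mask[l]) continue;
        int c = 0;
        for (size_t t = 0; t < dx.size(); ++t) {
          int ii = i + dx[t], jj = j + dy[t], kk = k + dz[t];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
          if (mask[lin(ii, jj, kk, nx, ny)]) ++c;
        }
        out[l] = c;
      }
  return out;
}
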