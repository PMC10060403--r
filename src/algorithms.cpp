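// Compiled kernels for raster processing. Images are base-R numeric matrices
// (nrow = height = y, ncol = width = x, column-major), so pixel (x, y)
// zero-based maps to linear index y + x * h.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

static inline int idx(int y, int x, int h) { return y + x * h; }

// ---------------------------------------------------------------------------
// 4-connected component labeling; labels assigned consecutively in raster
// scan order (row-major over y then x), deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_label4(LogicalMatrix mask) {
  int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  std::vector<int> stack;
  int next = 0;
  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) {
      int i = idx(y, x, h);
      if (!mask[i] || lab[i] != 0) continue;
      ++next;
      lab[i] = next;
      stack.push_back(i);
      while (!stack.empty()) {
        int c = stack.back(); stack.pop_back();
        int cy = c % h, cx = c / h;
        const int dy[4] = {-1, 1, 0, 0};
        const int dx[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int ny = cy + dy[k], nx = cx + dx[k];
          if (ny < 0 || ny >= h || nx < 0 || nx >= w) continue;
          int ni = idx(ny, nx, h);
          if (mask[ni] && lab[ni] == 0) { lab[ni] = next; stack.push_back(ni); }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (distance of each foreground pixel to
// the nearest background pixel), Felzenszwalb-Huttenlocher lower envelope of
// parabolas, applied per column then per row on squared distances.
static void dt1d(std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_edt(LogicalMatrix mask) {
  int h = mask.nrow(), w = mask.ncol();
  NumericMatrix out(h, w);
  const double INF = 1e18;
  // squared distance along y (columns of the matrix)
  std::vector<double> f(std::max(h, w)), d(std::max(h, w));
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) f[y] = mask[idx(y, x, h)] ? INF : 0.0;
    dt1d(f, d, h);
    for (int y = 0; y < h; ++y) out[idx(y, x, h)] = d[y];
  }
  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) f[x] = out[idx(y, x, h)];
    dt1d(f, d, w);
    for (int x = 0; x < w; ++x) out[idx(y, x, h)] = std::sqrt(d[x]);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Grayscale morphological reconstruction by dilation of `marker` under
// `mask` (marker <= mask elementwise), 4-connectivity. Vincent's hybrid
// algorithm: raster + anti-raster sweep, then a FIFO queue.
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct(NumericMatrix marker, NumericMatrix mask) {
  int h = marker.nrow(), w = marker.ncol();
  NumericMatrix J(h, w);
  for (int i = 0; i < h * w; ++i) J[i] = std::min(marker[i], mask[i]);
  // raster scan (N and W neighbours)
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) {
      double m = J[idx(y, x, h)];
      if (y > 0) m = std::max(m, J[idx(y - 1, x, h)]);
      if (x > 0) m = std::max(m, J[idx(y, x - 1, h)]);
      J[idx(y, x, h)] = std::min(m, mask[idx(y, x, h)]);
    }
  }
  std::queue<int> fifo;
  // anti-raster scan (S and E neighbours), queue boundary pixels
  for (int x = w - 1; x >= 0; --x) {
    for (int y = h - 1; y >= 0; --y) {
      int i = idx(y, x, h);
      double m = J[i];
      if (y < h - 1) m = std::max(m, J[idx(y + 1, x, h)]);
      if (x < w - 1) m = std::max(m, J[idx(y, x + 1, h)]);
      J[i] = std::min(m, mask[i]);
      bool push = false;
      if (y < h - 1) {
        int n = idx(y + 1, x, h);
        if (J[n] < J[i] && J[n] < mask[n]) push = true;
      }
      if (x < w - 1) {
        int n = idx(y, x + 1, h);
        if (J[n] < J[i] && J[n] < mask[n]) push = true;
      }
      if (push) fifo.push(i);
    }
  }
  const int dy[4] = {-1, 1, 0, 0};
  const int dx[4] = {0, 0, -1, 1};
  while (!fifo.empty()) {
    int i = fifo.front(); fifo.pop();
    int cy = i % h, cx = i / h;
    for (int k = 0; k < 4; ++k) {
      int ny = cy + dy[k], nx = cx + dx[k];
      if (ny < 0 || ny >= h || nx < 0 || nx >= w) continue;
      int n = idx(ny, nx, h);
      if (J[n] < J[i] && mask[n] != J[n]) {
        J[n] = std::min(J[i], mask[n]);
        fifo.push(n);
      }
    }
  }
  return J;
}

// ---------------------------------------------------------------------------
// Seeded watershed on -dmap restricted to dmap > 0. `seeds` is an integer
// matrix, 0 where unseeded, k > 0 for seed k. Flooding order: descending
// dmap value, FIFO tie-break by insertion counter (deterministic).
struct WsEntry {
  double value;
  long order;
  int pixel;
  int label;
};
struct WsCmp {
  bool operator()(const WsEntry& a, const WsEntry& b) const {
    if (a.value != b.value) return a.value < b.value;  // max-heap on value
    return a.order > b.order;                          // FIFO on ties
  }
};

// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix dmap, IntegerMatrix seeds) {
  int h = dmap.nrow(), w = dmap.ncol();
  IntegerMatrix lab(h, w);
  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCmp> pq;
  long counter = 0;
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y) {
      int i = idx(y, x, h);
      if (seeds[i] > 0 && dmap[i] > 0) {
        lab[i] = seeds[i];
        pq.push(WsEntry{dmap[i], counter++, i, seeds[i]});
      }
    }
  const int dy[4] = {-1, 1, 0, 0};
  const int dx[4] = {0, 0, -1, 1};
  while (!pq.empty()) {
    WsEntry e = pq.top(); pq.pop();
    int cy = e.pixel % h, cx = e.pixel / h;
    for (int k = 0; k < 4; ++k) {
      int ny = cy + dy[k], nx = cx + dx[k];
      if (ny < 0 || ny >= h || nx < 0 || nx >= w) continue;
      int n = idx(ny, nx, h);
      if (dmap[n] > 0 && lab[n] == 0) {
        lab[n] = e.label;
        pq.push(WsEntry{dmap[n], counter++, n, e.label});
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// O(n^3) Hungarian algorithm (potentials / shortest augmenting path) for a
// square cost matrix; returns, for each row, the assigned column (1-based).
// [[Rcpp::export]]
IntegerVector cpp_hungarian(NumericMatrix cost) {
  int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }
  IntegerVector ans(n);
  for (int j = 1; j <= n; ++j)
    if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}

// ---------------------------------------------------------------------------
// PNG scanline unfiltering (filters 0-4, non-interlaced). `raw` holds
// height * (1 + rowbytes) bytes; returns height * rowbytes reconstructed
// bytes. bpp = bytes per complete pixel.
// [[Rcpp::export]]
RawVector cpp_png_unfilter(RawVector raw, int height, int rowbytes, int bpp) {
  if ((long)raw.size() < (long)height * (rowbytes + 1))
    stop("PNG data truncated");
  RawVector out((long)height * rowbytes);
  std::vector<unsigned char> prev(rowbytes, 0), cur(rowbytes, 0);
  long pos = 0;
  for (int r = 0; r < height; ++r) {
    int ft = raw[pos++];
    for (int i = 0; i < rowbytes; ++i) cur[i] = raw[pos + i];
    pos += rowbytes;
    switch (ft) {
      case 0: break;
      case 1:
        for (int i = bpp; i < rowbytes; ++i) cur[i] = (unsigned char)(cur[i] + cur[i - bpp]);
        break;
      case 2:
        for (int i = 0; i < rowbytes; ++i) cur[i] = (unsigned char)(cur[i] + prev[i]);
        break;
      case 3:
        for (int i = 0; i < rowbytes; ++i) {
          int a = (i >= bpp) ? cur[i - bpp] : 0;
          cur[i] = (unsigned char)(cur[i] + ((a + prev[i]) >> 1));
        }
        break;
      case 4:
        for (int i = 0; i < rowbytes; ++i) {
          int a = (i >= bpp) ? cur[i - bpp] : 0;
          int b = prev[i];
          int c = (i >= bpp) ? prev[i - bpp] : 0;
          int pp = a + b - c;
          int pa = std::abs(pp - a), pb = std::abs(pp - b), pc = std::abs(pp - c);
          int pr = (pa <= pb && pa <= pc) ? a : (pb <= pc ? b : c);
          cur[i] = (unsigned char)(cur[i] + pr);
        }
        break;
      default:
        stop("unsupported PNG filter type %d", ft);
    }
    for (int i = 0; i < rowbytes; ++i) out[(long)r * rowbytes + i] = cur[i];
    prev = cur;
  }
  return out;
}

// CRC-32 (PNG chunk checksum), standard polynomial 0xEDB88320.
// [[Rcpp::export]]
double cpp_crc32(RawVector data) {
  static unsigned long table[256];
  static bool have = false;
  if (!have) {
    for (unsigned long n = 0; n < 256; ++n) {
      unsigned long c = n;
      for (int k = 0; k < 8; ++k)
        c = (c & 1) ? 0xEDB88320UL ^ (c >> 1) : c >> 1;
      table[n] = c;
    }
    have = true;
  }
  unsigned long c = 0xFFFFFFFFUL;
  for (long i = 0; i < (long)data.size(); ++i)
    c = table[(c ^ data[i]) & 0xFF] ^ (c >> 8);
  return (double)(c ^ 0xFFFFFFFFUL);
}
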