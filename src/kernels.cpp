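#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Binary-image kernels shared by the mask machinery. All matrices are
// row x col in R's column-major layout; masks are 0/1 integer matrices.

// ---------------------------------------------------------------------------
// Connected-component labeling (BFS, scan-order label assignment so labels
// are deterministic and consecutive 1..K).
// [[Rcpp::export]]
IntegerMatrix cpp_label(const IntegerMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  const int nd = (connectivity == 8) ? 8 : 4;

  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int k = 0; k < nd; ++k) {
          int qi = pi + dr[k], qj = pj + dc[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) != 0 && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher lower
// envelope of parabolas): distance from each foreground pixel to the nearest
// background pixel center. Background pixels get 0.

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
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
NumericMatrix cpp_edt(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e18;
  NumericMatrix d(nr, nc);
  // pass 1: along columns
  {
    std::vector<double> f(nr), out(nr), z(nr + 1);
    std::vector<int> v(nr);
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) f[i] = (mask(i, j) != 0) ? INF : 0.0;
      dt1d(f, out, nr, v, z);
      for (int i = 0; i < nr; ++i) d(i, j) = out[i];
    }
  }
  // pass 2: along rows
  {
    std::vector<double> f(nc), out(nc), z(nc + 1);
    std::vector<int> v(nc);
    for (int i = 0; i < nr; ++i) {
      for (int j = 0; j < nc; ++j) f[j] = d(i, j);
      dt1d(f, out, nc, v, z);
      for (int j = 0; j < nc; ++j) d(i, j) = std::sqrt(out[j]);
    }
  }
  return d;
}

// ---------------------------------------------------------------------------
// Marker-controlled watershed on a height map (here -EDT conceptually:
// basins grow from seeds in order of DECREASING dist). Every mask pixel is
// assigned to exactly one seed basin; no separating background lines are
// produced. Ties pop in insertion order, so the result is deterministic.

struct WsNode {
  double d;
  long long order;
  int idx;
  int label;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.d != b.d) return a.d < b.d;   // max-heap on distance
    return a.order > b.order;            // FIFO among ties
  }
};

// [[Rcpp::export]]
IntegerMatrix cpp_watershed(const NumericMatrix& dist,
                            const IntegerMatrix& seeds,
                            const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long long order = 0;
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (seeds(i, j) > 0 && mask(i, j) != 0)
        pq.push({dist(i, j), order++, i + j * nr, seeds(i, j)});

  // labels are committed at POP time, so each pixel joins the basin whose
  // front reaches it at the globally highest remaining priority - assigning
  // on push would let a front reserve pixels ahead of a better-placed
  // rival. Only the assigning pop expands, so each pixel is expanded once.
  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    int pi = nd.idx % nr, pj = nd.idx / nr;
    if (lab(pi, pj) != 0) continue;
    lab(pi, pj) = nd.label;
    for (int k = 0; k < 8; ++k) {
      int qi = pi + dr[k], qj = pj + dc[k];
      if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
      if (mask(qi, qj) != 0 && lab(qi, qj) == 0) {
        pq.push({dist(qi, qj), order++, qi + qj * nr, nd.label});
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Greyscale morphological reconstruction by dilation (8-connectivity):
// iteratively propagates the marker under the mask image until stable
// (Vincent's sequential algorithm with forward/backward raster passes).
// Used for the h-maxima transform that seeds the watershed.

// [[Rcpp::export]]
NumericMatrix cpp_reconstruct(const NumericMatrix& marker,
                              const NumericMatrix& mask) {
  const int nr = marker.nrow(), nc = marker.ncol();
  NumericMatrix v(clone(marker));
  bool changed = true;
  auto val = [&](int i, int j) -> double {
    if (i < 0 || i >= nr || j < 0 || j >= nc)
      return -std::numeric_limits<double>::infinity();
    return v(i, j);
  };
  while (changed) {
    changed = false;
    // forward pass: N, NW, NE, W neighbours
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        double m = v(i, j);
        m = std::max(m, val(i - 1, j));
        m = std::max(m, val(i - 1, j - 1));
        m = std::max(m, val(i - 1, j + 1));
        m = std::max(m, val(i, j - 1));
        m = std::min(m, mask(i, j));
        if (m > v(i, j)) { v(i, j) = m; changed = true; }
      }
    // backward pass: S, SE, SW, E neighbours
    for (int j = nc - 1; j >= 0; --j)
      for (int i = nr - 1; i >= 0; --i) {
        double m = v(i, j);
        m = std::max(m, val(i + 1, j));
        m = std::max(m, val(i + 1, j + 1));
        m = std::max(m, val(i + 1, j - 1));
        m = std::max(m, val(i, j + 1));
        m = std::min(m, mask(i, j));
        if (m > v(i, j)) { v(i, j) = m; changed = true; }
      }
  }
  return v;
}

// ---------------------------------------------------------------------------
// Guo-Hall binary thinning (two-subiteration parallel algorithm): iterative
// deletion of simple border pixels until stable; yields an (approximately)
// 1-px-wide, 8-connected, topology-preserving skeleton. Chosen over
// textbook Zhang-Suen, which completely erodes 2-px-wide diagonal strokes
// at certain phase offsets.

// [[Rcpp::export]]
IntegerMatrix cpp_thin(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix img(clone(mask));
  std::vector<int> kill;
  bool changed = true;

  auto at = [&](int i, int j) -> int {
    if (i < 0 || i >= nr || j < 0 || j >= nc) return 0;
    return img(i, j) != 0 ? 1 : 0;
  };

  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      kill.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (img(i, j) == 0) continue;
          // neighbours clockwise from north: p2..p9
          int p2 = at(i - 1, j),     p3 = at(i - 1, j + 1);
          int p4 = at(i, j + 1),     p5 = at(i + 1, j + 1);
          int p6 = at(i + 1, j),     p7 = at(i + 1, j - 1);
          int p8 = at(i, j - 1),     p9 = at(i - 1, j - 1);
          int C = ((!p2) && (p3 || p4)) + ((!p4) && (p5 || p6)) +
                  ((!p6) && (p7 || p8)) + ((!p8) && (p9 || p2));
          if (C != 1) continue;
          int N1 = (p9 || p2) + (p3 || p4) + (p5 || p6) + (p7 || p8);
          int N2 = (p2 || p3) + (p4 || p5) + (p6 || p7) + (p8 || p9);
          int N = N1 < N2 ? N1 : N2;
          if (N < 2 || N > 3) continue;
          if (sub == 0) {
            if (((p2 || p3 || !p5) && p4) != 0) continue;
          } else {
            if (((p6 || p7 || !p9) && p8) != 0) continue;
          }
          kill.push_back(i + j * nr);
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (size_t k = 0; k < kill.size(); ++k)
          img(kill[k] % nr, kill[k] / nr) = 0;
      }
    }
  }
  return img;
}
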