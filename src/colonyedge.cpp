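// Pixel-level primitives for the edge-detection colony pipeline.
//
// Conventions (shared with the R layer):
//  * images are R matrices, nrow = height (y, rows), ncol = width (x, cols),
//    column-major as stored by R;
//  * all window operations use edge replication (indices clamped to the
//    frame), which keeps object measurements stable at image borders;
//  * a digital disk of radius r contains the offsets with
//    dx^2 + dy^2 <= (r + 0.5)^2, the ImageJ rank-filter convention;
//  * deterministic tie-breaking everywhere: pixels are ordered by
//    (value, column-major index).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <vector>

using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Offsets of a digital disk of radius r (ImageJ convention: d <= r + 0.5).
static void disk_offsets(double radius, std::vector<int>& dr,
                         std::vector<int>& dc) {
  int ir = (int)std::floor(radius + 0.5);
  double r2 = (radius + 0.5) * (radius + 0.5);
  for (int y = -ir; y <= ir; ++y)
    for (int x = -ir; x <= ir; ++x)
      if ((double)x * x + (double)y * y <= r2) {
        dr.push_back(y);
        dc.push_back(x);
      }
}

// [[Rcpp::export]]
NumericMatrix cpp_conv2(const NumericMatrix& x, const NumericMatrix& k) {
  const int H = x.nrow(), W = x.ncol();
  const int kh = k.nrow(), kw = k.ncol();
  const int rh = kh / 2, rw = kw / 2;
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      for (int b = 0; b < kw; ++b) {
        int jj = clampi(j + b - rw, 0, W - 1);
        for (int a = 0; a < kh; ++a) {
          int ii = clampi(i + a - rh, 0, H - 1);
          s += k(a, b) * x(ii, jj);
        }
      }
      out(i, j) = s;
    }
  return out;
}

// Separable convolution with a 1-D kernel applied along rows then columns.
// With per-axis index clamping this equals the dense 2-D convolution of the
// replicate-padded image by the outer-product kernel.
// [[Rcpp::export]]
NumericMatrix cpp_sepconv(const NumericMatrix& x, const NumericVector& k) {
  const int H = x.nrow(), W = x.ncol();
  const int n = k.size(), r = n / 2;
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      for (int a = 0; a < n; ++a) s += k[a] * x(clampi(i + a - r, 0, H - 1), j);
      tmp(i, j) = s;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      for (int a = 0; a < n; ++a) s += k[a] * tmp(i, clampi(j + a - r, 0, W - 1));
      out(i, j) = s;
    }
  return out;
}

// Rank filter over a digital disk: type 0 = minimum, 1 = maximum, 2 = median.
// [[Rcpp::export]]
NumericMatrix cpp_rank_disk(const NumericMatrix& x, double radius, int type) {
  const int H = x.nrow(), W = x.ncol();
  std::vector<int> dr, dc;
  disk_offsets(radius, dr, dc);
  const int n = (int)dr.size();
  NumericMatrix out(H, W);
  std::vector<double> buf(n);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (type == 2) {
        for (int t = 0; t < n; ++t)
          buf[t] = x(clampi(i + dr[t], 0, H - 1), clampi(j + dc[t], 0, W - 1));
        std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
        double med = buf[n / 2];
        if (n % 2 == 0) {
          double lo = *std::max_element(buf.begin(), buf.begin() + n / 2);
          med = 0.5 * (med + lo);
        }
        out(i, j) = med;
      } else {
        double v = x(clampi(i + dr[0], 0, H - 1), clampi(j + dc[0], 0, W - 1));
        for (int t = 1; t < n; ++t) {
          double u = x(clampi(i + dr[t], 0, H - 1), clampi(j + dc[t], 0, W - 1));
          if (type == 0 ? (u < v) : (u > v)) v = u;
        }
        out(i, j) = v;
      }
    }
  return out;
}

// Median-deviation outlier removal (ImageJ Remove Outliers): a pixel whose
// deviation from the disk-neighbourhood median exceeds `threshold` in the
// stated polarity is replaced by that median.
// [[Rcpp::export]]
// Disk median of a two-valued image by foreground counting (exact, and
// much faster than selection for binary masks).
static NumericMatrix rank_median_binary(const NumericMatrix& x, double lo,
                                        double hi, double radius) {
  const int H = x.nrow(), W = x.ncol();
  std::vector<int> dr, dc;
  disk_offsets(radius, dr, dc);
  const int n = (int)dr.size();  // odd by symmetry
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      int cnt = 0;
      for (int t = 0; t < n; ++t)
        if (x(clampi(i + dr[t], 0, H - 1), clampi(j + dc[t], 0, W - 1)) ==
            hi)
          ++cnt;
      out(i, j) = (2 * cnt > n) ? hi : lo;
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_remove_outliers(const NumericMatrix& x, double radius,
                                  double threshold, bool bright) {
  double mn = x[0], mx = x[0];
  bool twoval = true;
  for (R_xlen_t p = 0; p < x.size(); ++p) {
    double v = x[p];
    if (v < mn) mn = v;
    if (v > mx) mx = v;
  }
  for (R_xlen_t p = 0; p < x.size() && twoval; ++p)
    if (x[p] != mn && x[p] != mx) twoval = false;
  NumericMatrix med = twoval ? rank_median_binary(x, mn, mx, radius)
                             : cpp_rank_disk(x, radius, 2);
  const int H = x.nrow(), W = x.ncol();
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double dev = bright ? x(i, j) - med(i, j) : med(i, j) - x(i, j);
      out(i, j) = dev > threshold ? med(i, j) : x(i, j);
    }
  return out;
}

// 3x3 square min/max, `iter` passes (binary dilation/erosion workhorse).
// [[Rcpp::export]]
NumericMatrix cpp_morph3x3(const NumericMatrix& x, int type, int iter) {
  const int H = x.nrow(), W = x.ncol();
  NumericMatrix cur = clone(x);
  for (int it = 0; it < iter; ++it) {
    NumericMatrix nxt(H, W);
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double v = cur(i, j);
        for (int b = -1; b <= 1; ++b) {
          int jj = clampi(j + b, 0, W - 1);
          for (int a = -1; a <= 1; ++a) {
            double u = cur(clampi(i + a, 0, H - 1), jj);
            if (type == 0 ? (u < v) : (u > v)) v = u;
          }
        }
        nxt(i, j) = v;
      }
    cur = nxt;
  }
  return cur;
}

// Grayscale opening with a ball-height structuring element (Sternberg's
// rolling-ball construction): heights h(d) = sqrt(r^2 - |d|^2) over the
// disk |d| <= r.  Returns the opened image (the background estimate).
// Offset-outer streaming over a replicate-padded copy keeps memory access
// sequential.
// [[Rcpp::export]]
NumericMatrix cpp_ball_open(const NumericMatrix& x, double radius) {
  const int H = x.nrow(), W = x.ncol();
  const int r = (int)std::ceil(radius);
  std::vector<int> dr, dc;
  std::vector<double> hgt;
  for (int y = -r; y <= r; ++y)
    for (int xx = -r; xx <= r; ++xx) {
      double d2 = (double)xx * xx + (double)y * y;
      if (d2 <= radius * radius) {
        dr.push_back(y);
        dc.push_back(xx);
        hgt.push_back(std::sqrt(radius * radius - d2));
      }
    }
  const int n = (int)dr.size();
  const int PH = H + 2 * r, PW = W + 2 * r;

  std::vector<double> pad((size_t)PH * PW), ero((size_t)H * W),
      pero((size_t)PH * PW), opn((size_t)H * W);

  // replicate-pad x
  for (int j = 0; j < PW; ++j) {
    int js = clampi(j - r, 0, W - 1);
    for (int i = 0; i < PH; ++i)
      pad[(size_t)j * PH + i] = x(clampi(i - r, 0, H - 1), js);
  }
  std::fill(ero.begin(), ero.end(), R_PosInf);
  for (int t = 0; t < n; ++t) {
    const double h = hgt[t];
    for (int j = 0; j < W; ++j) {
      const double* __restrict src =
          &pad[(size_t)(j + r + dc[t]) * PH + (r + dr[t])];
      double* __restrict dst = &ero[(size_t)j * H];
      for (int i = 0; i < H; ++i) dst[i] = std::min(dst[i], src[i] - h);
    }
  }
  for (int j = 0; j < PW; ++j) {
    int js = clampi(j - r, 0, W - 1);
    for (int i = 0; i < PH; ++i)
      pero[(size_t)j * PH + i] = ero[(size_t)js * H + clampi(i - r, 0, H - 1)];
  }
  std::fill(opn.begin(), opn.end(), R_NegInf);
  for (int t = 0; t < n; ++t) {
    const double h = hgt[t];
    for (int j = 0; j < W; ++j) {
      const double* __restrict src =
          &pero[(size_t)(j + r + dc[t]) * PH + (r + dr[t])];
      double* __restrict dst = &opn[(size_t)j * H];
      for (int i = 0; i < H; ++i) dst[i] = std::max(dst[i], src[i] + h);
    }
  }
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) out(i, j) = opn[(size_t)j * H + i];
  return out;
}

// Connected-component labeling, deterministic label order: components are
// numbered by the column-major index of their first pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_label(const NumericMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<long> stack;
  int next = 0;
  const int dr8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dc8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = {0, 0, -1, 1};
  const int nn = connectivity == 8 ? 8 : 4;
  const int* DR = connectivity == 8 ? dr8 : dr4;
  const int* DC = connectivity == 8 ? dc8 : dc4;
  for (long p = 0; p < (long)H * W; ++p) {
    int j0 = (int)(p / H), i0 = (int)(p % H);
    if (mask(i0, j0) == 0 || lab(i0, j0) != 0) continue;
    ++next;
    lab(i0, j0) = next;
    stack.clear();
    stack.push_back(p);
    while (!stack.empty()) {
      long q = stack.back();
      stack.pop_back();
      int j = (int)(q / H), i = (int)(q % H);
      for (int t = 0; t < nn; ++t) {
        int ii = i + DR[t], jj = j + DC[t];
        if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
        if (mask(ii, jj) != 0 && lab(ii, jj) == 0) {
          lab(ii, jj) = next;
          stack.push_back((long)jj * H + ii);
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}

// Regional maxima of a distance map with ImageJ-style tolerance merging:
// candidates are visited in decreasing (value, -index) order; each floods
// the connected region within `tolerance` of its peak; a flood that touches
// an already-claimed (higher) region is merged and yields no seed.
// Returns the number of seeds, a map labeling each seed's peak plateau,
// and plateau centroids (x = column, y = row, 1-based).
// [[Rcpp::export]]
List cpp_find_seeds(const NumericMatrix& edm, double tolerance) {
  const int H = edm.nrow(), W = edm.ncol();
  const long N = (long)H * W;
  const double eps = 1e-9;
  std::vector<long> order;
  order.reserve(N / 4);
  for (long p = 0; p < N; ++p)
    if (edm[p] > 0) order.push_back(p);
  std::stable_sort(order.begin(), order.end(), [&](long a, long b) {
    if (edm[a] != edm[b]) return edm[a] > edm[b];
    return a < b;
  });
  std::vector<char> visited(N, 0);
  std::vector<int> stamp(N, 0);
  IntegerMatrix seed_map(H, W);
  std::vector<double> cx, cy;
  std::vector<long> region, stack;
  int iter = 0, nseeds = 0;
  const int dr8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dc8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  for (long p : order) {
    if (visited[p]) continue;
    ++iter;
    const double v = edm[p];
    bool merged = false;
    region.clear();
    stack.clear();
    stack.push_back(p);
    stamp[p] = iter;
    while (!stack.empty()) {
      long q = stack.back();
      stack.pop_back();
      region.push_back(q);
      int j = (int)(q / H), i = (int)(q % H);
      for (int t = 0; t < 8; ++t) {
        int ii = i + dr8[t], jj = j + dc8[t];
        if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
        long q2 = (long)jj * H + ii;
        if (edm[q2] <= 0 || edm[q2] < v - tolerance - eps) continue;
        if (visited[q2]) {
          merged = true;  // reaches ground claimed by a higher maximum
        } else if (stamp[q2] != iter) {
          stamp[q2] = iter;
          stack.push_back(q2);
        }
      }
    }
    for (long q : region) visited[q] = 1;
    if (!merged) {
      ++nseeds;
      double sx = 0, sy = 0;
      long np = 0;
      for (long q : region)
        if (edm[q] >= v - eps) {
          seed_map[q] = nseeds;
          sx += (double)(q / H) + 1.0;
          sy += (double)(q % H) + 1.0;
          ++np;
        }
      cx.push_back(sx / np);
      cy.push_back(sy / np);
    }
  }
  NumericMatrix centroids(nseeds, 2);
  for (int s = 0; s < nseeds; ++s) {
    centroids(s, 0) = cx[s];
    centroids(s, 1) = cy[s];
  }
  colnames(centroids) = CharacterVector::create("x", "y");
  return List::create(_["n"] = nseeds, _["seed_map"] = seed_map,
                      _["centroids"] = centroids);
}

// Meyer flooding of the inverted distance map from labeled seeds.
// Highest distance floods first; ties broken by column-major index.
// A pixel adjacent to two different labels becomes a divide-line pixel
// (background in the returned map).  Returns seed-labeled regions,
// 0 = background or divide line.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(const NumericMatrix& edm,
                            const IntegerMatrix& seed_map) {
  const int H = edm.nrow(), W = edm.ncol();
  const long N = (long)H * W;
  std::vector<int> lab(N, 0);  // 0 unassigned, -1 divide line
  const int dr8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dc8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  typedef std::pair<double, long> PQE;  // (distance, -index)
  std::priority_queue<PQE> pq;
  for (long p = 0; p < N; ++p)
    if (seed_map[p] > 0) lab[p] = seed_map[p];
  for (long p = 0; p < N; ++p) {
    if (lab[p] <= 0 || edm[p] <= 0) continue;
    int j = (int)(p / H), i = (int)(p % H);
    for (int t = 0; t < 8; ++t) {
      int ii = i + dr8[t], jj = j + dc8[t];
      if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
      long q = (long)jj * H + ii;
      if (edm[q] > 0 && lab[q] == 0) pq.push(PQE(edm[q], -q));
    }
  }
  while (!pq.empty()) {
    long p = -pq.top().second;
    pq.pop();
    if (lab[p] != 0) continue;
    int j = (int)(p / H), i = (int)(p % H);
    int first = 0;
    bool conflict = false;
    for (int t = 0; t < 8; ++t) {
      int ii = i + dr8[t], jj = j + dc8[t];
      if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
      int l = lab[(long)jj * H + ii];
      if (l > 0) {
        if (first == 0)
          first = l;
        else if (l != first)
          conflict = true;
      }
    }
    if (first == 0) continue;  // stale entry
    if (conflict) {
      lab[p] = -1;
      continue;
    }
    lab[p] = first;
    for (int t = 0; t < 8; ++t) {
      int ii = i + dr8[t], jj = j + dc8[t];
      if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
      long q = (long)jj * H + ii;
      if (edm[q] > 0 && lab[q] == 0) pq.push(PQE(edm[q], -q));
    }
  }
  // mop up foreground pixels walled off by divide lines
  bool changed = true;
  while (changed) {
    changed = false;
    for (long p = 0; p < N; ++p) {
      if (lab[p] != 0 || edm[p] <= 0) continue;
      int j = (int)(p / H), i = (int)(p % H);
      int first = 0;
      bool conflict = false;
      for (int t = 0; t < 8; ++t) {
        int ii = i + dr8[t], jj = j + dc8[t];
        if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
        int l = lab[(long)jj * H + ii];
        if (l > 0) {
          if (first == 0)
            first = l;
          else if (l != first)
            conflict = true;
        }
      }
      if (first > 0 && !conflict) {
        lab[p] = first;
        changed = true;
      }
    }
  }
  IntegerMatrix out(H, W);
  for (long p = 0; p < N; ++p) out[p] = lab[p] > 0 ? lab[p] : 0;
  return out;
}

// Freeman chain-code perimeter of each label's outer contour, by Moore
// neighbour tracing with Jacob's stopping criterion.  Orthogonal step = 1,
// diagonal = sqrt(2).  A single-pixel object has perimeter 0.
// [[Rcpp::export]]
NumericVector cpp_perimeters(const IntegerMatrix& lab, int nlab) {
  const int H = lab.nrow(), W = lab.ncol();
  // clockwise Moore neighbourhood starting East, in (dr, dc) image terms
  const int dr[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  const int dc[8] = {1, 1, 0, -1, -1, -1, 0, 1};
  NumericVector per(nlab);
  std::vector<long> start(nlab + 1, -1);
  for (long p = 0; p < (long)H * W; ++p) {
    int l = lab[p];
    if (l > 0 && start[l] < 0) start[l] = p;
  }
  const double SQ2 = std::sqrt(2.0);
  for (int l = 1; l <= nlab; ++l) {
    long s = start[l];
    if (s < 0) continue;
    int si = (int)(s % H), sj = (int)(s / H);
    // entering direction: the West neighbour of the first scan pixel is
    // guaranteed outside the object (column-major scan order)
    int ci = si, cj = sj;
    int bdir = 4;  // direction from current pixel to its backtrack (West)
    double total = 0.0;
    long steps = 0, maxsteps = 8L * H * W;
    int seci = -1, secj = -1;  // second contour pixel (first move target)
    bool isolated = true;
    for (int t = 0; t < 8; ++t) {
      int ii = si + dr[t], jj = sj + dc[t];
      if (ii >= 0 && ii < H && jj >= 0 && jj < W && lab(ii, jj) == l)
        isolated = false;
    }
    if (isolated) {
      per[l - 1] = 0.0;
      continue;
    }
    while (steps++ < maxsteps) {
      int found = -1;
      for (int k = 1; k <= 8; ++k) {
        int d = (bdir + k) % 8;
        int ii = ci + dr[d], jj = cj + dc[d];
        if (ii >= 0 && ii < H && jj >= 0 && jj < W && lab(ii, jj) == l) {
          found = d;
          break;
        }
      }
      if (found < 0) break;  // cannot happen for non-isolated objects
      int ni = ci + dr[found], nj = cj + dc[found];
      // stop when the opening move start->second is about to repeat
      if (ci == si && cj == sj && ni == seci && nj == secj) break;
      total += (found % 2 == 0) ? 1.0 : SQ2;
      if (seci < 0) {
        seci = ni;
        secj = nj;
      }
      // new backtrack: the last background neighbour examined before the
      // move, seen from the new pixel
      int prevd = (found + 7) % 8;
      int pi = ci + dr[prevd], pj = cj + dc[prevd];
      int nbdir = (found + 4) % 8;  // fallback: straight back
      for (int t = 0; t < 8; ++t) {
        if (ni + dr[t] == pi && nj + dc[t] == pj) {
          nbdir = t;
          break;
        }
      }
      ci = ni;
      cj = nj;
      bdir = nbdir;
    }
    per[l - 1] = total;
  }
  return per;
}
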