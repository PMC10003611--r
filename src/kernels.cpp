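#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Pixel kernels shared by the preprocessing, segmentation and skeleton
// modules. Matrices are R column-major; loops index (row i, col j).
// "Raster-scan order" throughout means left-to-right, top-to-bottom.

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// ---- 3x3 median (despeckle), edge replication --------------------------

// [[Rcpp::export]]
NumericMatrix cpp_median3x3(NumericMatrix img) {
  int h = img.nrow(), w = img.ncol();
  NumericMatrix out(h, w);
  double buf[9];
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      int k = 0;
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di)
          buf[k++] = img(clampi(i + di, 0, h - 1), clampi(j + dj, 0, w - 1));
      std::nth_element(buf, buf + 4, buf + 9);
      out(i, j) = buf[4];
    }
  }
  return out;
}

// ---- disk-median outlier replacement -----------------------------------
// Disk = pixels with centre distance <= radius (centre included). Median of
// an even count is the mean of the two middle order statistics. Edges by
// replication. polarity +1: replace when pixel - median > threshold
// (bright outliers); -1: median - pixel > threshold.

// [[Rcpp::export]]
NumericMatrix cpp_remove_outliers(NumericMatrix img, double radius,
                                  double threshold, int polarity) {
  int h = img.nrow(), w = img.ncol();
  std::vector<int> di, dj;
  int r = (int)std::floor(radius);
  for (int a = -r; a <= r; ++a)
    for (int b = -r; b <= r; ++b)
      if ((double)(a * a + b * b) <= radius * radius) {
        di.push_back(a);
        dj.push_back(b);
      }
  int n = (int)di.size();
  std::vector<double> buf(n);
  NumericMatrix out(h, w);
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      for (int k = 0; k < n; ++k)
        buf[k] = img(clampi(i + di[k], 0, h - 1), clampi(j + dj[k], 0, w - 1));
      double med;
      int m = n / 2;
      std::nth_element(buf.begin(), buf.begin() + m, buf.end());
      med = buf[m];
      if (n % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + m);
        med = (med + lo) / 2.0;
      }
      double v = img(i, j);
      double dev = polarity > 0 ? v - med : med - v;
      out(i, j) = dev > threshold ? med : v;
    }
  }
  return out;
}

// ---- binary morphology, 3x3 square SE ----------------------------------
// Dilation treats out-of-image as background, erosion as foreground, so the
// derived closing is extensive and idempotent at the borders.

// [[Rcpp::export]]
IntegerMatrix cpp_dilate3x3(IntegerMatrix m) {
  int h = m.nrow(), w = m.ncol();
  IntegerMatrix out(h, w);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      int v = 0;
      for (int dj = -1; dj <= 1 && !v; ++dj)
        for (int di = -1; di <= 1; ++di) {
          int ii = i + di, jj = j + dj;
          if (ii >= 0 && ii < h && jj >= 0 && jj < w && m(ii, jj)) {
            v = 1;
            break;
          }
        }
      out(i, j) = v;
    }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_erode3x3(IntegerMatrix m) {
  int h = m.nrow(), w = m.ncol();
  IntegerMatrix out(h, w);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      int v = 1;
      for (int dj = -1; dj <= 1 && v; ++dj)
        for (int di = -1; di <= 1; ++di) {
          int ii = i + di, jj = j + dj;
          if (ii >= 0 && ii < h && jj >= 0 && jj < w && !m(ii, jj)) {
            v = 0;
            break;
          }
        }
      out(i, j) = v;
    }
  return out;
}

// ---- topology helpers ---------------------------------------------------
// Ring neighbour order: N, NE, E, SE, S, SW, W, NW.
static const int RDI[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
static const int RDJ[8] = {0, 1, 1, 1, 0, -1, -1, -1};

// 8-simple lookup over the 256 ring configurations: deletion of the centre
// preserves topology iff the foreground ring cells form exactly one
// 8-connected component and the background ring cells 4-adjacent to the
// centre form exactly one 4-connected component (8-fg / 4-bg duality).
static int simple_lut[256];
static bool lut_ready = false;

static int ring_components(int cfg, bool fg, bool conn8, bool *touches4) {
  // component count among ring cells with the requested value; conn8 uses
  // chebyshev<=1 adjacency between ring offsets, else manhattan==1.
  bool cell[8];
  for (int k = 0; k < 8; ++k) cell[k] = ((cfg >> k) & 1) == (fg ? 1 : 0);
  int comp[8];
  for (int k = 0; k < 8; ++k) comp[k] = -1;
  int ncomp = 0;
  bool any4 = false;
  for (int k = 0; k < 8; ++k) {
    if (!cell[k] || comp[k] >= 0) continue;
    // BFS
    std::vector<int> st(1, k);
    comp[k] = ncomp;
    while (!st.empty()) {
      int a = st.back();
      st.pop_back();
      if (a == 0 || a == 2 || a == 4 || a == 6) any4 = true;
      for (int b = 0; b < 8; ++b) {
        if (!cell[b] || comp[b] >= 0) continue;
        int dr = RDI[a] - RDI[b], dc = RDJ[a] - RDJ[b];
        int adr = dr < 0 ? -dr : dr, adc = dc < 0 ? -dc : dc;
        bool adj = conn8 ? (adr <= 1 && adc <= 1) : (adr + adc == 1);
        if (adj) {
          comp[b] = ncomp;
          st.push_back(b);
        }
      }
    }
    ++ncomp;
  }
  if (touches4) *touches4 = any4;
  return ncomp;
}

static void build_lut() {
  for (int cfg = 0; cfg < 256; ++cfg) {
    int nfg = ring_components(cfg, true, true, NULL);
    bool bg_touch;
    // count only background components that touch a 4-neighbour of centre
    // by recomputing per component:
    bool cell[8];
    for (int k = 0; k < 8; ++k) cell[k] = ((cfg >> k) & 1) == 0;
    int comp[8];
    for (int k = 0; k < 8; ++k) comp[k] = -1;
    int nbg_touch = 0, ncomp = 0;
    for (int k = 0; k < 8; ++k) {
      if (!cell[k] || comp[k] >= 0) continue;
      std::vector<int> st(1, k);
      comp[k] = ncomp;
      bool touch = false;
      while (!st.empty()) {
        int a = st.back();
        st.pop_back();
        if (a == 0 || a == 2 || a == 4 || a == 6) touch = true;
        for (int b = 0; b < 8; ++b) {
          if (!cell[b] || comp[b] >= 0) continue;
          int dr = RDI[a] - RDI[b], dc = RDJ[a] - RDJ[b];
          int adr = dr < 0 ? -dr : dr, adc = dc < 0 ? -dc : dc;
          if (adr + adc == 1) {
            comp[b] = ncomp;
            st.push_back(b);
          }
        }
      }
      if (touch) ++nbg_touch;
      ++ncomp;
    }
    bg_touch = nbg_touch == 1;
    simple_lut[cfg] = (nfg == 1 && bg_touch) ? 1 : 0;
  }
  lut_ready = true;
}

static inline int ring_cfg(const IntegerMatrix &m, int i, int j) {
  int h = m.nrow(), w = m.ncol(), cfg = 0;
  for (int k = 0; k < 8; ++k) {
    int ii = i + RDI[k], jj = j + RDJ[k];
    if (ii >= 0 && ii < h && jj >= 0 && jj < w && m(ii, jj)) cfg |= (1 << k);
  }
  return cfg;
}

static inline int popcount8(int cfg) {
  int n = 0;
  for (int k = 0; k < 8; ++k) n += (cfg >> k) & 1;
  return n;
}

// ---- topology-preserving thinning --------------------------------------
// Two-subiteration scheme: candidates are marked on the frozen image with
// the classic conditions (2 <= B(p) <= 6, crossing number A(p) == 1, and
// the alternating directional products), then deleted sequentially, each
// deletion re-checked against the current image with the 8-simple lookup
// and an endpoint guard. Marking on the frozen image stops deletions from
// cascading along a curve within one pass; the sequential simple-point
// re-check makes every deletion topology-preserving (in particular an
// isolated 2x2 square shrinks to a 2-pixel component instead of
// vanishing, which pure parallel application would allow).

// number of 0->1 transitions in the circular ring sequence
static inline int crossings8(int cfg) {
  int a = 0;
  for (int k = 0; k < 8; ++k) {
    int cur = (cfg >> k) & 1, nxt = (cfg >> ((k + 1) % 8)) & 1;
    if (cur == 0 && nxt == 1) ++a;
  }
  return a;
}

// [[Rcpp::export]]
IntegerMatrix cpp_thin(IntegerMatrix mask) {
  if (!lut_ready) build_lut();
  int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix m = clone(mask);
  std::vector<int> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      cand.clear();
      for (int i = 0; i < h; ++i) {
        for (int j = 0; j < w; ++j) {
          if (!m(i, j)) continue;
          int cfg = ring_cfg(m, i, j);
          int b = popcount8(cfg);
          if (b < 2 || b > 6) continue;
          if (crossings8(cfg) != 1) continue;
          // ring bits: 0 N, 2 E, 4 S, 6 W
          int n = (cfg >> 0) & 1, e = (cfg >> 2) & 1;
          int s = (cfg >> 4) & 1, we = (cfg >> 6) & 1;
          bool ok = sub == 0 ? ((n & e & s) == 0 && (e & s & we) == 0)
                             : ((n & e & we) == 0 && (n & s & we) == 0);
          if (ok) cand.push_back(i * w + j);
        }
      }
      // No endpoint guard here: true arm tips (B == 1 in the frozen
      // image) were never marked, while staircase bumps whose support was
      // deleted earlier in this pass should die with it - keeping them
      // would seed one spur branch per boundary bump.
      for (size_t k = 0; k < cand.size(); ++k) {
        int i = cand[k] / w, j = cand[k] % w;
        int cfg = ring_cfg(m, i, j);
        if (simple_lut[cfg]) {
          m(i, j) = 0;
          changed = true;
        }
      }
    }
  }
  // Staircase simplification: the subiteration scheme leaves redundant
  // corner pixels on shallow curves (both the orthogonal and the diagonal
  // step survive), and those make their neighbours look like junctions,
  // shredding an arm into strings of 1-2 px "branches". On the now-thin
  // skeleton, deleting every 8-simple non-endpoint pixel converges to a
  // minimally 8-connected curve: mid-line pixels (two non-adjacent
  // neighbours) and true junction centres are not simple, so only the
  // redundant corners die.
  bool simplify = true;
  while (simplify) {
    simplify = false;
    for (int i = 0; i < h; ++i)
      for (int j = 0; j < w; ++j) {
        if (!m(i, j)) continue;
        int cfg = ring_cfg(m, i, j);
        if (popcount8(cfg) >= 2 && simple_lut[cfg]) {
          m(i, j) = 0;
          simplify = true;
        }
      }
  }
  // Residual 2x2 blocks. Usually one pixel of the block is simple and can
  // just be deleted. The irreducible case is a diagonal X-crossing: four
  // arms attached at the four corners, where deleting any corner would
  // disconnect its arm. That is repaired by rewiring: delete one corner
  // and re-add the orthogonal bridge pixel (taken from the original mask,
  // so the skeleton stays a subset of it) that reconnects the arm, then
  // re-run the corner simplification.
  for (int round = 0; round < 32; ++round) {
    bool any_block = false, progress = false;
    for (int i = 0; i + 1 < h; ++i) {
      for (int j = 0; j + 1 < w; ++j) {
        if (!(m(i, j) && m(i + 1, j) && m(i, j + 1) && m(i + 1, j + 1)))
          continue;
        any_block = true;
        const int ci[4] = {i, i + 1, i, i + 1};
        const int cj[4] = {j, j, j + 1, j + 1};
        bool done = false;
        for (int k = 0; k < 4 && !done; ++k) {
          int cfg = ring_cfg(m, ci[k], cj[k]);
          if (popcount8(cfg) >= 2 && simple_lut[cfg]) {
            m(ci[k], cj[k]) = 0;
            progress = done = true;
          }
        }
        if (done) continue;
        // stuck: rewire a corner whose only outside neighbour is its
        // outward diagonal arm pixel
        for (int k = 0; k < 4 && !done; ++k) {
          int a = ci[k], b = cj[k];
          int odi = (a == i) ? -1 : 1, odj = (b == j) ? -1 : 1;
          int pi = a + odi, pj = b + odj;
          if (!(pi >= 0 && pi < h && pj >= 0 && pj < w && m(pi, pj)))
            continue;
          // outside neighbours of the corner other than p must be empty
          bool clean = true;
          for (int t = 0; t < 8; ++t) {
            int ii = a + RDI[t], jj = b + RDJ[t];
            if (ii < 0 || ii >= h || jj < 0 || jj >= w) continue;
            bool inblock = ii >= i && ii <= i + 1 && jj >= j && jj <= j + 1;
            if (!inblock && m(ii, jj) && !(ii == pi && jj == pj))
              clean = false;
          }
          if (!clean) continue;
          // bridge candidates: orthogonal neighbours of the corner that
          // touch both p and the rest of the block
          const int bri[2] = {a + odi, a};
          const int brj[2] = {b, b + odj};
          for (int t = 0; t < 2 && !done; ++t) {
            int xi = bri[t], xj = brj[t];
            if (xi >= 0 && xi < h && xj >= 0 && xj < w && !m(xi, xj) &&
                mask(xi, xj)) {
              m(a, b) = 0;
              m(xi, xj) = 1;
              progress = done = true;
            }
          }
        }
      }
    }
    if (!any_block) break;
    if (!progress) break;
    // re-run corner simplification after any rewiring
    bool s2 = true;
    while (s2) {
      s2 = false;
      for (int i2 = 0; i2 < h; ++i2)
        for (int j2 = 0; j2 < w; ++j2) {
          if (!m(i2, j2)) continue;
          int cfg = ring_cfg(m, i2, j2);
          if (popcount8(cfg) >= 2 && simple_lut[cfg]) {
            m(i2, j2) = 0;
            s2 = true;
          }
        }
    }
  }
  return m;
}

// ---- 8-connected component labelling, raster-scan label order ----------

// [[Rcpp::export]]
IntegerMatrix cpp_label8(IntegerMatrix mask) {
  int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  int next = 0;
  std::vector<std::pair<int, int> > st;
  for (int i = 0; i < h; ++i) {
    for (int j = 0; j < w; ++j) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      lab(i, j) = next;
      st.clear();
      st.push_back(std::make_pair(i, j));
      while (!st.empty()) {
        std::pair<int, int> p = st.back();
        st.pop_back();
        for (int k = 0; k < 8; ++k) {
          int ii = p.first + RDI[k], jj = p.second + RDJ[k];
          if (ii >= 0 && ii < h && jj >= 0 && jj < w && mask(ii, jj) &&
              !lab(ii, jj)) {
            lab(ii, jj) = next;
            st.push_back(std::make_pair(ii, jj));
          }
        }
      }
    }
  }
  return lab;
}

// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_count8(IntegerMatrix mask) {
  int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix out(h, w);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      if (!mask(i, j)) continue;
      int n = 0;
      for (int k = 0; k < 8; ++k) {
        int ii = i + RDI[k], jj = j + RDJ[k];
        if (ii >= 0 && ii < h && jj >= 0 && jj < w && mask(ii, jj)) ++n;
      }
      out(i, j) = n;
    }
  return out;
}

// ---- separable Gaussian blur, edge replication -------------------------

// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(NumericMatrix img, double sigma) {
  int h = img.nrow(), w = img.ncol();
  int r = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int a = -r; a <= r; ++a) {
    k[a + r] = std::exp(-0.5 * a * a / (sigma * sigma));
    s += k[a + r];
  }
  for (int a = 0; a < 2 * r + 1; ++a) k[a] /= s;
  NumericMatrix tmp(h, w), out(h, w);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      double v = 0;
      for (int a = -r; a <= r; ++a)
        v += k[a + r] * img(clampi(i + a, 0, h - 1), j);
      tmp(i, j) = v;
    }
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      double v = 0;
      for (int a = -r; a <= r; ++a)
        v += k[a + r] * tmp(i, clampi(j + a, 0, w - 1));
      out(i, j) = v;
    }
  return out;
}
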