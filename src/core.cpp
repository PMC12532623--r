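#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Descriptors are stored column-wise: one column of raw bytes per keypoint.
// Byte/bit order follows R's packBits() (bit i of the descriptor lives in
// byte i/8, least-significant bit first); Hamming distance is order-agnostic.

static inline int popcount8(unsigned char x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcount((unsigned int)x);
#else
  int n = 0;
  while (x) { n += x & 1; x >>= 1; }
  return n;
#endif
}

// [[Rcpp::export]]
IntegerMatrix hamming_matrix_cpp(RawMatrix q, RawMatrix t) {
  const int nb = q.nrow();
  if (t.nrow() != nb) stop("descriptor byte lengths differ");
  const int nq = q.ncol(), nt = t.ncol();
  IntegerMatrix out(nq, nt);
  for (int j = 0; j < nt; ++j) {
    const Rbyte* tj = &t(0, j);
    for (int i = 0; i < nq; ++i) {
      const Rbyte* qi = &q(0, i);
      int d = 0;
      for (int b = 0; b < nb; ++b) d += popcount8((unsigned char)(qi[b] ^ tj[b]));
      out(i, j) = d;
    }
  }
  return out;
}

// Nearest target per query; ties resolved to the lowest target index.
// [[Rcpp::export]]
List bf_match_cpp(RawMatrix q, RawMatrix t) {
  const int nb = q.nrow();
  if (t.nrow() != nb) stop("descriptor byte lengths differ");
  const int nq = q.ncol(), nt = t.ncol();
  IntegerVector idx(nq), dist(nq);
  for (int i = 0; i < nq; ++i) {
    const Rbyte* qi = &q(0, i);
    int best = -1, bestd = nb * 8 + 1;
    for (int j = 0; j < nt; ++j) {
      const Rbyte* tj = &t(0, j);
      int d = 0;
      for (int b = 0; b < nb; ++b) d += popcount8((unsigned char)(qi[b] ^ tj[b]));
      if (d < bestd) { bestd = d; best = j; }
    }
    idx[i] = best + 1;
    dist[i] = bestd;
  }
  return List::create(_["target"] = idx, _["distance"] = dist);
}

// One explicit diffusion step in conservative (flux) form with zero-flux
// (Neumann) boundaries; conductivity at half-points is the arithmetic mean.
// [[Rcpp::export]]
NumericMatrix fed_step_cpp(NumericMatrix L, NumericMatrix g, double tau) {
  const int nr = L.nrow(), nc = L.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const double Lc = L(i, j), gc = g(i, j);
      double flux = 0.0;
      if (i + 1 < nr) flux += 0.5 * (gc + g(i + 1, j)) * (L(i + 1, j) - Lc);
      if (i - 1 >= 0) flux += 0.5 * (gc + g(i - 1, j)) * (L(i - 1, j) - Lc);
      if (j + 1 < nc) flux += 0.5 * (gc + g(i, j + 1)) * (L(i, j + 1) - Lc);
      if (j - 1 >= 0) flux += 0.5 * (gc + g(i, j - 1)) * (L(i, j - 1) - Lc);
      out(i, j) = Lc + tau * flux;
    }
  }
  return out;
}

// FAST segment test on the 16-pixel Bresenham circle of radius 3.
// Returns the corner score image: 0 where the arc test fails, otherwise the
// sum of |I(c)-I(p)| over all circle pixels satisfying the detected polarity,
// accumulated in circle-index order. Border of width 3 is never a corner.
static const int CIRC_DY[16] = {-3, -3, -2, -1, 0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3};
static const int CIRC_DX[16] = {0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3, -3, -3, -2, -1};

// [[Rcpp::export]]
NumericMatrix fast_score_cpp(NumericMatrix img, double t, int n_contig) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  double c[16];
  for (int j = 3; j < nc - 3; ++j) {
    for (int i = 3; i < nr - 3; ++i) {
      const double v = img(i, j);
      bool bright[16], dark[16];
      for (int k = 0; k < 16; ++k) {
        c[k] = img(i + CIRC_DY[k], j + CIRC_DX[k]);
        bright[k] = c[k] > v + t;
        dark[k] = c[k] < v - t;
      }
      bool is_bright = false, is_dark = false;
      int run = 0;
      for (int k = 0; k < 16 + n_contig && !is_bright; ++k) {
        if (bright[k % 16]) { if (++run >= n_contig) is_bright = true; }
        else run = 0;
      }
      run = 0;
      for (int k = 0; k < 16 + n_contig && !is_dark; ++k) {
        if (dark[k % 16]) { if (++run >= n_contig) is_dark = true; }
        else run = 0;
      }
      if (is_bright || is_dark) {
        double s = 0.0;
        for (int k = 0; k < 16; ++k) {
          if (is_bright ? bright[k] : dark[k]) s += std::abs(c[k] - v);
        }
        out(i, j) = s;
      }
    }
  }
  return out;
}

// 4-connected labelling of a logical mask; labels are 1..K in scan order of
// each component's first-encountered pixel (column-major, as R stores).
// [[Rcpp::export]]
IntegerMatrix label4_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.clear();
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pi = p % nr, pj = p / nr;
        const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          const int qi = pi + di[k], qj = pj + dj[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) && !lab(qi, qj)) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  return lab;
}
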