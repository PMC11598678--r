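// Small image-processing kernels. Matrices follow R's column-major layout;
// (i, j) = (row, col). Borders are handled by symmetric reflection.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static inline int reflect(int i, int n) {
  // symmetric (edge-inclusive) reflection: -1 -> 0, n -> n-1
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix X, int k) {
  const int H = X.nrow(), W = X.ncol(), r = k / 2;
  NumericMatrix Y(H, W);
  std::vector<double> buf((size_t)k * k);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      size_t m = 0;
      for (int dj = -r; dj <= r; ++dj) {
        const int jj = reflect(j + dj, W);
        for (int di = -r; di <= r; ++di)
          buf[m++] = X(reflect(i + di, H), jj);
      }
      std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
      double med = buf[m / 2];
      if (m % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + m / 2);
        med = (med + lo) / 2.0;
      }
      Y(i, j) = med;
    }
  return Y;
}

// Separable correlation with a centred odd-length 1-D kernel, rows then cols.
// [[Rcpp::export]]
NumericMatrix cpp_sepconv_reflect(NumericMatrix X, NumericVector kr,
                                  NumericVector kc) {
  const int H = X.nrow(), W = X.ncol();
  const int rr = kr.size() / 2, rc = kc.size() / 2;
  NumericMatrix T(H, W), Y(H, W);
  for (int j = 0; j < W; ++j)           // vertical pass (along rows)
    for (int i = 0; i < H; ++i) {
      double s = 0;
      for (int t = -rr; t <= rr; ++t) s += kr[t + rr] * X(reflect(i + t, H), j);
      T(i, j) = s;
    }
  for (int j = 0; j < W; ++j)           // horizontal pass
    for (int i = 0; i < H; ++i) {
      double s = 0;
      for (int t = -rc; t <= rc; ++t) s += kc[t + rc] * T(i, reflect(j + t, W));
      Y(i, j) = s;
    }
  return Y;
}

// Zhang-Suen thinning of a binary mask to an 8-connected unit-width skeleton.
// [[Rcpp::export]]
IntegerMatrix cpp_thin(IntegerMatrix M) {
  const int H = M.nrow(), W = M.ncol();
  IntegerMatrix A(clone(M));
  auto at = [&](int i, int j) -> int {
    if (i < 0 || i >= H || j < 0 || j >= W) return 0;
    return A(i, j);
  };
  bool changed = true;
  std::vector<std::pair<int, int> > del;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      del.clear();
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          if (!A(i, j)) continue;
          // neighbours clockwise from north: p2..p9
          const int p2 = at(i - 1, j), p3 = at(i - 1, j + 1), p4 = at(i, j + 1),
                    p5 = at(i + 1, j + 1), p6 = at(i + 1, j),
                    p7 = at(i + 1, j - 1), p8 = at(i, j - 1),
                    p9 = at(i - 1, j - 1);
          const int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int Acnt = 0;
          const int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          for (int t = 0; t < 8; ++t)
            if (seq[t] == 0 && seq[t + 1] == 1) ++Acnt;
          if (Acnt != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          del.push_back(std::make_pair(i, j));
        }
      for (size_t t = 0; t < del.size(); ++t) A(del[t].first, del[t].second) = 0;
      if (!del.empty()) changed = true;
    }
  }
  return A;
}

// CRC-32 (PNG polynomial) of a raw vector, returned as 4 big-endian bytes.
// [[Rcpp::export]]
RawVector cpp_crc32(RawVector data) {
  static uint32_t tab[256];
  static bool init = false;
  if (!init) {
    for (uint32_t n = 0; n < 256; ++n) {
      uint32_t c = n;
      for (int k = 0; k < 8; ++k)
        c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : (c >> 1);
      tab[n] = c;
    }
    init = true;
  }
  uint32_t c = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    c = tab[(c ^ data[i]) & 0xFF] ^ (c >> 8);
  c ^= 0xFFFFFFFFu;
  RawVector out(4);
  out[0] = (c >> 24) & 0xFF; out[1] = (c >> 16) & 0xFF;
  out[2] = (c >> 8) & 0xFF;  out[3] = c & 0xFF;
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_bilinear_resize(NumericMatrix X, int oh, int ow) {
  const int H = X.nrow(), W = X.ncol();
  NumericMatrix Y(oh, ow);
  const double si = (double)H / oh, sj = (double)W / ow;
  for (int j = 0; j < ow; ++j) {
    double fj = (j + 0.5) * sj - 0.5;
    int j0 = (int)std::floor(fj);
    double wj = fj - j0;
    int j0c = std::min(std::max(j0, 0), W - 1);
    int j1c = std::min(std::max(j0 + 1, 0), W - 1);
    for (int i = 0; i < oh; ++i) {
      double fi = (i + 0.5) * si - 0.5;
      int i0 = (int)std::floor(fi);
      double wi = fi - i0;
      int i0c = std::min(std::max(i0, 0), H - 1);
      int i1c = std::min(std::max(i0 + 1, 0), H - 1);
      Y(i, j) = (1 - wi) * ((1 - wj) * X(i0c, j0c) + wj * X(i0c, j1c)) +
                wi * ((1 - wj) * X(i1c, j0c) + wj * X(i1c, j1c));
    }
  }
  return Y;
}
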