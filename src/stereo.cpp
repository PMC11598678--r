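// AD-Census stereo kernels: census transform, combined cost volume,
// adaptive cross construction (single-threshold and two-tier rules) and
// cross-based cost aggregation. Intensities are on the 0-255 scale.
// Disparity d matches left pixel (r, c) with right pixel (r, c - d).
#include <Rcpp.h>
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

// Census bit strings packed into two 64-bit words per pixel (windows up to
// 129 neighbours). Bit order: window rows top to bottom, columns left to
// right within a row, centre skipped; bit = 1 iff neighbour < centre.
static void census_pack(const NumericMatrix& X, int wh, int ww,
                        std::vector<uint64_t>& lo, std::vector<uint64_t>& hi) {
  const int H = X.nrow(), W = X.ncol(), rh = wh / 2, rw = ww / 2;
  lo.assign((size_t)H * W, 0);
  hi.assign((size_t)H * W, 0);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const double ctr = X(i, j);
      uint64_t a = 0, b = 0;
      int bit = 0;
      for (int di = -rh; di <= rh; ++di)
        for (int dj = -rw; dj <= rw; ++dj) {
          if (di == 0 && dj == 0) continue;
          const double v = X(reflect(i + di, H), reflect(j + dj, W));
          if (v < ctr) {
            if (bit < 64) a |= (uint64_t)1 << bit;
            else b |= (uint64_t)1 << (bit - 64);
          }
          ++bit;
        }
      lo[(size_t)j * H + i] = a;
      hi[(size_t)j * H + i] = b;
    }
}

static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int n = 0;
  while (x) { x &= x - 1; ++n; }
  return n;
#endif
}

// [[Rcpp::export]]
IntegerVector cpp_census(NumericMatrix X, int wh, int ww) {
  const int H = X.nrow(), W = X.ncol(), nb = wh * ww - 1;
  std::vector<uint64_t> lo, hi;
  census_pack(X, wh, ww, lo, hi);
  IntegerVector out(Rcpp::no_init((size_t)H * W * nb));
  out.attr("dim") = IntegerVector::create(H, W, nb);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const uint64_t a = lo[(size_t)j * H + i], b = hi[(size_t)j * H + i];
      for (int t = 0; t < nb; ++t) {
        const int bit = t < 64 ? (int)((a >> t) & 1) : (int)((b >> (t - 64)) & 1);
        out[((size_t)t * W + j) * H + i] = bit;
      }
    }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_cost_volume(NumericMatrix L, NumericMatrix R,
                              int wh, int ww, NumericMatrix alpha,
                              double lambda_ad, double lambda_c,
                              int dmin, int dmax) {
  const int H = L.nrow(), W = L.ncol(), D = dmax - dmin + 1;
  std::vector<uint64_t> cl, ch, rl, rh;
  census_pack(L, wh, ww, cl, ch);
  census_pack(R, wh, ww, rl, rh);
  NumericVector V(Rcpp::no_init((size_t)H * W * D));
  V.attr("dim") = IntegerVector::create(H, W, D);
  for (int t = 0; t < D; ++t) {
    const int d = dmin + t;
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const size_t o = ((size_t)t * W + j) * H + i;
        const int q = j - d;
        if (q < 0 || q >= W) { V[o] = 1.0; continue; }
        const double cad = std::abs(L(i, j) - R(i, q));
        const int ham =
            popcount64(cl[(size_t)j * H + i] ^ rl[(size_t)q * H + i]) +
            popcount64(ch[(size_t)j * H + i] ^ rh[(size_t)q * H + i]);
        const double a = alpha(i, j);
        V[o] = a * (1.0 - std::exp(-cad / lambda_ad)) +
               (1.0 - a) * (1.0 - std::exp(-ham / lambda_c));
      }
  }
  return V;
}

// Arm extension in one direction. Single-threshold rule: candidate at
// distance e qualifies iff e < L and |I(p) - I(p')| < tau. Two-tier rule:
// near tier e <= L2 uses tau1, far tier L2 < e <= L1 uses tau2; both tiers
// also bound the consecutive difference |I(p') - I(p'')| with the tier
// threshold, where p'' is one further step (skipped at the image border).
static int arm_extent(const NumericMatrix& X, int i, int j, int di, int dj,
                      bool optimized, int L, double tau,
                      int L1, int L2, double tau1, double tau2) {
  const int H = X.nrow(), W = X.ncol();
  const double ctr = X(i, j);
  int ext = 0;
  const int emax = optimized ? L1 : (L - 1);
  for (int e = 1; e <= emax; ++e) {
    const int ii = i + e * di, jj = j + e * dj;
    if (ii < 0 || ii >= H || jj < 0 || jj >= W) break;
    const double v = X(ii, jj);
    bool ok;
    if (!optimized) {
      ok = std::abs(ctr - v) < tau;
    } else {
      const double th = (e <= L2) ? tau1 : tau2;
      ok = std::abs(ctr - v) < th;
      const int i2 = ii + di, j2 = jj + dj;
      if (ok && i2 >= 0 && i2 < H && j2 >= 0 && j2 < W)
        ok = std::abs(v - X(i2, j2)) < th;
    }
    if (!ok) break;
    ext = e;
  }
  return ext;
}

// [[Rcpp::export]]
List cpp_build_cross(NumericMatrix X, bool optimized, int L, double tau,
                     int L1, int L2, double tau1, double tau2) {
  const int H = X.nrow(), W = X.ncol();
  IntegerMatrix al(H, W), ar(H, W), au(H, W), ad(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      al(i, j) = arm_extent(X, i, j, 0, -1, optimized, L, tau, L1, L2, tau1, tau2);
      ar(i, j) = arm_extent(X, i, j, 0, +1, optimized, L, tau, L1, L2, tau1, tau2);
      au(i, j) = arm_extent(X, i, j, -1, 0, optimized, L, tau, L1, L2, tau1, tau2);
      ad(i, j) = arm_extent(X, i, j, +1, 0, optimized, L, tau, L1, L2, tau1, tau2);
    }
  return List::create(_["left"] = al, _["right"] = ar,
                      _["up"] = au, _["down"] = ad);
}

// One aggregation pass over the cost volume. The support region of p at
// disparity d combines p's cross in the left image with the matched pixel
// q's cross in the right image (per-direction minimum); where q is out of
// frame the left cross alone is used. Aggregation is the exact mean over
// the region: horizontal-first sums each pixel's horizontal arm span, then
// sums those sums over the vertical arm span (vertical-first transposes
// the order), with pixel counts propagated for normalisation.
// [[Rcpp::export]]
NumericVector cpp_cbca_pass(NumericVector V, List armsL, List armsR,
                            int dmin, bool horizontal_first) {
  IntegerVector dm = V.attr("dim");
  const int H = dm[0], W = dm[1], D = dm[2];
  IntegerMatrix Ll = armsL["left"], Lr = armsL["right"], Lu = armsL["up"],
                Ld = armsL["down"];
  IntegerMatrix Rl = armsR["left"], Rr = armsR["right"], Ru = armsR["up"],
                Rd = armsR["down"];
  NumericVector out(Rcpp::no_init(V.size()));
  out.attr("dim") = dm;
  std::vector<double> S1((size_t)H * W), N1((size_t)H * W);
  std::vector<int> el((size_t)H * W), er((size_t)H * W), eu((size_t)H * W),
      ed((size_t)H * W);
  for (int t = 0; t < D; ++t) {
    const int d = dmin + t;
    const double* Vp = V.begin() + (size_t)t * H * W;
    double* Op = out.begin() + (size_t)t * H * W;
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const size_t o = (size_t)j * H + i;
        const int q = j - d;
        if (q >= 0 && q < W) {
          el[o] = std::min(Ll(i, j), Rl(i, q));
          er[o] = std::min(Lr(i, j), Rr(i, q));
          eu[o] = std::min(Lu(i, j), Ru(i, q));
          ed[o] = std::min(Ld(i, j), Rd(i, q));
        } else {
          el[o] = Ll(i, j); er[o] = Lr(i, j);
          eu[o] = Lu(i, j); ed[o] = Ld(i, j);
        }
      }
    if (horizontal_first) {
      // stage 1: horizontal spans via row prefix sums
      std::vector<double> pre(W + 1);
      for (int i = 0; i < H; ++i) {
        pre[0] = 0;
        for (int j = 0; j < W; ++j) pre[j + 1] = pre[j] + Vp[(size_t)j * H + i];
        for (int j = 0; j < W; ++j) {
          const size_t o = (size_t)j * H + i;
          const int a = j - el[o], b = j + er[o];
          S1[o] = pre[b + 1] - pre[a];
          N1[o] = b - a + 1;
        }
      }
      // stage 2: vertical spans of stage-1 sums
      std::vector<double> ps(H + 1), pn(H + 1);
      for (int j = 0; j < W; ++j) {
        ps[0] = pn[0] = 0;
        for (int i = 0; i < H; ++i) {
          ps[i + 1] = ps[i] + S1[(size_t)j * H + i];
          pn[i + 1] = pn[i] + N1[(size_t)j * H + i];
        }
        for (int i = 0; i < H; ++i) {
          const size_t o = (size_t)j * H + i;
          const int a = i - eu[o], b = i + ed[o];
          Op[o] = (ps[b + 1] - ps[a]) / (pn[b + 1] - pn[a]);
        }
      }
    } else {
      std::vector<double> pre(H + 1);
      for (int j = 0; j < W; ++j) {
        pre[0] = 0;
        for (int i = 0; i < H; ++i) pre[i + 1] = pre[i] + Vp[(size_t)j * H + i];
        for (int i = 0; i < H; ++i) {
          const size_t o = (size_t)j * H + i;
          const int a = i - eu[o], b = i + ed[o];
          S1[o] = pre[b + 1] - pre[a];
          N1[o] = b - a + 1;
        }
      }
      std::vector<double> ps(W + 1), pn(W + 1);
      for (int i = 0; i < H; ++i) {
        ps[0] = pn[0] = 0;
        for (int j = 0; j < W; ++j) {
          ps[j + 1] = ps[j] + S1[(size_t)j * H + i];
          pn[j + 1] = pn[j] + N1[(size_t)j * H + i];
        }
        for (int j = 0; j < W; ++j) {
          const size_t o = (size_t)j * H + i;
          const int a = j - el[o], b = j + er[o];
          Op[o] = (ps[b + 1] - ps[a]) / (pn[b + 1] - pn[a]);
        }
      }
    }
  }
  return out;
}
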