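// Dynamic-programming cores and brute-force grid scans.
//
// All matrices are dense; instances are protein-sized (m, n up to ~1000),
// so O(mn) tables are fine.  Tracebacks are fully deterministic: candidate
// moves are scanned in a fixed order (diagonal, then vertical, then
// horizontal; match state before gap states) and the first candidate
// attaining the maximum wins.

#include <Rcpp.h>
#include <cfloat>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double NEG_INF = -DBL_MAX / 4.0;

// Build the 1-based pair list from a reversed traceback stack.
static List pairs_result(std::vector<int>& pi, std::vector<int>& pj,
                         double score) {
  const int k = static_cast<int>(pi.size());
  IntegerVector ri(k), rj(k);
  for (int r = 0; r < k; ++r) {  // stacks hold pairs in reverse order
    ri[r] = pi[k - 1 - r];
    rj[r] = pj[k - 1 - r];
  }
  return List::create(_["i"] = ri, _["j"] = rj, _["score"] = score);
}

// Semi-global linear-gap DP over a precomputed score matrix.
//
// free_ends = true (default in R): maximizes sum(S over matched pairs)
//   minus gap * (number of skipped positions strictly inside the aligned
//   span, in either sequence); unmatched prefixes and suffixes of both
//   sequences are free.  Implemented with a match state M and a gap state
//   H plus a restart option, which equals the subset semantics even for
//   negative score entries.
// free_ends = false: the literal zero-boundary recurrence
//   D(i,j) = max{D(i-1,j-1)+S(i,j), D(i-1,j)-gap, D(i,j-1)-gap},
//   D(i,0) = D(0,j) = 0, answer D(m,n).
// [[Rcpp::export(name = ".dp_linear_cpp")]]
List dp_linear_cpp(NumericMatrix S, double gap, bool free_ends) {
  const int m = S.nrow(), n = S.ncol();
  if (m == 0 || n == 0)
    return List::create(_["i"] = IntegerVector(0), _["j"] = IntegerVector(0),
                        _["score"] = 0.0);
  const int W = n + 1;
  if (!free_ends) {
    std::vector<double> D((m + 1) * W, 0.0);
    std::vector<signed char> mv((m + 1) * W, 0);  // 0 diag, 1 up, 2 left
    for (int i = 1; i <= m; ++i) {
      for (int j = 1; j <= n; ++j) {
        const double diag = D[(i - 1) * W + (j - 1)] + S(i - 1, j - 1);
        const double up = D[(i - 1) * W + j] - gap;
        const double left = D[i * W + (j - 1)] - gap;
        double best = diag;
        signed char b = 0;
        if (up > best) { best = up; b = 1; }
        if (left > best) { best = left; b = 2; }
        D[i * W + j] = best;
        mv[i * W + j] = b;
      }
    }
    std::vector<int> pi, pj;
    int i = m, j = n;
    while (i > 0 && j > 0) {
      const signed char b = mv[i * W + j];
      if (b == 0) { pi.push_back(i); pj.push_back(j); --i; --j; }
      else if (b == 1) --i;
      else --j;
    }
    return pairs_result(pi, pj, D[m * W + n]);
  }

  // free-end variant: states M (last move is a match) and H (inside a gap).
  std::vector<double> M((m + 1) * W, NEG_INF), H((m + 1) * W, NEG_INF);
  // pm: 0 start, 1 from M diag, 2 from H diag
  // ph: 1 M-up, 2 H-up, 3 M-left, 4 H-left
  std::vector<signed char> pm((m + 1) * W, 0), ph((m + 1) * W, 0);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int id = i * W + j, di = (i - 1) * W + (j - 1);
      double bp = M[di];
      signed char b = 1;
      if (H[di] > bp) { bp = H[di]; b = 2; }
      if (0.0 > bp) { bp = 0.0; b = 0; }
      M[id] = S(i - 1, j - 1) + bp;
      pm[id] = b;
      const int up = (i - 1) * W + j, left = i * W + (j - 1);
      double hb = M[up] - gap;
      signed char hbm = 1;
      if (H[up] - gap > hb) { hb = H[up] - gap; hbm = 2; }
      if (M[left] - gap > hb) { hb = M[left] - gap; hbm = 3; }
      if (H[left] - gap > hb) { hb = H[left] - gap; hbm = 4; }
      H[id] = hb;
      ph[id] = hbm;
      if (M[id] > best) { best = M[id]; bi = i; bj = j; }
    }
  }
  std::vector<int> pi, pj;
  if (best > 0.0) {
    int i = bi, j = bj, state = 0;  // 0 = M, 1 = H
    for (;;) {
      if (state == 0) {
        pi.push_back(i); pj.push_back(j);
        const signed char b = pm[i * W + j];
        if (b == 0) break;
        state = (b == 2) ? 1 : 0;
        --i; --j;
      } else {
        const signed char b = ph[i * W + j];
        state = (b == 2 || b == 4) ? 1 : 0;
        if (b <= 2) --i; else --j;
      }
    }
  }
  return pairs_result(pi, pj, best > 0.0 ? best : 0.0);
}

// Semi-global affine-gap (Gotoh) DP: a run of g skipped positions strictly
// inside the aligned span costs open + (g - 1) * extend; end gaps free.
// States: M match, X gap run consuming sequence a, Y gap run consuming b.
// [[Rcpp::export(name = ".dp_affine_cpp")]]
List dp_affine_cpp(NumericMatrix S, double open, double extend) {
  const int m = S.nrow(), n = S.ncol();
  if (m == 0 || n == 0)
    return List::create(_["i"] = IntegerVector(0), _["j"] = IntegerVector(0),
                        _["score"] = 0.0);
  const int W = n + 1;
  std::vector<double> M((m + 1) * W, NEG_INF), X((m + 1) * W, NEG_INF),
      Y((m + 1) * W, NEG_INF);
  // pm: 0 start, 1 M, 2 X, 3 Y (predecessor at diag)
  // px: 1 M-up, 2 X-up, 3 Y-up;  py: 1 M-left, 2 Y-left, 3 X-left
  std::vector<signed char> pm((m + 1) * W, 0), px((m + 1) * W, 0),
      py((m + 1) * W, 0);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int id = i * W + j, di = (i - 1) * W + (j - 1);
      const int up = (i - 1) * W + j, left = i * W + (j - 1);
      double bp = M[di];
      signed char b = 1;
      if (X[di] > bp) { bp = X[di]; b = 2; }
      if (Y[di] > bp) { bp = Y[di]; b = 3; }
      if (0.0 > bp) { bp = 0.0; b = 0; }
      M[id] = S(i - 1, j - 1) + bp;
      pm[id] = b;

      double xb = M[up] - open;
      signed char xbm = 1;
      if (X[up] - extend > xb) { xb = X[up] - extend; xbm = 2; }
      if (Y[up] - open > xb) { xb = Y[up] - open; xbm = 3; }
      X[id] = xb;
      px[id] = xbm;

      double yb = M[left] - open;
      signed char ybm = 1;
      if (Y[left] - extend > yb) { yb = Y[left] - extend; ybm = 2; }
      if (X[left] - open > yb) { yb = X[left] - open; ybm = 3; }
      Y[id] = yb;
      py[id] = ybm;

      if (M[id] > best) { best = M[id]; bi = i; bj = j; }
    }
  }
  std::vector<int> pi, pj;
  if (best > 0.0) {
    int i = bi, j = bj, state = 0;  // 0 M, 1 X, 2 Y
    for (;;) {
      if (state == 0) {
        pi.push_back(i); pj.push_back(j);
        const signed char b = pm[i * W + j];
        if (b == 0) break;
        state = (b == 1) ? 0 : (b == 2 ? 1 : 2);
        --i; --j;
      } else if (state == 1) {
        const signed char b = px[i * W + j];
        state = (b == 1) ? 0 : (b == 2 ? 1 : 2);
        --i;
      } else {
        const signed char b = py[i * W + j];
        state = (b == 1) ? 0 : (b == 2 ? 2 : 1);
        --j;
      }
    }
  }
  return pairs_result(pi, pj, best > 0.0 ? best : 0.0);
}

static inline double dist2(const double* a, const double* b) {
  const double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return dx * dx + dy * dy + dz * dz;
}

// Count-only maximum-cardinality monotone matching with every matched pair
// within distance d.  Coordinates are row-major double[3] arrays.
static int numpairs_count(const double* A, int m, const double* B, int n,
                          double dd, std::vector<int>& D) {
  const int W = n + 1;
  if (static_cast<int>(D.size()) < (m + 1) * W) D.resize((m + 1) * W);
  for (int j = 0; j <= n; ++j) D[j] = 0;
  for (int i = 1; i <= m; ++i) {
    D[i * W] = 0;
    const double* ai = A + 3 * (i - 1);
    for (int j = 1; j <= n; ++j) {
      int best = D[(i - 1) * W + j];
      const int left = D[i * W + (j - 1)];
      if (left > best) best = left;
      if (dist2(ai, B + 3 * (j - 1)) <= dd) {
        const int diag = D[(i - 1) * W + (j - 1)] + 1;
        if (diag > best) best = diag;
      }
      D[i * W + j] = best;
    }
  }
  return D[m * W + n];
}

// Maximum-cardinality monotone matching under a distance threshold, with
// traceback (the CA <= d count for a fixed superposition).
// [[Rcpp::export(name = ".numpairs_cpp")]]
List numpairs_cpp(NumericMatrix A, NumericMatrix B, double d) {
  const int m = A.nrow(), n = B.nrow();
  const double dd = d * d;
  const int W = n + 1;
  std::vector<double> a(3 * m), b(3 * n);
  for (int i = 0; i < m; ++i)
    for (int c = 0; c < 3; ++c) a[3 * i + c] = A(i, c);
  for (int j = 0; j < n; ++j)
    for (int c = 0; c < 3; ++c) b[3 * j + c] = B(j, c);
  std::vector<int> D((m + 1) * W, 0);
  std::vector<signed char> mv((m + 1) * W, 1);  // 0 diag, 1 up, 2 left
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const bool ok = dist2(&a[3 * (i - 1)], &b[3 * (j - 1)]) <= dd;
      int best;
      signed char bmv;
      if (ok) {  // diagonal preferred on ties
        best = D[(i - 1) * W + (j - 1)] + 1;
        bmv = 0;
        if (D[(i - 1) * W + j] > best) { best = D[(i - 1) * W + j]; bmv = 1; }
      } else {
        best = D[(i - 1) * W + j];
        bmv = 1;
      }
      if (D[i * W + (j - 1)] > best) { best = D[i * W + (j - 1)]; bmv = 2; }
      D[i * W + j] = best;
      mv[i * W + j] = bmv;
    }
  }
  std::vector<int> pi, pj;
  int i = m, j = n;
  while (i > 0 && j > 0) {
    const signed char b2 = mv[i * W + j];
    if (b2 == 0) { pi.push_back(i); pj.push_back(j); --i; --j; }
    else if (b2 == 1) --i;
    else --j;
  }
  return pairs_result(pi, pj, static_cast<double>(D[m * W + n]));
}

// Exhaustive scan of rotation x translation space for the threshold-pair
// count.  rots is K x 9 (row-major 3x3 rotation per row); translations run
// on a cubic grid of step tstep covering the displacement bounding box of
// the centred, rotated second structure, padded by pad on each side.
// Returns the best count, the rotation index and the winning translation
// of the centred-rotated coordinates.
// [[Rcpp::export(name = ".grid_scan_cpp")]]
List grid_scan_cpp(NumericMatrix A, NumericMatrix B, NumericMatrix rots,
                   double tstep, double d, double pad) {
  const int m = A.nrow(), n = B.nrow(), K = rots.nrow();
  const double dd = d * d;
  std::vector<double> a(3 * m), b0(3 * n), rb(3 * n), rbt(3 * n);
  double cb[3] = {0, 0, 0};
  for (int j = 0; j < n; ++j)
    for (int c = 0; c < 3; ++c) cb[c] += B(j, c) / n;
  for (int i = 0; i < m; ++i)
    for (int c = 0; c < 3; ++c) a[3 * i + c] = A(i, c);
  for (int j = 0; j < n; ++j)
    for (int c = 0; c < 3; ++c) b0[3 * j + c] = B(j, c) - cb[c];
  double amin[3], amax[3];
  for (int c = 0; c < 3; ++c) { amin[c] = R_PosInf; amax[c] = R_NegInf; }
  for (int i = 0; i < m; ++i)
    for (int c = 0; c < 3; ++c) {
      if (a[3 * i + c] < amin[c]) amin[c] = a[3 * i + c];
      if (a[3 * i + c] > amax[c]) amax[c] = a[3 * i + c];
    }
  std::vector<int> D;
  int best = -1, bestk = 0;
  double bestt[3] = {0, 0, 0};
  long evaluated = 0;
  for (int k = 0; k < K; ++k) {
    double R[9];
    for (int c = 0; c < 9; ++c) R[c] = rots(k, c);
    double bmin[3], bmax[3];
    for (int c = 0; c < 3; ++c) { bmin[c] = R_PosInf; bmax[c] = R_NegInf; }
    for (int j = 0; j < n; ++j) {
      const double* p = &b0[3 * j];
      for (int c = 0; c < 3; ++c) {
        const double v = R[3 * c] * p[0] + R[3 * c + 1] * p[1] +
                         R[3 * c + 2] * p[2];
        rb[3 * j + c] = v;
        if (v < bmin[c]) bmin[c] = v;
        if (v > bmax[c]) bmax[c] = v;
      }
    }
    double lo[3], hi[3];
    int ns[3];
    for (int c = 0; c < 3; ++c) {
      lo[c] = amin[c] - bmax[c] - pad;
      hi[c] = amax[c] - bmin[c] + pad;
      ns[c] = static_cast<int>(std::floor((hi[c] - lo[c]) / tstep)) + 1;
    }
    for (int sx = 0; sx < ns[0]; ++sx) {
      const double tx = lo[0] + sx * tstep;
      for (int sy = 0; sy < ns[1]; ++sy) {
        const double ty = lo[1] + sy * tstep;
        for (int sz = 0; sz < ns[2]; ++sz) {
          const double tz = lo[2] + sz * tstep;
          for (int j = 0; j < n; ++j) {
            rbt[3 * j] = rb[3 * j] + tx;
            rbt[3 * j + 1] = rb[3 * j + 1] + ty;
            rbt[3 * j + 2] = rb[3 * j + 2] + tz;
          }
          const int cnt = numpairs_count(a.data(), m, rbt.data(), n, dd, D);
          ++evaluated;
          if (cnt > best) {
            best = cnt;
            bestk = k;
            bestt[0] = tx; bestt[1] = ty; bestt[2] = tz;
          }
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["count"] = best, _["rot_index"] = bestk + 1,
                      _["translation"] = NumericVector::create(
                          bestt[0], bestt[1], bestt[2]),
                      _["centroid_b"] = NumericVector::create(
                          cb[0], cb[1], cb[2]),
                      _["evaluated"] = static_cast<double>(evaluated));
}

static double crms2_euler(const double* L, const double* Rt, int k,
                          double al, double be, double ga) {
  const double ca = std::cos(al), sa = std::sin(al);
  const double cb = std::cos(be), sb = std::sin(be);
  const double cg = std::cos(ga), sg = std::sin(ga);
  // zyz Euler rotation Rz(al) Ry(be) Rz(ga)
  const double r11 = ca * cb * cg - sa * sg, r12 = -ca * cb * sg - sa * cg,
               r13 = ca * sb;
  const double r21 = sa * cb * cg + ca * sg, r22 = -sa * cb * sg + ca * cg,
               r23 = sa * sb;
  const double r31 = -sb * cg, r32 = sb * sg, r33 = cb;
  double s = 0.0;
  for (int i = 0; i < k; ++i) {
    const double* p = Rt + 3 * i;
    const double x = r11 * p[0] + r12 * p[1] + r13 * p[2] - L[3 * i];
    const double y = r21 * p[0] + r22 * p[1] + r23 * p[2] - L[3 * i + 1];
    const double z = r31 * p[0] + r32 * p[1] + r33 * p[2] - L[3 * i + 2];
    s += x * x + y * y + z * z;
  }
  return s / k;
}

// Rotation-grid oracle for the least-squares superposition: for centred
// point sets the optimal translation is the centroid match for every
// rotation, so only SO(3) is scanned (global zyz grid at coarse_deg, then
// nested local refinement).  Independent of the Kabsch/quaternion solvers.
// [[Rcpp::export(name = ".crms_grid_cpp")]]
double crms_grid_cpp(NumericMatrix Lm, NumericMatrix Rm, double coarse_deg,
                     int levels) {
  const int k = Lm.nrow();
  std::vector<double> L(3 * k), Rt(3 * k);
  double cl[3] = {0, 0, 0}, cr[3] = {0, 0, 0};
  for (int i = 0; i < k; ++i)
    for (int c = 0; c < 3; ++c) {
      cl[c] += Lm(i, c) / k;
      cr[c] += Rm(i, c) / k;
    }
  for (int i = 0; i < k; ++i)
    for (int c = 0; c < 3; ++c) {
      L[3 * i + c] = Lm(i, c) - cl[c];
      Rt[3 * i + c] = Rm(i, c) - cr[c];
    }
  const double deg = M_PI / 180.0, s = coarse_deg * deg;
  // coarse global scan keeping the NKEEP best cells; local refinement is
  // run from each of them, guarding against basins of the Euler
  // parametrization (gimbal degeneracy near beta = 0 or pi)
  const int NKEEP = 12;
  double kv[NKEEP], ka[NKEEP], kb[NKEEP], kg[NKEEP];
  for (int c = 0; c < NKEEP; ++c) kv[c] = R_PosInf;
  for (double al = 0; al < 2 * M_PI; al += s)
    for (double be = 0; be <= M_PI + 1e-12; be += s)
      for (double ga = 0; ga < 2 * M_PI; ga += s) {
        const double v = crms2_euler(L.data(), Rt.data(), k, al, be, ga);
        if (v < kv[NKEEP - 1]) {
          int c = NKEEP - 1;
          while (c > 0 && kv[c - 1] > v) {
            kv[c] = kv[c - 1]; ka[c] = ka[c - 1];
            kb[c] = kb[c - 1]; kg[c] = kg[c - 1];
            --c;
          }
          kv[c] = v; ka[c] = al; kb[c] = be; kg[c] = ga;
        }
      }
  double best = R_PosInf;
  for (int c = 0; c < NKEEP && R_FINITE(kv[c]); ++c) {
    double cb2 = kv[c], ba = ka[c], bb = kb[c], bg = kg[c];
    double range = s;
    for (int lev = 0; lev < levels; ++lev) {
      const double step = range / 4.0;
      const double a0 = ba, b0 = bb, g0 = bg;
      for (int ia = -4; ia <= 4; ++ia)
        for (int ib = -4; ib <= 4; ++ib)
          for (int ig = -4; ig <= 4; ++ig) {
            const double v = crms2_euler(L.data(), Rt.data(), k,
                                         a0 + ia * step, b0 + ib * step,
                                         g0 + ig * step);
            if (v < cb2) {
              cb2 = v;
              ba = a0 + ia * step; bb = b0 + ib * step; bg = g0 + ig * step;
            }
          }
      range = step;
    }
    if (cb2 < best) best = cb2;
  }
  return std::sqrt(best);
}
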