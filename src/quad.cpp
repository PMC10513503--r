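// Fast path for the exhaustive 4-electrode initialization: criteria are
// evaluated from the 3x3 Gram matrix G = t(Ts) %*% Ts of each row
// subset (eigenvalues of G are the squared singular values), with the
// per-row rank-1 outer products precomputed once.  Equivalence with
// direct SVD is asserted by the test suite.
#include <Rcpp.h>
#include <cmath>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// eigenvalues of a symmetric 3x3 (trigonometric method), descending
static inline void eig3(double xx, double xy, double xz,
                        double yy, double yz, double zz,
                        double *l1, double *l2, double *l3) {
  double p1 = xy * xy + xz * xz + yz * yz;
  if (p1 == 0.0) {
    double a = xx, b = yy, c = zz;
    if (a < b) std::swap(a, b);
    if (b < c) std::swap(b, c);
    if (a < b) std::swap(a, b);
    *l1 = a; *l2 = b; *l3 = c;
    return;
  }
  double q = (xx + yy + zz) / 3.0;
  double p2 = (xx - q) * (xx - q) + (yy - q) * (yy - q) +
              (zz - q) * (zz - q) + 2.0 * p1;
  double p = std::sqrt(p2 / 6.0);
  double bxx = (xx - q) / p, byy = (yy - q) / p, bzz = (zz - q) / p;
  double bxy = xy / p, bxz = xz / p, byz = yz / p;
  double detB = bxx * (byy * bzz - byz * byz) -
                bxy * (bxy * bzz - byz * bxz) +
                bxz * (bxy * byz - byy * bxz);
  double r = detB / 2.0;
  if (r < -1.0) r = -1.0;
  if (r > 1.0) r = 1.0;
  double phi = std::acos(r) / 3.0;
  *l1 = q + 2.0 * p * std::cos(phi);
  *l3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
  *l2 = 3.0 * q - *l1 - *l3;
}

static inline double score_of(double xx, double xy, double xz,
                              double yy, double yz, double zz,
                              int crit) {
  if (crit == 2) {  // B: product of singular values = sqrt(det G)
    double det = xx * (yy * zz - yz * yz) - xy * (xy * zz - yz * xz) +
                 xz * (xy * yz - yy * xz);
    return det > 0.0 ? std::sqrt(det) : 0.0;
  }
  double l1, l2, l3;
  eig3(xx, xy, xz, yy, yz, zz, &l1, &l2, &l3);
  if (l1 < 0.0) l1 = 0.0;
  if (l2 < 0.0) l2 = 0.0;
  if (l3 < 0.0) l3 = 0.0;
  if (crit == 1) {  // A: condition number sigma1/sigma3, +Inf sentinel
    if (l3 < 1e-24 * l1 || l1 == 0.0) return R_PosInf;
    return std::sqrt(l1 / l3);
  }
  // C: nuclear norm
  return std::sqrt(l1) + std::sqrt(l2) + std::sqrt(l3);
}

// Per-row Gram outer products: M x 6 matrix (xx, xy, xz, yy, yz, zz)
// [[Rcpp::export]]
NumericMatrix cpp_row_gram(NumericMatrix block) {
  int M = block.nrow();
  NumericMatrix G(M, 6);
  for (int i = 0; i < M; ++i) {
    double x = block(i, 0), y = block(i, 1), z = block(i, 2);
    G(i, 0) = x * x; G(i, 1) = x * y; G(i, 2) = x * z;
    G(i, 3) = y * y; G(i, 4) = y * z; G(i, 5) = z * z;
  }
  return G;
}

// Scores of all C(M,4) quadruples in lexicographic order (i<j<k<l).
// [[Rcpp::export]]
NumericVector cpp_quad_scores(NumericMatrix G6, int crit) {
  int M = G6.nrow();
  R_xlen_t n = (R_xlen_t)M * (M - 1) * (M - 2) * (M - 3) / 24;
  NumericVector out(n);
  R_xlen_t idx = 0;
  for (int i = 0; i < M - 3; ++i) {
    for (int j = i + 1; j < M - 2; ++j) {
      double xx2 = G6(i, 0) + G6(j, 0), xy2 = G6(i, 1) + G6(j, 1),
             xz2 = G6(i, 2) + G6(j, 2), yy2 = G6(i, 3) + G6(j, 3),
             yz2 = G6(i, 4) + G6(j, 4), zz2 = G6(i, 5) + G6(j, 5);
      for (int k = j + 1; k < M - 1; ++k) {
        double xx3 = xx2 + G6(k, 0), xy3 = xy2 + G6(k, 1),
               xz3 = xz2 + G6(k, 2), yy3 = yy2 + G6(k, 3),
               yz3 = yz2 + G6(k, 4), zz3 = zz2 + G6(k, 5);
        for (int l = k + 1; l < M; ++l) {
          out[idx++] = score_of(xx3 + G6(l, 0), xy3 + G6(l, 1),
                                xz3 + G6(l, 2), yy3 + G6(l, 3),
                                yz3 + G6(l, 4), zz3 + G6(l, 5), crit);
        }
      }
    }
  }
  return out;
}

// Best quadruple without storing all scores; first strict improvement
// in lexicographic order implements the smallest-index-set tie-break.
// [[Rcpp::export]]
List cpp_quad_best(NumericMatrix G6, int crit, bool minimize) {
  int M = G6.nrow();
  double best = minimize ? R_PosInf : R_NegInf;
  int bi = 0, bj = 1, bk = 2, bl = 3;
  R_xlen_t n = 0;
  for (int i = 0; i < M - 3; ++i) {
    for (int j = i + 1; j < M - 2; ++j) {
      double xx2 = G6(i, 0) + G6(j, 0), xy2 = G6(i, 1) + G6(j, 1),
             xz2 = G6(i, 2) + G6(j, 2), yy2 = G6(i, 3) + G6(j, 3),
             yz2 = G6(i, 4) + G6(j, 4), zz2 = G6(i, 5) + G6(j, 5);
      for (int k = j + 1; k < M - 1; ++k) {
        double xx3 = xx2 + G6(k, 0), xy3 = xy2 + G6(k, 1),
               xz3 = xz2 + G6(k, 2), yy3 = yy2 + G6(k, 3),
               yz3 = yz2 + G6(k, 4), zz3 = zz2 + G6(k, 5);
        for (int l = k + 1; l < M; ++l) {
          double s = score_of(xx3 + G6(l, 0), xy3 + G6(l, 1),
                              xz3 + G6(l, 2), yy3 + G6(l, 3),
                              yz3 + G6(l, 4), zz3 + G6(l, 5), crit);
          ++n;
          if (minimize ? (s < best) : (s > best)) {
            best = s; bi = i; bj = j; bk = k; bl = l;
          }
        }
      }
    }
  }
  return List::create(_["subset"] = IntegerVector::create(bi + 1, bj + 1,
                                                          bk + 1, bl + 1),
                      _["score"] = best, _["n_combinations"] = (double)n);
}

// Membership counts of each electrode among the n_keep best quadruples
// (ties resolved toward the lexicographically smallest combination).
// `scores` must come from cpp_quad_scores (same enumeration order).
// [[Rcpp::export]]
List cpp_top_occurrence(NumericVector scores, int M, double n_keep,
                        bool minimize) {
  R_xlen_t n = scores.size(), keep_n = (R_xlen_t)n_keep;
  if (keep_n < 1 || keep_n > n) stop("empty or oversized selection");
  std::vector<R_xlen_t> ord(n);
  for (R_xlen_t i = 0; i < n; ++i) ord[i] = i;
  const double *s = REAL(scores);
  auto cmp = [s, minimize](R_xlen_t a, R_xlen_t b) {
    double sa = s[a], sb = s[b];
    if (sa != sb) return minimize ? (sa < sb) : (sa > sb);
    return a < b;
  };
  std::nth_element(ord.begin(), ord.begin() + keep_n - 1, ord.end(), cmp);
  std::vector<char> keep(n, 0);
  for (R_xlen_t i = 0; i < keep_n; ++i) keep[ord[i]] = 1;
  IntegerVector counts(M);
  R_xlen_t idx = 0;
  for (int i = 0; i < M - 3; ++i)
    for (int j = i + 1; j < M - 2; ++j)
      for (int k = j + 1; k < M - 1; ++k)
        for (int l = k + 1; l < M; ++l, ++idx)
          if (keep[idx]) {
            ++counts[i]; ++counts[j]; ++counts[k]; ++counts[l];
          }
  return List::create(_["counts"] = counts, _["n_retained"] = (double)keep_n);
}
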