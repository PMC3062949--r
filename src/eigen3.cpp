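#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cyclic Jacobi diagonalization of one symmetric 3x3 matrix. Converges to
// machine precision in a handful of sweeps; a[] holds the matrix (modified
// in place), V the accumulated rotations (eigenvectors in columns).
static inline void jacobi3(double a[3][3], double V[3][3], double lam[3],
                           const bool want_vectors) {
  if (want_vectors) {
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c) V[r][c] = (r == c) ? 1.0 : 0.0;
  }
  for (int sweep = 0; sweep < 50; ++sweep) {
    double off = std::fabs(a[0][1]) + std::fabs(a[0][2]) + std::fabs(a[1][2]);
    if (off == 0.0) break;
    double diag = std::fabs(a[0][0]) + std::fabs(a[1][1]) + std::fabs(a[2][2]);
    if (off <= 1e-15 * (diag + off)) break;
    for (int p = 0; p < 2; ++p) {
      for (int q = p + 1; q < 3; ++q) {
        const double apq = a[p][q];
        if (apq == 0.0) continue;
        const double theta = (a[q][q] - a[p][p]) / (2.0 * apq);
        double t = 1.0 / (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        if (theta < 0.0) t = -t;
        const double c = 1.0 / std::sqrt(t * t + 1.0);
        const double s = t * c;
        const double tau = s / (1.0 + c);
        const double h = t * apq;
        a[p][p] -= h;
        a[q][q] += h;
        a[p][q] = a[q][p] = 0.0;
        const int r = 3 - p - q;  // the remaining index
        const double arp = a[r][p], arq = a[r][q];
        a[r][p] = a[p][r] = arp - s * (arq + tau * arp);
        a[r][q] = a[q][r] = arq + s * (arp - tau * arq);
        if (want_vectors) {
          for (int i = 0; i < 3; ++i) {
            const double vip = V[i][p], viq = V[i][q];
            V[i][p] = vip - s * (viq + tau * vip);
            V[i][q] = viq + s * (vip - tau * viq);
          }
        }
      }
    }
  }
  lam[0] = a[0][0]; lam[1] = a[1][1]; lam[2] = a[2][2];
}

// Per-voxel eigenvalues (and optionally eigenvectors) of symmetric 3x3
// matrices given as six component vectors. Output eigenvalues sorted by
// ascending magnitude, ties broken by ascending signed value.
// [[Rcpp::export(name = ".eigenSym3Field")]]
List eigen_sym3_field(const NumericVector& ixx, const NumericVector& iyy,
                      const NumericVector& izz, const NumericVector& ixy,
                      const NumericVector& ixz, const NumericVector& iyz,
                      const bool vectors) {
  const R_xlen_t n = ixx.size();
  if (iyy.size() != n || izz.size() != n || ixy.size() != n ||
      ixz.size() != n || iyz.size() != n)
    stop("all six Hessian components must have the same length");

  NumericVector l1(no_init(n)), l2(no_init(n)), l3(no_init(n));
  NumericMatrix e1, e2, e3;
  if (vectors) {
    e1 = NumericMatrix(n, 3); e2 = NumericMatrix(n, 3); e3 = NumericMatrix(n, 3);
  }

  for (R_xlen_t i = 0; i < n; ++i) {
    const double xx = ixx[i], yy = iyy[i], zz = izz[i];
    const double xy = ixy[i], xz = ixz[i], yz = iyz[i];
    if (!std::isfinite(xx) || !std::isfinite(yy) || !std::isfinite(zz) ||
        !std::isfinite(xy) || !std::isfinite(xz) || !std::isfinite(yz))
      stop("non-finite Hessian component at voxel %td", (ptrdiff_t)(i + 1));
    double a[3][3] = {{xx, xy, xz}, {xy, yy, yz}, {xz, yz, zz}};
    double V[3][3], lam[3];
    jacobi3(a, V, lam, vectors);

    // magnitude sort, signed ascending on |.| ties
    int ord[3] = {0, 1, 2};
    for (int p = 0; p < 2; ++p)
      for (int q = 0; q < 2 - p; ++q) {
        const double mq = std::fabs(lam[ord[q]]), mq1 = std::fabs(lam[ord[q + 1]]);
        if (mq > mq1 || (mq == mq1 && lam[ord[q]] > lam[ord[q + 1]])) {
          const int tmp = ord[q]; ord[q] = ord[q + 1]; ord[q + 1] = tmp;
        }
      }
    l1[i] = lam[ord[0]]; l2[i] = lam[ord[1]]; l3[i] = lam[ord[2]];
    if (vectors) {
      for (int r = 0; r < 3; ++r) {
        e1(i, r) = V[r][ord[0]];
        e2(i, r) = V[r][ord[1]];
        e3(i, r) = V[r][ord[2]];
      }
    }
  }

  if (vectors)
    return List::create(_["l1"] = l1, _["l2"] = l2, _["l3"] = l3,
                        _["e1"] = e1, _["e2"] = e2, _["e3"] = e3);
  return List::create(_["l1"] = l1, _["l2"] = l2, _["l3"] = l3);
}
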