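#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Propagate natural-frame triads and centerline positions along the organ.
//
// Frames are stored with the basis vectors as ROWS: row 1 = m1, row 2 = m2,
// row 3 = T.  Consecutive frames obey D(n+1) = R(n) D(n) with
// R = exp(U * ds), U the skew Darboux matrix built from (kappa1, kappa2).
// The exponential is evaluated in closed form (Rodrigues):
//   R = I + sin(k ds)/k * U + (1 - cos(k ds))/k^2 * U^2,  k = |kappa|,
// with the k -> 0 limit handled by a series expansion.  This keeps every
// frame orthonormal to rounding error regardless of step count.
//
// Returns m1, m2, tangent as n x 3 matrices (one row per segment) and
// positions as an (n+1) x 3 matrix of segment endpoints starting at the base.
// [[Rcpp::export]]
List propagate_frames_cpp(NumericVector kappa1, NumericVector kappa2,
                          double ds, NumericMatrix base_frame,
                          NumericVector base_position) {
  const int n = kappa1.size();
  NumericMatrix m1(n, 3), m2(n, 3), tang(n, 3), pos(n + 1, 3);

  double D[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      D[i][j] = base_frame(i, j);
  double p[3] = {base_position[0], base_position[1], base_position[2]};
  pos(0, 0) = p[0]; pos(0, 1) = p[1]; pos(0, 2) = p[2];

  for (int seg = 0; seg < n; ++seg) {
    for (int j = 0; j < 3; ++j) {
      m1(seg, j)   = D[0][j];
      m2(seg, j)   = D[1][j];
      tang(seg, j) = D[2][j];
      p[j] += D[2][j] * ds;
      pos(seg + 1, j) = p[j];
    }

    const double k1 = kappa1[seg], k2 = kappa2[seg];
    const double k = std::sqrt(k1 * k1 + k2 * k2);
    if (k > 0.0) {
      const double th = k * ds;
      double a, b;  // sin(th)/k and (1 - cos(th))/k^2
      if (th < 1e-6) {
        a = ds * (1.0 - th * th / 6.0);
        b = 0.5 * ds * ds * (1.0 - th * th / 12.0);
      } else {
        a = std::sin(th) / k;
        b = (1.0 - std::cos(th)) / (k * k);
      }
      // U = [[0,0,-k1],[0,0,-k2],[k1,k2,0]]
      // R = I + a U + b U^2
      const double R00 = 1.0 - b * k1 * k1;
      const double R01 = -b * k1 * k2;
      const double R02 = -a * k1;
      const double R10 = -b * k1 * k2;
      const double R11 = 1.0 - b * k2 * k2;
      const double R12 = -a * k2;
      const double R20 = a * k1;
      const double R21 = a * k2;
      const double R22 = 1.0 - b * (k1 * k1 + k2 * k2);

      double Dn[3][3];
      for (int j = 0; j < 3; ++j) {
        Dn[0][j] = R00 * D[0][j] + R01 * D[1][j] + R02 * D[2][j];
        Dn[1][j] = R10 * D[0][j] + R11 * D[1][j] + R12 * D[2][j];
        Dn[2][j] = R20 * D[0][j] + R21 * D[1][j] + R22 * D[2][j];
      }
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j)
          D[i][j] = Dn[i][j];
    }
    // k == 0: frame unchanged (identity rotation)
  }

  return List::create(_["m1"] = m1, _["m2"] = m2,
                      _["tangent"] = tang, _["positions"] = pos);
}
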