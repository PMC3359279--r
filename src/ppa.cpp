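// Ping-pong fixed-point iteration.
//
// Conventions (documented in the methods vignette and mirrored by the pure-R
// thresholdScores()): population (divide-by-n) standard deviation for both
// normalization and thresholding; support = values strictly above
// mean + t * sd; surviving values rescaled by the maximum survivor so scores
// lie in (0, 1]; supports whose maximum survivor is not positive are treated
// as empty (membership requires a positive score).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// returns false when the thresholded support is empty
static bool threshold_vec(const arma::vec& x, double t, arma::vec& out) {
  const double m = arma::mean(x);
  const double s = std::sqrt(arma::mean(arma::square(x - m)));
  const double cut = m + t * s;
  out.zeros(x.n_elem);
  double mx = 0.0;
  for (arma::uword i = 0; i < x.n_elem; ++i)
    if (x[i] > cut && x[i] > mx) mx = x[i];
  if (mx <= 0.0) return false;
  for (arma::uword i = 0; i < x.n_elem; ++i)
    if (x[i] > cut && x[i] > 0.0) out[i] = x[i] / mx;
  return true;
}

static bool same_support(const arma::vec& a, const arma::vec& b) {
  for (arma::uword i = 0; i < a.n_elem; ++i)
    if ((a[i] > 0.0) != (b[i] > 0.0)) return false;
  return true;
}

// One full ping-pong cycle: dataset-1 features <- shared, shared <-
// dataset-1 features, dataset-2 features <- shared, shared <- dataset-2
// features. R1/R2 are row-normalized (features x shared), C1/C2
// column-normalized copies of the same matrices. Feature scores are
// computed from the column-normalized copy (each shared element's profile
// standardized across features, so a feature's score measures how high it
// sits within the selected shared elements); shared scores from the
// row-normalized copy (each feature's profile standardized across the
// shared dimension, so a shared element's score measures how specific the
// selected features are to it).
// [[Rcpp::export(name = ".ppaFixedPointCpp")]]
List ppa_fixed_point_cpp(const arma::mat& R1, const arma::mat& C1,
                         const arma::mat& R2, const arma::mat& C2,
                         const arma::uvec& seed0,
                         double tf1, double tf2, double ts,
                         int maxIter, double tol) {
  const arma::uword nShared = R1.n_cols;
  arma::vec s(nShared, arma::fill::zeros);
  for (arma::uword i = 0; i < seed0.n_elem; ++i) s[seed0[i]] = 1.0;

  arma::vec f1, f2, sPrev, f1Prev, f2Prev;
  bool havePrev = false;
  int iter = 0;
  bool converged = false;

  while (iter < maxIter) {
    ++iter;
    if (!threshold_vec(C1 * s, tf1, f1)) break;
    if (!threshold_vec(R1.t() * f1, ts, s)) break;
    if (!threshold_vec(C2 * s, tf2, f2)) break;
    if (!threshold_vec(R2.t() * f2, ts, s)) break;

    if (havePrev) {
      const bool sameSets = same_support(s, sPrev) &&
        same_support(f1, f1Prev) && same_support(f2, f2Prev);
      const double dmax = std::max(
          arma::abs(s - sPrev).max(),
          std::max(arma::abs(f1 - f1Prev).max(),
                   arma::abs(f2 - f2Prev).max()));
      if (sameSets || dmax < tol) { converged = true; break; }
    }
    sPrev = s; f1Prev = f1; f2Prev = f2;
    havePrev = true;
  }

  if (!converged)
    return List::create(Named("converged") = false,
                        Named("iterations") = iter);
  return List::create(Named("converged") = true,
                      Named("iterations") = iter,
                      Named("shared") = NumericVector(s.begin(), s.end()),
                      Named("f1") = NumericVector(f1.begin(), f1.end()),
                      Named("f2") = NumericVector(f2.begin(), f2.end()));
}
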