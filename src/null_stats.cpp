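#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Columns scaled to unit-norm z-scores so that cross products are Pearson
// correlations. Constant columns are flagged (returned correlations for them
// are forced to the sentinel -2, i.e. below any real correlation).
static arma::mat std_unit_cols(const arma::mat& M, std::vector<bool>& constant) {
  arma::mat Z(M.n_rows, M.n_cols);
  constant.assign(M.n_cols, false);
  for (arma::uword j = 0; j < M.n_cols; ++j) {
    arma::vec c = M.col(j) - arma::mean(M.col(j));
    double nrm = arma::norm(c);
    if (nrm < 1e-12) {
      constant[j] = true;
      Z.col(j).zeros();
    } else {
      Z.col(j) = c / nrm;
    }
  }
  return Z;
}

// Null sampling for one ordered dataset pair: the reference centroid frame is
// re-embedded at a uniformly random orientation about the reference data's
// overall mean point ('center'). Writing the centered centroid matrix
// B = C - center = Q_b * R_b, a uniform rotation of the frame is
// distributionally equivalent to V * R_b with V a Haar-uniform orthonormal
// genes x k frame (QR of a Gaussian matrix, sign-corrected). All pairwise
// centroid distances and norms about 'center' are preserved exactly.
//
// For each draw, every query sample is assigned to its nearest null centroid
// by Pearson correlation; per query cluster we record the best-fit nearest
// neighbor fraction and the mean correlation with the best-fit null centroid.
//
// Zq:     genes x m query samples, unit-norm z-scored columns
// labels: 1..n_clusters cluster index per query sample
// Rb:     k x k R factor of qr(C - center)
// center: genes vector
// [[Rcpp::export]]
List cpp_null_stats(const arma::mat& Zq, const IntegerVector& labels,
                    const int n_clusters, const arma::mat& Rb,
                    const arma::vec& center, const int n_null) {
  const arma::uword g = Zq.n_rows, m = Zq.n_cols, k = Rb.n_cols;
  if ((arma::uword)labels.size() != m)
    stop("labels length must match query sample count");
  std::vector<std::vector<arma::uword>> members(n_clusters);
  for (arma::uword i = 0; i < m; ++i) {
    int q = labels[i];
    if (q < 1 || q > n_clusters) stop("label out of range");
    members[q - 1].push_back(i);
  }
  arma::mat null_sim(n_null, n_clusters), null_nnf(n_null, n_clusters);
  arma::mat G(g, k);
  std::vector<bool> constant;
  for (int it = 0; it < n_null; ++it) {
    for (arma::uword j = 0; j < k; ++j)
      for (arma::uword i = 0; i < g; ++i)
        G(i, j) = norm_rand();
    arma::mat Qm, Rm;
    if (!arma::qr_econ(Qm, Rm, G)) stop("QR decomposition failed");
    for (arma::uword j = 0; j < k; ++j)
      if (Rm(j, j) < 0) Qm.col(j) *= -1.0;
    arma::mat N = Qm * Rb;
    N.each_col() += center;
    arma::mat Zc = std_unit_cols(N, constant);
    arma::mat S = Zq.t() * Zc;                     // m x k Pearson correlations
    for (arma::uword j = 0; j < k; ++j)
      if (constant[j]) S.col(j).fill(-2.0);
    for (int q = 0; q < n_clusters; ++q) {
      const std::vector<arma::uword>& mem = members[q];
      std::vector<int> counts(k, 0);
      for (arma::uword idx : mem) {
        arma::uword best;
        S.row(idx).max(best);                      // first max on ties
        counts[best]++;
      }
      int best_c = 0;
      for (arma::uword j = 1; j < k; ++j)
        if (counts[j] > counts[best_c]) best_c = (int)j;
      double sim = 0.0;
      for (arma::uword idx : mem) sim += S(idx, best_c);
      null_nnf(it, q) = mem.empty() ? NA_REAL
                                    : (double)counts[best_c] / (double)mem.size();
      null_sim(it, q) = mem.empty() ? NA_REAL : sim / (double)mem.size();
    }
  }
  return List::create(_["sim"] = null_sim, _["nnf"] = null_nnf);
}
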