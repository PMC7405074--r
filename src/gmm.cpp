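// Gaussian mixture fitting for the evidence-accumulation ensemble:
// full, per-component, diagonally regularized covariances; k-means++
// initialization; several restarts keeping the best log-likelihood.
// Randomness is drawn from R's RNG so seeded runs reproduce exactly.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// k-means++ seeding: pick k rows of X as initial centers by D^2 sampling.
arma::uvec kmeanspp_centers(const arma::mat &X, int k) {
  const arma::uword n = X.n_rows;
  arma::uvec centers(k);
  centers(0) = static_cast<arma::uword>(unif_rand() * n);
  if (centers(0) >= n) centers(0) = n - 1;
  arma::vec d2(n);
  d2.fill(arma::datum::inf);
  for (int c = 1; c < k; ++c) {
    const arma::rowvec prev = X.row(centers(c - 1));
    for (arma::uword i = 0; i < n; ++i) {
      double d = arma::accu(arma::square(X.row(i) - prev));
      if (d < d2(i)) d2(i) = d;
    }
    double tot = arma::accu(d2);
    if (!(tot > 0)) { // all points coincide with a center
      centers(c) = static_cast<arma::uword>(unif_rand() * n);
      if (centers(c) >= n) centers(c) = n - 1;
      continue;
    }
    double u = unif_rand() * tot, cum = 0.0;
    arma::uword pick = n - 1;
    for (arma::uword i = 0; i < n; ++i) {
      cum += d2(i);
      if (cum >= u) { pick = i; break; }
    }
    centers(c) = pick;
  }
  return centers;
}

// log N(x; mu, Sigma) for all rows of X, given chol(Sigma) upper R.
arma::vec dmvnorm_log(const arma::mat &X, const arma::rowvec &mu,
                      const arma::mat &R) {
  const arma::uword d = X.n_cols;
  double logdet = 0.0;
  for (arma::uword j = 0; j < d; ++j) logdet += std::log(R(j, j));
  arma::mat Xc = X.each_row() - mu;
  // solve R' z = xc  =>  z = R'^{-1} xc ; quadform = ||z||^2
  arma::mat Z = arma::solve(arma::trimatl(R.t()), Xc.t());
  arma::vec q = arma::sum(arma::square(Z), 0).t();
  double cst = -0.5 * d * std::log(2.0 * M_PI) - logdet;
  return cst - 0.5 * q;
}

struct GmmFit {
  double loglik;
  arma::mat means;    // k x d
  arma::cube covs;    // d x d x k
  arma::vec weights;  // k
  bool ok;
};

GmmFit gmm_em(const arma::mat &X, int k, double reg, int max_iter,
              double tol) {
  const arma::uword n = X.n_rows, d = X.n_cols;
  GmmFit fit;
  fit.ok = false;
  fit.loglik = -arma::datum::inf;

  arma::uvec cidx = kmeanspp_centers(X, k);
  arma::mat means(k, d);
  for (int c = 0; c < k; ++c) means.row(c) = X.row(cidx(c));

  // initial covariances: diagonal of the data covariance (+ reg)
  arma::rowvec v = arma::var(X, 0, 0); // population variance per column
  for (arma::uword j = 0; j < d; ++j)
    if (!(v(j) > 0)) v(j) = 1.0;
  arma::mat cov0 = arma::diagmat(arma::conv_to<arma::vec>::from(v));
  cov0.diag() += reg;
  arma::cube covs(d, d, k);
  for (int c = 0; c < k; ++c) covs.slice(c) = cov0;
  arma::vec w(k, arma::fill::value(1.0 / k));

  arma::mat logp(n, k);
  double ll_prev = -arma::datum::inf;
  double ll = -arma::datum::inf;

  for (int it = 0; it < max_iter; ++it) {
    // E-step
    for (int c = 0; c < k; ++c) {
      arma::mat R;
      arma::mat S = covs.slice(c);
      bool chol_ok = arma::chol(R, S);
      double bump = reg > 0 ? reg : 1e-8;
      while (!chol_ok && bump < 1e6) {
        S.diag() += bump;
        bump *= 10.0;
        chol_ok = arma::chol(R, S);
      }
      if (!chol_ok) return fit;
      logp.col(c) = dmvnorm_log(X, means.row(c), R) + std::log(w(c));
    }
    arma::vec mx = arma::max(logp, 1);
    arma::mat resp = arma::exp(logp.each_col() - mx);
    arma::vec rs = arma::sum(resp, 1);
    ll = arma::accu(mx + arma::log(rs));
    resp.each_col() /= rs;

    if (std::abs(ll - ll_prev) < tol * (std::abs(ll) + 1.0)) {
      ll_prev = ll;
      break;
    }
    ll_prev = ll;

    // M-step
    arma::rowvec nk = arma::sum(resp, 0);
    for (int c = 0; c < k; ++c) {
      double Nc = nk(c);
      if (Nc < 1e-10) {
        // dead component: re-seed on a random point
        arma::uword p = static_cast<arma::uword>(unif_rand() * n);
        if (p >= n) p = n - 1;
        means.row(c) = X.row(p);
        covs.slice(c) = cov0;
        w(c) = 1.0 / n;
        continue;
      }
      means.row(c) = (resp.col(c).t() * X) / Nc;
      arma::mat Xc = X.each_row() - means.row(c);
      arma::mat S = Xc.t() * (Xc.each_col() % resp.col(c)) / Nc;
      S.diag() += reg;
      covs.slice(c) = S;
      w(c) = Nc / n;
    }
    w /= arma::accu(w);
  }

  fit.loglik = ll_prev;
  fit.means = means;
  fit.covs = covs;
  fit.weights = w;
  fit.ok = std::isfinite(ll_prev);
  return fit;
}

} // namespace

// [[Rcpp::export]]
List gmm_fit_best_cpp(const arma::mat &X, int k, int n_restarts, double reg,
                      int max_iter, double tol) {
  GmmFit best;
  best.ok = false;
  best.loglik = -arma::datum::inf;
  for (int r = 0; r < n_restarts; ++r) {
    GmmFit f = gmm_em(X, k, reg, max_iter, tol);
    if (f.ok && f.loglik > best.loglik) best = f;
  }
  if (!best.ok) stop("all GMM restarts failed to converge to a finite fit");
  return List::create(_["loglik"] = best.loglik, _["means"] = best.means,
                      _["covs"] = best.covs, _["weights"] = best.weights);
}

// Hard assignment of rows of X to the component with the largest posterior.
// [[Rcpp::export]]
IntegerVector gmm_assign_cpp(const arma::mat &X, const arma::mat &means,
                             const arma::cube &covs,
                             const arma::vec &weights) {
  const int k = means.n_rows;
  const arma::uword n = X.n_rows;
  arma::mat logp(n, k);
  for (int c = 0; c < k; ++c) {
    arma::mat R;
    arma::mat S = covs.slice(c);
    bool ok = arma::chol(R, S);
    double bump = 1e-8;
    while (!ok && bump < 1e6) {
      S.diag() += bump;
      bump *= 10.0;
      ok = arma::chol(R, S);
    }
    if (!ok) stop("non positive-definite component covariance");
    logp.col(c) = dmvnorm_log(X, means.row(c), R) + std::log(weights(c));
  }
  arma::uvec lab = arma::index_max(logp, 1);
  IntegerVector out(n);
  for (arma::uword i = 0; i < n; ++i) out[i] = lab(i) + 1;
  return out;
}

// Accumulate pairwise co-assignment evidence: E += I[l_i == l_j].
// [[Rcpp::export]]
void accumulate_coassign_cpp(NumericMatrix E, IntegerVector labels) {
  const int n = labels.size();
  for (int i = 0; i < n; ++i) {
    const int li = labels[i];
    for (int j = i; j < n; ++j) {
      if (labels[j] == li) {
        E(i, j) += 1.0;
        if (j != i) E(j, i) += 1.0;
      }
    }
  }
}
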