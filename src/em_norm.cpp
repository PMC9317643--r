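// EM for a multivariate normal with missing data.
//
// Observations are rows of X (n x p); NA marks missing cells. The E-step
// sweeps the conditional distribution of missing given observed coordinates
// for each row; the M-step updates (mu, Sigma) from the expected sufficient
// statistics, optionally shrinking off-diagonals toward zero with a ridge
// prior of weight `ridge` pseudo-observations (the stabiliser that stands in
// for an empirical prior when p is close to n). The observed-data
// log-likelihood is accumulated during each E-step (at the parameters
// entering the step), reusing the same Cholesky factor as the conditional
// sweep, so the returned trace is the classic non-decreasing EM sequence.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List em_norm_cpp(const arma::mat& X, double ridge, double tol,
                       int max_iter) {
  const uword n = X.n_rows, p = X.n_cols;
  const double log2pi = std::log(2.0 * M_PI);

  std::vector<uvec> obs_idx(n), mis_idx(n);
  for (uword i = 0; i < n; ++i) {
    const rowvec xi = X.row(i);
    std::vector<uword> o, m;
    for (uword j = 0; j < p; ++j) {
      if (std::isfinite(xi(j))) o.push_back(j); else m.push_back(j);
    }
    obs_idx[i] = uvec(o);
    mis_idx[i] = uvec(m);
  }

  // init: observed column means, diagonal covariance of observed values
  vec mu(p), dvar(p);
  for (uword j = 0; j < p; ++j) {
    uvec o = find_finite(X.col(j));
    vec xo = X.col(j);
    xo = xo.elem(o);
    mu(j) = mean(xo);
    dvar(j) = xo.n_elem > 1 ? var(xo) : 1.0;
    if (!(dvar(j) > 1e-12)) dvar(j) = 1e-12;
  }
  mat sigma = diagmat(dvar);

  std::vector<double> ll_trace;
  bool converged = false;
  int iters = 0;
  for (int iter = 1; iter <= max_iter; ++iter) {
    iters = iter;
    vec sumx(p, fill::zeros);
    mat sumxx(p, p, fill::zeros);
    double ll = 0.0;
    for (uword i = 0; i < n; ++i) {
      const uvec& o = obs_idx[i];
      const uvec& m = mis_idx[i];
      vec xhat = X.row(i).t();
      mat cpad;
      if (m.n_elem > 0 && o.n_elem == 0) {
        xhat = mu;
        cpad = sigma;
        sumx += xhat;
        sumxx += xhat * xhat.t() + cpad;
        continue;
      }
      const vec xo = xhat.elem(o);
      const vec d = xo - mu.elem(o);
      mat L;
      if (!chol(L, sigma.submat(o, o), "lower"))
        Rcpp::stop("covariance lost positive definiteness during EM");
      const vec z = solve(trimatl(L), d);
      ll += -0.5 * (o.n_elem * log2pi + 2.0 * sum(log(L.diag())) +
                    dot(z, z));
      if (m.n_elem > 0) {
        const mat Smo = sigma.submat(m, o);
        // K = Soo^{-1} Som via the Cholesky factor
        const mat W = solve(trimatl(L), Smo.t());          // L^{-1} Som
        xhat.elem(m) = mu.elem(m) + W.t() * z;
        const mat cc = sigma.submat(m, m) - W.t() * W;
        sumx += xhat;
        mat xx = xhat * xhat.t();
        xx.submat(m, m) += cc;
        sumxx += xx;
      } else {
        sumx += xhat;
        sumxx += xhat * xhat.t();
      }
    }
    ll_trace.push_back(ll);

    vec mu_new = sumx / double(n);
    mat sig_mle = sumxx / double(n) - mu_new * mu_new.t();
    sig_mle = 0.5 * (sig_mle + sig_mle.t());
    mat sig_new = sig_mle;
    if (ridge > 0) {
      sig_new = (double(n) * sig_mle + ridge * diagmat(sig_mle.diag())) /
                (double(n) + ridge);
    }

    double num = std::max(abs(mu_new - mu).max(),
                          abs(sig_new - sigma).max());
    double den = std::max(abs(mu).max(), abs(sigma).max()) + 1e-8;
    mu = mu_new;
    sigma = sig_new;
    if (num / den < tol) {
      converged = true;
      break;
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("mu") = mu,
      Rcpp::Named("sigma") = sigma,
      Rcpp::Named("loglik") = ll_trace,
      Rcpp::Named("iterations") = iters,
      Rcpp::Named("converged") = converged);
}

// Conditional mean and a lower-triangular Cholesky factor of the
// conditional covariance of the missing coordinates of one row, given the
// observed ones, under N(mu, sigma). Used for conditional draws.
// [[Rcpp::export]]
Rcpp::List cond_normal_cpp(const arma::vec& xi, const arma::vec& mu,
                           const arma::mat& sigma) {
  uvec m = find_nonfinite(xi);
  uvec o = find_finite(xi);
  vec cm;
  mat cc;
  if (o.n_elem == 0) {
    cm = mu.elem(m);
    cc = sigma.submat(m, m);
  } else {
    mat Soo = sigma.submat(o, o);
    mat Smo = sigma.submat(m, o);
    mat K = solve(Soo, Smo.t());
    cm = mu.elem(m) + K.t() * (xi.elem(o) - mu.elem(o));
    cc = sigma.submat(m, m) - Smo * K;
  }
  cc = 0.5 * (cc + cc.t());
  mat L;
  bool ok = chol(L, cc + 1e-12 * eye(cc.n_rows, cc.n_cols), "lower");
  return Rcpp::List::create(
      Rcpp::Named("idx") = Rcpp::IntegerVector(m.begin(), m.end()),
      Rcpp::Named("mean") = cm,
      Rcpp::Named("chol") = L,
      Rcpp::Named("ok") = ok);
}
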