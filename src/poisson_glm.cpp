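#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Poisson log-link IRLS with step-halving; deviance is non-increasing
// across accepted steps. Linear predictor clamped at +/-30 to avoid
// overflow on degenerate designs.

static double pois_deviance(const arma::vec& y, const arma::vec& mu) {
  double dev = 0.0;
  for (arma::uword i = 0; i < y.n_elem; ++i) {
    double d = (y[i] > 0) ? y[i] * std::log(y[i] / mu[i]) - (y[i] - mu[i])
                          : mu[i];
    dev += 2.0 * d;
  }
  return dev;
}

static arma::vec clamp_eta(const arma::vec& eta) {
  return arma::clamp(eta, -30.0, 30.0);
}

// Fit by IRLS; returns deviance (SSE computed by caller on count scale),
// coefficients and convergence flag. Optional warm start.
static void irls_fit(const arma::mat& X, const arma::vec& y,
                     arma::vec& beta, double& dev, bool& converged,
                     int maxit = 60, double tol = 1e-10) {
  int p = X.n_cols;
  if (!beta.is_finite() || (int)beta.n_elem != p) {
    beta = arma::zeros(p);
    double ybar = arma::mean(y);
    beta[0] = std::log(ybar > 1e-8 ? ybar : 1e-8); // column 0 = intercept
  }
  arma::vec eta = clamp_eta(X * beta);
  arma::vec mu = arma::exp(eta);
  dev = pois_deviance(y, mu);
  converged = false;

  for (int it = 0; it < maxit; ++it) {
    arma::vec w = mu;
    arma::vec z = eta + (y - mu) / mu;
    arma::mat Xw = X.each_col() % w;
    arma::mat XtWX = X.t() * Xw;
    XtWX.diag() += 1e-10; // guard against exact singularity
    arma::vec XtWz = Xw.t() * z;
    arma::vec beta_new;
    bool ok = arma::solve(beta_new, XtWX, XtWz, arma::solve_opts::no_approx);
    if (!ok || !beta_new.is_finite()) break;

    // step-halving: accept only deviance-non-increasing steps
    arma::vec step = beta_new - beta;
    double dev_new = dev;
    arma::vec eta_new, mu_new;
    double frac = 1.0;
    bool accepted = false;
    for (int h = 0; h < 20; ++h) {
      eta_new = clamp_eta(X * (beta + frac * step));
      mu_new = arma::exp(eta_new);
      dev_new = pois_deviance(y, mu_new);
      if (std::isfinite(dev_new) && dev_new <= dev + 1e-12) {
        accepted = true;
        break;
      }
      frac *= 0.5;
    }
    if (!accepted) break;
    beta += frac * step;
    eta = eta_new;
    mu = mu_new;
    double rel = std::fabs(dev - dev_new) / (std::fabs(dev_new) + 0.1);
    dev = dev_new;
    if (rel < tol) {
      converged = true;
      break;
    }
  }
}

// [[Rcpp::export]]
List poisson_irls_cpp(const arma::mat& X, const arma::vec& y,
                      int maxit = 60, double tol = 1e-10) {
  arma::vec beta;
  double dev;
  bool conv;
  irls_fit(X, y, beta, dev, conv, maxit, tol);
  arma::vec mu = arma::exp(clamp_eta(X * beta));
  return List::create(_["coefficients"] = beta, _["deviance"] = dev,
                      _["fitted"] = mu, _["converged"] = conv);
}

// Sum-squared-error (count scale) of the full model and of each
// drop-one-regressor reduced model, for every response column of Y.
// X includes the intercept in column 0; drop_cols lists, per regressor,
// the 0-based column indices removed for its reduced model.
// Returns SSE matrix [(1 + n_regressors) x ncol(Y)], row 0 = full model,
// and a matching convergence-indicator matrix.
// [[Rcpp::export]]
List cpd_sse_cpp(const arma::mat& X, const arma::mat& Y, List drop_cols,
                 int maxit = 60) {
  int m = Y.n_cols, R = drop_cols.size(), p = X.n_cols;
  arma::mat sse(R + 1, m), convm(R + 1, m);

  // pre-build reduced design column keeps
  std::vector<arma::uvec> keeps(R);
  for (int r = 0; r < R; ++r) {
    IntegerVector dc = drop_cols[r];
    std::vector<arma::uword> keep;
    for (int j = 0; j < p; ++j) {
      bool dropped = false;
      for (int k = 0; k < dc.size(); ++k)
        if (dc[k] == j) dropped = true;
      if (!dropped) keep.push_back(j);
    }
    keeps[r] = arma::uvec(keep);
  }

  for (int c = 0; c < m; ++c) {
    arma::vec y = Y.col(c);
    arma::vec beta;
    double dev;
    bool conv;
    irls_fit(X, y, beta, dev, conv, maxit);
    arma::vec mu = arma::exp(clamp_eta(X * beta));
    sse(0, c) = arma::accu(arma::square(y - mu));
    convm(0, c) = conv ? 1.0 : 0.0;
    for (int r = 0; r < R; ++r) {
      arma::mat Xr = X.cols(keeps[r]);
      arma::vec br;
      double devr;
      bool convr;
      irls_fit(Xr, y, br, devr, convr, maxit);
      arma::vec mur = arma::exp(clamp_eta(Xr * br));
      sse(r + 1, c) = arma::accu(arma::square(y - mur));
      convm(r + 1, c) = convr ? 1.0 : 0.0;
    }
  }
  return List::create(_["sse"] = sse, _["converged"] = convm);
}
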