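// Sparse Bayesian linear regression core (relevance vector regression).
//
// Works on an explicit design matrix Phi (for the linear-kernel model this is
// [K | 1] with K_is = x_i . x_s and a trailing bias column). Hyperparameters
// are optimised by type-II maximum likelihood with the classic fixed-point
// updates:
//   gamma_i  = 1 - alpha_i * Sigma_ii
//   alpha_i <- gamma_i / mu_i^2
//   sigma2  <- ||y - Phi mu||^2 / (n - sum(gamma))
// Columns whose alpha exceeds `prune_thresh` are removed (never the bias).
//
// Numerics: the posterior is solved through Bs = Phi'Phi + sigma2 * A
// (sigma2 factored out), which stays well-conditioned even when sigma2
// collapses on interpolable targets, and the evidence quadratic uses the
// stationarity identity y'C^-1 y = rss/sigma2 + mu'A mu.
//
// The log marginal likelihood (evidence) is evaluated at every iteration and
// returned as a trace so callers can assert monotonicity.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

namespace {

struct Posterior {
  vec mu;          // posterior mean
  vec sigma_diag;  // diag of posterior covariance
  double log_ev;   // log marginal likelihood at (alpha, sigma2)
  int n_jitter;
};

Posterior solve_posterior(const mat& GramA, const mat& PhiA,
                          const vec& Phity, const vec& y, const vec& alphaA,
                          double sigma2) {
  const double n = static_cast<double>(y.n_elem);
  const double m = static_cast<double>(PhiA.n_cols);
  mat Bs = GramA;
  Bs.diag() += sigma2 * alphaA;
  int n_jitter = 0;
  mat R;
  if (!chol(R, Bs)) {
    Bs.diag() += 1e-10;
    ++n_jitter;
    if (!chol(R, Bs)) {
      Bs.diag() += 1e-8 * Bs.diag().max();
      ++n_jitter;
      if (!chol(R, Bs)) Rcpp::stop("posterior covariance not positive definite");
    }
  }
  mat Rinv = inv(trimatu(R));
  vec diag_Bsinv = sum(square(Rinv), 1);
  vec mu = Rinv * (Rinv.t() * Phity);
  double rss = accu(square(y - PhiA * mu));
  double quad = rss / sigma2 + accu(alphaA % square(mu));
  double logdetBs = 2.0 * accu(log(R.diag()));
  double log_ev = -0.5 * (n * std::log(2.0 * M_PI) +
                          (n - m) * std::log(sigma2) + logdetBs -
                          accu(log(alphaA)) + quad);
  return {mu, sigma2 * diag_Bsinv, log_ev, n_jitter};
}

}  // namespace

// [[Rcpp::export(name = ".rvr_fit_core")]]
Rcpp::List rvr_fit_core(const arma::mat& Phi, const arma::vec& y,
                        const double alpha_init, const double sigma2_init,
                        const int bias_index,  // 0-based column of Phi; -1 none
                        const double prune_thresh, const double tol,
                        const int max_iter, const double sigma2_floor,
                        const bool fixed_alpha, const bool fixed_sigma2) {
  const uword n = Phi.n_rows, m = Phi.n_cols;
  vec alpha(m);
  alpha.fill(alpha_init);
  double sigma2 = std::max(sigma2_init, sigma2_floor);

  uvec active = regspace<uvec>(0, m - 1);
  vec mu, gamma_active;
  std::vector<double> evidence;
  evidence.reserve(64);
  int n_jitter = 0, iter = 0;
  bool converged = false;

  // Gram matrix and Phi'y depend only on the data; computed once and
  // subset per active set
  const mat Gram = symmatu(Phi.t() * Phi);
  const vec Phity_full = Phi.t() * y;

  for (iter = 0; iter < max_iter; ++iter) {
    const mat PhiA = Phi.cols(active);
    const vec alphaA = alpha.elem(active);
    Posterior post = solve_posterior(Gram.submat(active, active), PhiA,
                                     Phity_full.elem(active), y, alphaA,
                                     sigma2);
    mu = post.mu;
    n_jitter += post.n_jitter;
    evidence.push_back(post.log_ev);

    gamma_active = 1.0 - alphaA % post.sigma_diag;

    // hyperparameter updates
    vec alpha_new = alphaA;
    if (!fixed_alpha) {
      for (uword i = 0; i < active.n_elem; ++i) {
        double mu2 = mu(i) * mu(i);
        alpha_new(i) = (mu2 > 0.0)
                           ? std::max(gamma_active(i), 1e-12) / mu2
                           : std::numeric_limits<double>::infinity();
        // the bias is never pruned, so cap its alpha at the prune threshold
        // to keep the system finite when the target needs no intercept
        if (static_cast<int>(active(i)) == bias_index &&
            !(alpha_new(i) <= prune_thresh)) {
          alpha_new(i) = prune_thresh;
        }
      }
    }
    if (!fixed_sigma2) {
      double rss = accu(square(y - PhiA * mu));
      double denom = std::max(static_cast<double>(n) - accu(gamma_active), 1e-6);
      sigma2 = std::max(rss / denom, sigma2_floor);
    }

    // convergence on max |delta log alpha| over columns kept this iteration
    double max_dla = 0.0;
    for (uword i = 0; i < active.n_elem; ++i) {
      bool keep = std::isfinite(alpha_new(i)) &&
                  (alpha_new(i) <= prune_thresh ||
                   static_cast<int>(active(i)) == bias_index);
      if (keep) {
        double d = std::fabs(std::log(alpha_new(i)) - std::log(alphaA(i)));
        if (d > max_dla) max_dla = d;
      }
    }

    // write back and prune (bias column exempt)
    for (uword i = 0; i < active.n_elem; ++i) alpha(active(i)) = alpha_new(i);
    std::vector<uword> keep;
    keep.reserve(active.n_elem);
    for (uword i = 0; i < active.n_elem; ++i) {
      bool is_bias = static_cast<int>(active(i)) == bias_index;
      if (is_bias ||
          (std::isfinite(alpha_new(i)) && alpha_new(i) <= prune_thresh)) {
        keep.push_back(active(i));
      }
    }
    if (keep.empty()) break;  // no bias column and everything pruned
    active = conv_to<uvec>::from(keep);

    if (!fixed_alpha && max_dla < tol) {
      converged = true;
      ++iter;
      break;
    }
    if (fixed_alpha && fixed_sigma2) {  // nothing to iterate
      converged = true;
      ++iter;
      break;
    }
  }

  // final posterior at the converged hyperparameters
  const mat PhiA = Phi.cols(active);
  const vec alphaA = alpha.elem(active);
  Posterior post = solve_posterior(Gram.submat(active, active), PhiA,
                                   Phity_full.elem(active), y, alphaA,
                                   sigma2);
  mu = post.mu;
  n_jitter += post.n_jitter;
  evidence.push_back(post.log_ev);
  gamma_active = 1.0 - alphaA % post.sigma_diag;

  return Rcpp::List::create(
      Rcpp::Named("active") = active,  // 0-based column indices of Phi
      Rcpp::Named("mu") = mu,
      Rcpp::Named("alpha") = alpha,
      Rcpp::Named("sigma2") = sigma2,
      Rcpp::Named("gamma") = gamma_active,
      Rcpp::Named("evidence") = evidence,
      Rcpp::Named("n_iter") = iter,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("n_jitter") = n_jitter);
}
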