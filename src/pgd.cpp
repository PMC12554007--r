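// Proximal gradient descent core for the sparsity-smoothness penalized
// binomial varying-coefficient model.
//
// Works in the reparameterized coordinates eta (eta_p = L_p theta_p for
// penalized groups, eta_0 = theta_0), where the penalty is the plain group
// norm lambda * sum_p ||eta_p||_2. Coefficients are held as a K x (P+1)
// matrix Eta (column p = group p; column 0 = intercept). Tmat maps eta to
// theta per group: theta_p = Tmat[tindex_p] * eta_p.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double PI_CLIP = 1e-10;

// -2 log-likelihood given Eta; also fills resid (= Y - X * pi) if wanted.
// Bt is the K x M transpose of the basis-row matrix (records contiguous).
static double loglik_eta(const mat& Bt, const mat& Zaug, const uvec& sidx,
                         const vec& Y, const vec& Xtot, const cube& Tmat,
                         const uvec& tindex, const mat& Eta,
                         vec* resid_out) {
  const uword K = Bt.n_rows, G = Eta.n_cols, M = Bt.n_cols;
  mat Theta(K, G);
  for (uword p = 0; p < G; ++p)
    Theta.col(p) = Tmat.slice(tindex(p)) * Eta.col(p);
  mat U = Theta * Zaug.t(); // K x N
  double ll = 0.0;
  if (resid_out) resid_out->set_size(M);
  // clamp the logit so pi stays inside [PI_CLIP, 1 - PI_CLIP]
  const double LP_MAX = std::log((1.0 - PI_CLIP) / PI_CLIP);
  const double* bp = Bt.memptr();
  for (uword r = 0; r < M; ++r) {
    const double* up = U.colptr(sidx(r));
    double lp = 0.0;
    for (uword k = 0; k < K; ++k) lp += bp[r * K + k] * up[k];
    if (lp > LP_MAX) lp = LP_MAX;
    if (lp < -LP_MAX) lp = -LP_MAX;
    double e = std::exp(lp);
    double pi = e / (1.0 + e);
    // Y log pi + (X - Y) log(1 - pi) = Y * lp - X * log(1 + e)
    ll += Y(r) * lp - Xtot(r) * std::log1p(e);
    if (resid_out) (*resid_out)(r) = Y(r) - Xtot(r) * pi;
  }
  return -2.0 * ll;
}

// Gradient of -2 loglik wrt Eta (K x G), given resid.
static mat grad_eta(const mat& Bt, const mat& Zaug, const uvec& sidx,
                    const vec& resid, const cube& Tmat, const uvec& tindex,
                    uword N) {
  const uword K = Bt.n_rows, M = Bt.n_cols, G = Zaug.n_cols;
  mat S(K, N, fill::zeros);
  const double* bp = Bt.memptr();
  for (uword r = 0; r < M; ++r) {
    double* sp = S.colptr(sidx(r));
    const double w = resid(r);
    for (uword k = 0; k < K; ++k) sp[k] += w * bp[r * K + k];
  }
  mat Gth = -2.0 * (S * Zaug); // K x G, gradient wrt theta
  mat Geta(K, G);
  for (uword p = 0; p < G; ++p)
    Geta.col(p) = Tmat.slice(tindex(p)).t() * Gth.col(p);
  return Geta;
}

// Group-wise proximal map: soft-threshold penalized group norms at thr,
// zero locked groups, leave intercept (column 0) untouched.
static void prox_inplace(mat& Eta, double thr, const uvec& penalized,
                         const uvec& locked) {
  for (uword i = 0; i < penalized.n_elem; ++i) {
    uword p = penalized(i);
    double nrm = norm(Eta.col(p), 2);
    if (nrm <= thr)
      Eta.col(p).zeros();
    else
      Eta.col(p) *= (1.0 - thr / nrm);
  }
  for (uword i = 0; i < locked.n_elem; ++i) Eta.col(locked(i)).zeros();
}

static double penalty_norm(const mat& Eta, const uvec& penalized) {
  double s = 0.0;
  for (uword i = 0; i < penalized.n_elem; ++i)
    s += norm(Eta.col(penalized(i)), 2);
  return s;
}

// [[Rcpp::export]]
Rcpp::List pgd_fit_cpp(const arma::mat& B, const arma::mat& Zaug,
                       const arma::uvec& sidx, const arma::vec& Y,
                       const arma::vec& Xtot, const arma::cube& Tmat,
                       const arma::uvec& tindex, const arma::uvec& penalized,
                       const arma::uvec& locked, arma::mat Eta,
                       double lambda, double t_init, double delta,
                       double tol, int max_iter, bool keep_trace,
                       bool reset_step) {
  const uword N = Zaug.n_rows;
  const mat Bt = B.t();   // records contiguous in memory
  double t_carry = t_init;
  vec resid;
  double ll = loglik_eta(Bt, Zaug, sidx, Y, Xtot, Tmat, tindex, Eta, &resid);
  double F = ll + lambda * penalty_norm(Eta, penalized);
  std::vector<double> trace;
  if (keep_trace) trace.push_back(F);
  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    mat G = grad_eta(Bt, Zaug, sidx, resid, Tmat, tindex, N);
    // Either restart the line search at t_init every iteration, or carry the
    // last accepted step forward with one growth attempt (cheaper; the
    // acceptance condition still guarantees descent).
    double t = reset_step ? t_init : std::min(t_carry / delta, t_init);
    mat Cand;
    double ll_new = 0.0;
    int shrinks = 0;
    for (;;) {
      Cand = Eta - t * G;
      prox_inplace(Cand, t * lambda, penalized, locked);
      mat Gt = (Eta - Cand) / t;
      double gg = accu(Gt % Gt);
      if (gg == 0.0) { // fixed point: any step is accepted, eta unchanged
        ll_new = ll;
        break;
      }
      ll_new = loglik_eta(Bt, Zaug, sidx, Y, Xtot, Tmat, tindex, Cand, &resid);
      double bound = ll - t * accu(G % Gt) + 0.5 * t * gg +
        1e-10 * (std::abs(ll) + 1.0);
      if (ll_new <= bound) break;
      t *= delta;
      if (++shrinks > 100) {
        Rcpp::stop("backtracking failed after 100 shrinkages (gradient norm %g)",
                   norm(G, "fro"));
      }
    }
    double F_new = ll_new + lambda * penalty_norm(Cand, penalized);
    if (F_new > F + 1e-6 * (std::abs(F) + 1.0)) {
      Rcpp::stop("objective increased (%.6g -> %.6g): divergence", F, F_new);
    }
    bool small_change = std::abs(F - F_new) <= tol * (std::abs(F) + 1e-10);
    Eta = Cand; // resid was filled at the accepted candidate
    ll = ll_new;
    F = F_new;
    t_carry = t;
    if (keep_trace) trace.push_back(F);
    if (small_change) { converged = true; break; }
  }
  return Rcpp::List::create(
    Rcpp::Named("eta") = Eta,
    Rcpp::Named("objective") = F,
    Rcpp::Named("trace") = trace,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("n_iter") = std::min(iter, max_iter));
}

// Mean validation deviance for a set of fitted Theta matrices.
// Thetas: K x G x nfit cube; returns vector of mean deviances.
// [[Rcpp::export]]
arma::vec mean_deviance_cpp(const arma::mat& B, const arma::mat& Zaug,
                            const arma::uvec& sidx, const arma::vec& Y,
                            const arma::vec& Xtot, const arma::cube& Thetas) {
  const uword M = B.n_rows, nfit = Thetas.n_slices;
  vec out(nfit);
  for (uword f = 0; f < nfit; ++f) {
    mat U = Thetas.slice(f) * Zaug.t();
    double dev = 0.0;
    for (uword r = 0; r < M; ++r) {
      double lp = dot(B.row(r), U.col(sidx(r)));
      double pi = 1.0 / (1.0 + std::exp(-lp));
      if (pi < PI_CLIP) pi = PI_CLIP;
      if (pi > 1.0 - PI_CLIP) pi = 1.0 - PI_CLIP;
      dev += -2.0 * (Y(r) * std::log(pi) +
                     (Xtot(r) - Y(r)) * std::log(1.0 - pi));
    }
    out(f) = dev / double(M);
  }
  return out;
}
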