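// Proximal-gradient (FISTA) solver for the latent-overlap hierarchical
// group lasso on logistic regression with treatment-covariate
// interactions.
//
// Latent parameterization (q = 1 + p + 3p standardized columns, plus an
// unpenalized intercept handled separately):
//   col 0          : treatment singleton
//   cols 1..p      : main-effect singletons x_j
//   cols 1+p+3j .. : interaction group j = (latent treatment copy,
//                    latent x_j copy, product a*x_j), j = 0..p-1
// Penalty: lambda * (sum singleton |.| + w * sum_j ||group_j||_2).
// Selecting interaction group j re-introduces latent treatment and x_j
// contributions, so a nonzero product term implies nonzero observed
// treatment and main effects (strong hierarchy).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double logistic_loss(const vec& eta, const vec& y, double n) {
  // (1/n) * sum log(1 + exp(eta)) - y * eta, computed stably
  vec pos = clamp(eta, 0.0, datum::inf);
  double s = accu(pos + log1p(exp(-abs(eta))) - y % eta);
  return s / n;
}

static double penalty_value(const vec& theta, int p, double w) {
  double pen = std::abs(theta(0));
  for (int j = 1; j <= p; ++j) pen += std::abs(theta(j));
  for (int j = 0; j < p; ++j) {
    int s = 1 + p + 3 * j;
    pen += w * std::sqrt(theta(s) * theta(s) + theta(s + 1) * theta(s + 1) +
                         theta(s + 2) * theta(s + 2));
  }
  return pen;
}

// prox of step * [sum singleton |.| + w * sum group ||.||_2]
static void prox_step(vec& theta, int p, double w, double step) {
  for (int j = 0; j <= p; ++j) {
    double v = theta(j);
    double shr = std::abs(v) - step;
    theta(j) = shr > 0 ? (v > 0 ? shr : -shr) : 0.0;
  }
  for (int j = 0; j < p; ++j) {
    int s = 1 + p + 3 * j;
    double nrm = std::sqrt(theta(s) * theta(s) + theta(s + 1) * theta(s + 1) +
                           theta(s + 2) * theta(s + 2));
    double scl = nrm > w * step ? (1.0 - w * step / nrm) : 0.0;
    theta(s) *= scl;
    theta(s + 1) *= scl;
    theta(s + 2) *= scl;
  }
}

// [[Rcpp::export]]
Rcpp::List hgl_fista_path(const arma::mat& Xs, const arma::vec& y, int p,
                          const arma::vec& lambda, double w,
                          double tol, int maxit) {
  const double n = (double) Xs.n_rows;
  const int q = Xs.n_cols;
  const int nlam = lambda.n_elem;

  mat theta_path(q + 1, nlam, fill::zeros);  // row 0: intercept
  ivec iters(nlam, fill::zeros);
  vec objective(nlam, fill::zeros);

  double ybar = mean(y);
  double b0 = std::log(ybar / (1.0 - ybar));
  vec theta(q, fill::zeros);
  double L = 0.25 * std::max(1.0, norm(Xs, "fro") * norm(Xs, "fro") / n / q) ;

  for (int l = 0; l < nlam; ++l) {
    double lam = lambda(l);
    // FISTA with backtracking and adaptive restart, warm-started from
    // the previous path point
    vec th = theta;
    double b = b0;
    vec th_prev = th;
    double b_prev = b;
    double t_mom = 1.0;

    vec eta = b + Xs * th;
    double f_y = logistic_loss(eta, y, n);
    double F_old = f_y + lam * penalty_value(th, p, w);

    int it = 0;
    for (it = 0; it < maxit; ++it) {
      // momentum point
      double t_next = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * t_mom * t_mom));
      double mom = (t_mom - 1.0) / t_next;
      vec yk = th + mom * (th - th_prev);
      double byk = b + mom * (b - b_prev);

      vec eta_y = byk + Xs * yk;
      vec mu = 1.0 / (1.0 + exp(-eta_y));
      vec r = (mu - y) / n;
      double g0 = accu(r);
      vec g = Xs.t() * r;
      double f_at_y = logistic_loss(eta_y, y, n);

      // backtracking line search on L
      vec th_new;
      double b_new, f_new;
      for (;;) {
        th_new = yk - g / L;
        prox_step(th_new, p, w, lam / L);
        b_new = byk - g0 / L;
        vec d = th_new - yk;
        double db = b_new - byk;
        vec eta_new = b_new + Xs * th_new;
        f_new = logistic_loss(eta_new, y, n);
        double quad = f_at_y + dot(g, d) + g0 * db +
          0.5 * L * (dot(d, d) + db * db);
        if (f_new <= quad + 1e-12) break;
        L *= 2.0;
        if (L > 1e12) break;
      }

      th_prev = th;
      b_prev = b;
      th = th_new;
      b = b_new;
      t_mom = t_next;

      double F_new = f_new + lam * penalty_value(th, p, w);
      if (F_new > F_old) {  // adaptive restart
        t_mom = 1.0;
        th_prev = th;
        b_prev = b;
      }
      if (std::abs(F_old - F_new) <= tol * std::max(1.0, std::abs(F_old))) {
        F_old = F_new;
        break;
      }
      F_old = F_new;
    }

    theta = th;
    b0 = b;
    theta_path(0, l) = b;
    theta_path(span(1, q), l) = th;
    iters(l) = it + 1;
    objective(l) = F_old;
  }

  return Rcpp::List::create(
    Rcpp::Named("theta") = theta_path,
    Rcpp::Named("iterations") = iters,
    Rcpp::Named("objective") = objective
  );
}
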