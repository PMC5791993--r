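// Marginal likelihood kernel for the multilevel probit choice model with a
// latent IRT-measured covariate.
//
// Model, per person i in cluster j:
//   z_ij ~ N(theta'w_ij, 1)                      (latent living conditions)
//   v_ijk ~ Bernoulli(F(lambda_k z - kappa_k))   (binary items, F probit/logit)
//   y_ij  = 1{ x'beta + g1 z + g2 z^2 + u_j + eps > tau },  eps ~ N(0,1)
//   u_j ~ N(0, sigma_u^2)
//
// The cluster marginal likelihood integrates u (outer) and z per person
// (inner) by Gauss-Hermite quadrature standardized to the priors:
//   z node t: z_it = mu_i + sqrt(2) x_t,  log-weight la_t = log(w_t) - log(pi)/2
//   u node s: u_s  = sqrt(2) sigma_u x_s, log-weight lb_s likewise.
// Person weights enter as frequency-style exponents inside the cluster
// integral; they must arrive here already normalized.
//
// Gradient is analytic on the natural parameter scale
//   psi = (lambda[K], kappa[K], theta[L], beta[P], g1, g2, tau, sigma_u).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static const double LOG_PI = std::log(M_PI);
static const double SQRT2 = std::sqrt(2.0);

// log F for a Bernoulli term coded pos (true = success); only the needed
// tail is evaluated. need_d additionally fills d log F / d eta.
static inline void link_terms(double alpha, bool pos, int link, bool need_d,
                              double &logp, double &dlog) {
  if (link == 0) { // probit
    logp = R::pnorm(alpha, 0.0, 1.0, pos ? 1 : 0, 1);
    if (need_d) {
      double ld = R::dnorm(alpha, 0.0, 1.0, 1);
      dlog = pos ? std::exp(ld - logp) : -std::exp(ld - logp);
    }
  } else {       // logit
    // log plogis(alpha) = -log1p(exp(-alpha)), stable in both tails
    double l1 = (alpha > 0) ? -std::log1p(std::exp(-alpha))
                            : alpha - std::log1p(std::exp(alpha));
    double l0 = l1 - alpha; // log(1 - p)
    if (pos) { logp = l1; if (need_d) dlog = std::exp(l0); }   // 1 - p
    else     { logp = l0; if (need_d) dlog = -std::exp(l1); }  // -p
  }
}

static inline double logsumexp(const arma::vec &x) {
  double m = x.max();
  if (!std::isfinite(m)) return m;
  return m + std::log(arma::sum(arma::exp(x - m)));
}

// [[Rcpp::export]]
List joint_loglik_cpp(const arma::vec &lambda, const arma::vec &kappa,
                      const arma::vec &theta, const arma::vec &beta,
                      double gamma1, double gamma2, double tau, double sigma_u,
                      const arma::ivec &y, const arma::mat &X,
                      const arma::imat &V, const arma::mat &W,
                      const arma::vec &wt,
                      const arma::ivec &cl_start, const arma::ivec &cl_end,
                      const arma::vec &zx, const arma::vec &zw,
                      const arma::vec &ux, const arma::vec &uw,
                      int item_link, bool want_grad, bool want_scores,
                      bool want_post) {
  const int K = lambda.n_elem, L = theta.n_elem, P = beta.n_elem;
  const int N = cl_start.n_elem;
  const int T = zx.n_elem;
  const bool no_u = (sigma_u <= 0.0);
  const int S = no_u ? 1 : (int)ux.n_elem;
  const int npar = 2 * K + L + P + 4;

  arma::vec la = arma::log(zw) - 0.5 * LOG_PI;      // z log-weights
  arma::vec uval(S), lb(S);
  if (no_u) { uval.zeros(); lb.zeros(); }
  else {
    uval = SQRT2 * sigma_u * ux;
    lb = arma::log(uw) - 0.5 * LOG_PI;
  }
  // d u_s / d sigma_u
  arma::vec du = no_u ? arma::zeros(S) : arma::vec(SQRT2 * ux);

  double ll = 0.0;
  arma::vec grad(npar, arma::fill::zeros);
  arma::mat scores;
  if (want_scores) scores.zeros(N, npar);
  arma::vec post_u_mean, post_u_sd;
  if (want_post) { post_u_mean.zeros(N); post_u_sd.zeros(N); }

  const bool need_d = want_grad || want_scores;

  for (int j = 0; j < N; ++j) {
    const int i0 = cl_start(j), i1 = cl_end(j);
    const int nj = i1 - i0 + 1;

    arma::vec mu(nj, arma::fill::zeros), base(nj, arma::fill::zeros);
    for (int i = 0; i < nj; ++i) {
      for (int l = 0; l < L; ++l) mu(i) += W(i0 + i, l) * theta(l);
      for (int p = 0; p < P; ++p) base(i) += X(i0 + i, p) * beta(p);
      base(i) -= tau;
    }

    arma::mat zmat(nj, T);
    for (int t = 0; t < T; ++t) zmat.col(t) = mu + SQRT2 * zx(t);

    // measurement part: logm(i,t); r(i,t,k) = d logm / d alpha_k; sumrl
    arma::mat logm(nj, T, arma::fill::zeros);
    arma::cube r;
    arma::mat sumrl;
    if (need_d && K > 0) { r.zeros(nj, T, K); sumrl.zeros(nj, T); }
    for (int i = 0; i < nj; ++i) {
      for (int k = 0; k < K; ++k) {
        int v = V.n_cols > 0 ? V(i0 + i, k) : -1;
        if (v < 0) continue; // missing item: factor 1
        for (int t = 0; t < T; ++t) {
          double alpha = lambda(k) * zmat(i, t) - kappa(k);
          double lp, dl = 0.0;
          link_terms(alpha, v == 1, item_link, need_d, lp, dl);
          logm(i, t) += lp;
          if (need_d) {
            r(i, t, k) = dl;
            sumrl(i, t) += dl * lambda(k);
          }
        }
      }
    }

    // outcome part per u node: A(i,t,s) = la_t + logm + logp; H = dlogp/deta
    arma::cube A(nj, T, S), H;
    if (need_d) H.zeros(nj, T, S);
    for (int s = 0; s < S; ++s) {
      for (int i = 0; i < nj; ++i) {
        int yi = y(i0 + i);
        for (int t = 0; t < T; ++t) {
          double lp = 0.0, h = 0.0;
          if (yi >= 0) {
            double z = zmat(i, t);
            double eta = base(i) + gamma1 * z + gamma2 * z * z + uval(s);
            link_terms(eta, yi == 1, 0, need_d, lp, h); // outcome is probit
          }
          A(i, t, s) = la(t) + logm(i, t) + lp;
          if (need_d) H(i, t, s) = h;
        }
      }
    }

    // logf(i,s), cluster node log-likelihoods, cluster loglik
    arma::mat logf(nj, S);
    arma::vec logLs(S, arma::fill::zeros);
    for (int s = 0; s < S; ++s) {
      for (int i = 0; i < nj; ++i) {
        arma::vec ai = arma::vectorise(A.subcube(i, 0, s, i, T - 1, s));
        logf(i, s) = logsumexp(ai);
        logLs(s) += wt(i0 + i) * logf(i, s);
      }
    }
    double logLj = logsumexp(lb + logLs);
    if (!std::isfinite(logLj)) stop("non-finite cluster log-likelihood (cluster %d)", j + 1);
    ll += logLj;

    if (want_post) {
      arma::vec cs = arma::exp(lb + logLs - logLj);
      double m1 = arma::dot(cs, uval), m2 = arma::dot(cs, arma::square(uval));
      post_u_mean(j) = m1;
      post_u_sd(j) = std::sqrt(std::max(0.0, m2 - m1 * m1));
    }

    if (need_d) {
      arma::vec cs = arma::exp(lb + logLs - logLj);
      // G(i,t) = sum_s cs g_its ; Hm(i,t) = sum_s cs g h ; HU(i,t) = sum_s cs g h du_s
      arma::mat G(nj, T, arma::fill::zeros), Hm(nj, T, arma::fill::zeros),
          HU(nj, T, arma::fill::zeros);
      for (int s = 0; s < S; ++s) {
        for (int i = 0; i < nj; ++i) {
          for (int t = 0; t < T; ++t) {
            double g = cs(s) * std::exp(A(i, t, s) - logf(i, s));
            G(i, t) += g;
            double gh = g * H(i, t, s);
            Hm(i, t) += gh;
            HU(i, t) += gh * du(s);
          }
        }
      }
      arma::vec sj(npar, arma::fill::zeros);
      for (int i = 0; i < nj; ++i) {
        double w = wt(i0 + i);
        double sH = 0.0, sHz = 0.0, sHz2 = 0.0, sHU = 0.0, sTheta = 0.0;
        for (int t = 0; t < T; ++t) {
          double z = zmat(i, t);
          sH += Hm(i, t);
          sHz += Hm(i, t) * z;
          sHz2 += Hm(i, t) * z * z;
          sHU += HU(i, t);
          if (L > 0)
            sTheta += G(i, t) * sumrl(i, t) +
                      Hm(i, t) * (gamma1 + 2.0 * gamma2 * z);
          for (int k = 0; k < K; ++k) {
            double rk = r(i, t, k);
            if (rk != 0.0) {
              sj(k) += w * G(i, t) * rk * z;       // lambda_k
              sj(K + k) -= w * G(i, t) * rk;       // kappa_k
            }
          }
        }
        for (int l = 0; l < L; ++l) sj(2 * K + l) += w * W(i0 + i, l) * sTheta;
        for (int p = 0; p < P; ++p) sj(2 * K + L + p) += w * X(i0 + i, p) * sH;
        sj(2 * K + L + P) += w * sHz;          // gamma1
        sj(2 * K + L + P + 1) += w * sHz2;     // gamma2
        sj(2 * K + L + P + 2) -= w * sH;       // tau
        sj(2 * K + L + P + 3) += w * sHU;      // sigma_u
      }
      grad += sj;
      if (want_scores) scores.row(j) = sj.t();
    }
  }

  List out = List::create(Named("loglik") = ll);
  if (want_grad) out["gradient"] = grad;
  if (want_scores) out["scores"] = scores;
  if (want_post) {
    out["post_u_mean"] = post_u_mean;
    out["post_u_sd"] = post_u_sd;
  }
  return out;
}
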