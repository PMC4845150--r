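#include <Rcpp.h>
using namespace Rcpp;

// Log-likelihood of the Gaussian-copula joint model for one continuous and
// one binary channel, evaluated over a stacked design.
//
// theta = (beta_y [ky], log sigma, beta_x [kx], atanh rho)
//   mu_t   = Zy_t . beta_y                       (conditional LFP mean)
//   eta_t  = Zx_t . beta_x                       (probit linear predictor)
//   z_t    = (y_t - mu_t) / sigma
//   zeta_t = (eta_t + rho * z_t) / sqrt(1 - rho^2)
//   ll_t   = log N(y_t; mu_t, sigma^2) + log Phi(q_t * zeta_t),  q_t = 2 x_t - 1
//
// The latent-threshold construction makes the binary margin exact (no
// quadrature): marginally P(x=1) = Phi(eta), conditionally on y the latent
// normal has mean rho*z and sd sqrt(1-rho^2).

static void unpack(const NumericVector& theta, int ky, int kx,
                   double& logsig, double& sigma, double& rho, double& s) {
  logsig = theta[ky];
  sigma = std::exp(logsig);
  double ar = theta[ky + 1 + kx];
  rho = std::tanh(ar);
  s = std::sqrt(1.0 - rho * rho);
}

// [[Rcpp::export]]
double cop_nll(NumericVector theta, NumericMatrix Zy, NumericMatrix Zx,
               NumericVector y, IntegerVector x) {
  const int n = y.size(), ky = Zy.ncol(), kx = Zx.ncol();
  double logsig, sigma, rho, s;
  unpack(theta, ky, kx, logsig, sigma, rho, s);

  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double mu = 0.0, eta = 0.0;
    for (int j = 0; j < ky; ++j) mu += Zy(i, j) * theta[j];
    for (int j = 0; j < kx; ++j) eta += Zx(i, j) * theta[ky + 1 + j];
    double z = (y[i] - mu) / sigma;
    double zeta = (eta + rho * z) / s;
    double q = x[i] ? 1.0 : -1.0;
    ll += -logsig + R::dnorm(z, 0.0, 1.0, 1) + R::pnorm(q * zeta, 0.0, 1.0, 1, 1);
  }
  return -ll;
}

// [[Rcpp::export]]
NumericVector cop_nll_grad(NumericVector theta, NumericMatrix Zy,
                           NumericMatrix Zx, NumericVector y,
                           IntegerVector x) {
  const int n = y.size(), ky = Zy.ncol(), kx = Zx.ncol();
  double logsig, sigma, rho, s;
  unpack(theta, ky, kx, logsig, sigma, rho, s);

  NumericVector g(theta.size());
  double g_logsig = 0.0, g_ar = 0.0;

  for (int i = 0; i < n; ++i) {
    double mu = 0.0, eta = 0.0;
    for (int j = 0; j < ky; ++j) mu += Zy(i, j) * theta[j];
    for (int j = 0; j < kx; ++j) eta += Zx(i, j) * theta[ky + 1 + j];
    double z = (y[i] - mu) / sigma;
    double zeta = (eta + rho * z) / s;
    double q = x[i] ? 1.0 : -1.0;
    // lambda = d/d zeta of log Phi(q zeta), stable via log scale
    double lam = q * std::exp(R::dnorm(zeta, 0.0, 1.0, 1) -
                              R::pnorm(q * zeta, 0.0, 1.0, 1, 1));
    double gy = (z - lam * rho / s) / sigma;  // dll/dmu * (-1) chain folded in
    double gx = lam / s;
    for (int j = 0; j < ky; ++j) g[j] += Zy(i, j) * gy;
    for (int j = 0; j < kx; ++j) g[ky + 1 + j] += Zx(i, j) * gx;
    g_logsig += z * z - 1.0 - lam * rho * z / s;
    g_ar += lam * (z * s + zeta * rho);
  }
  g[ky] = g_logsig;
  g[ky + 1 + kx] = g_ar;
  for (R_xlen_t j = 0; j < g.size(); ++j) g[j] = -g[j];
  return g;
}
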