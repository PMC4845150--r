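# Independent oracles and small fixtures shared across tests.
# These deliberately re-derive quantities with naive code paths (explicit
# loops, direct formulas) so they cannot share bugs with the package
# implementation.

# brute-force joint conditional log-likelihood: explicit double loop and
# textbook formulas (log-scale tail probabilities via base R so the oracle
# itself does not lose precision for spike probabilities near 0/1)
bf_joint_loglik <- function(model, ts) {
  p <- model$p
  total <- 0
  for (r in seq_len(nrow(ts$lfp))) {
    for (t in (p + 1):ncol(ts$lfp)) {
      yh <- ts$lfp[r, t - (1:p)]
      xh <- ts$spikes[r, t - (1:p)]
      mu <- model$c_y + sum(model$a * yh) + sum(model$b * xh)
      eta <- model$c_x + sum(model$d * xh) + sum(model$e * yh)
      y <- ts$lfp[r, t]
      z <- (y - mu) / model$sigma
      thr <- (eta + model$rho * z) / sqrt(1 - model$rho^2)
      lpx <- if (ts$spikes[r, t] == 1) pnorm(thr, log.p = TRUE)
             else pnorm(thr, lower.tail = FALSE, log.p = TRUE)
      total <- total + dnorm(y, mu, model$sigma, log = TRUE) + lpx
    }
  }
  total
}

# numeric integral of the mixed joint density over y for one observation,
# summed over x in {0,1}; should be 1 for any valid parameter set
bf_density_mass <- function(model, lfp_hist, spk_hist) {
  f <- function(y, x) {
    vapply(y, function(yy)
      exp(mixed_pair_loglik(model, x, yy, lfp_hist, spk_hist)), 0)
  }
  mu <- cond_means(model, lfp_hist, spk_hist)$mu_y
  lo <- mu - 12 * model$sigma
  hi <- mu + 12 * model$sigma
  integrate(f, lo, hi, x = 0, rel.tol = 1e-9)$value +
    integrate(f, lo, hi, x = 1, rel.tol = 1e-9)$value
}

# integral of P(X=1|y) f(y) dy: must reproduce the marginal spike
# probability pnorm(eta) exactly (copula-margin consistency)
bf_margin_mass <- function(model, lfp_hist, spk_hist) {
  cm <- cond_means(model, lfp_hist, spk_hist)
  f <- function(y) {
    z <- (y - cm$mu_y) / model$sigma
    pcond <- pnorm((cm$eta_x + model$rho * z) / sqrt(1 - model$rho^2))
    pcond * dnorm(y, cm$mu_y, model$sigma)
  }
  integrate(f, cm$mu_y - 12 * model$sigma, cm$mu_y + 12 * model$sigma,
            rel.tol = 1e-9)$value
}

# random valid model of order p (coefficients bounded; AR part kept stable
# by scaling toward zero until the companion spectral radius is < 0.95)
random_model <- function(p = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- runif(p, -1, 1)
  while (copulagc:::.spectral_radius(a) >= 0.95) a <- a * 0.8
  joint_model(p,
              c_y = runif(1, -1, 1), a = a, b = runif(p, -1, 1),
              sigma = runif(1, 0.5, 2),
              c_x = runif(1, -1, 1), d = runif(p, -1, 1),
              e = runif(p, -1, 1), rho = runif(1, -0.9, 0.9))
}

# small deterministic trialset for likelihood fixtures
tiny_trialset <- function(n_trials = 2, n_bins = 8, seed = 5) {
  set.seed(seed)
  lfp <- matrix(rnorm(n_trials * n_bins), n_trials, n_bins)
  spikes <- matrix(rbinom(n_trials * n_bins, 1, 0.3), n_trials, n_bins)
  trialset(lfp, spikes, fs = 1000)
}

# default desk-scale null generator: stable AR(2) LFP, refractory spikes at
# a realistic-for-desk-scale rate (~Phi(-1.5) = 6.7% of 1 ms bins)
null_model <- function(p = 2, rho = 0) {
  joint_model(p, a = c(0.5, -0.3, numeric(max(0, p - 2)))[1:p], sigma = 1,
              c_x = -1.5, d = c(-0.8, -0.3, numeric(max(0, p - 2)))[1:p],
              rho = rho)
}
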