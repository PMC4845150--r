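#' Joint Gaussian-copula model for a continuous and a binary channel
#'
#' The continuous (LFP) margin is a Gaussian autoregression with cross-lagged
#' spike history; the binary (spike) margin is probit-Bernoulli with
#' cross-lagged LFP history; same-bin dependence is carried by the Gaussian
#' copula correlation `rho` through a latent-threshold construction:
#' \deqn{\mu_t = c_y + \sum_i a_i y_{t-i} + \sum_i b_i x_{t-i}}
#' \deqn{\eta_t = c_x + \sum_i d_i x_{t-i} + \sum_i e_i y_{t-i}}
#' \deqn{y_t \sim N(\mu_t, \sigma^2), \quad P(x_t = 1) = \Phi(\eta_t),}
#' with `corr` \eqn{\rho} between the two per-bin Gaussian innovations, so
#' that conditionally \eqn{P(x_t=1 \mid y_t) =
#' \Phi\{(\eta_t + \rho z_t)/\sqrt{1-\rho^2}\}}, \eqn{z_t=(y_t-\mu_t)/\sigma}.
#'
#' @param p model order (number of history lags), a positive integer.
#' @param c_y,a,b continuous-margin intercept, own-lag and cross-lag (spike
#'   history to LFP mean) coefficients; `a`, `b` have length `p`.
#' @param sigma innovation standard deviation, `> 0`.
#' @param c_x,d,e probit intercept, own-lag (spike history) and cross-lag
#'   (LFP history to spike probability) coefficients; length `p`.
#' @param rho copula correlation in `(-1, 1)` — the instantaneous (same-bin)
#'   dependence not explained by either history.
#' @return An object of class `joint_model`.
#' @export
joint_model <- function(p, c_y = 0, a = numeric(p), b = numeric(p), sigma = 1,
                        c_x = 0, d = numeric(p), e = numeric(p), rho = 0) {
  p <- as.integer(p)
  if (p < 1L) stop("order p must be >= 1")
  for (v in list(a = a, b = b, d = d, e = e)) {
    if (length(v) != p) stop("coefficient vectors a, b, d, e must have length p")
  }
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  if (!is.finite(rho) || abs(rho) >= 1) stop("rho must lie in (-1, 1)")
  structure(list(p = p, c_y = c_y, a = as.numeric(a), b = as.numeric(b),
                 sigma = sigma, c_x = c_x, d = as.numeric(d), e = as.numeric(e),
                 rho = rho),
            class = "joint_model")
}

#' @export
print.joint_model <- function(x, ...) {
  cat(sprintf("<joint_model> order %d, sigma = %.4g, rho = %.4g\n", x$p, x$sigma, x$rho))
  cat(sprintf("  LFP    : c_y = %.4g, a = (%s), b = (%s)\n", x$c_y,
              paste(signif(x$a, 4), collapse = ", "),
              paste(signif(x$b, 4), collapse = ", ")))
  cat(sprintf("  spikes : c_x = %.4g, d = (%s), e = (%s)\n", x$c_x,
              paste(signif(x$d, 4), collapse = ", "),
              paste(signif(x$e, 4), collapse = ", ")))
  invisible(x)
}

#' Conditional means of both margins given the histories
#'
#' @param model a [joint_model()].
#' @param lfp_hist,spk_hist length-`p` histories, most recent first.
#' @return List with `mu_y` (conditional LFP mean), `eta_x` (probit linear
#'   predictor) and `pi` (= `pnorm(eta_x)`, the marginal spike probability).
#' @export
cond_means <- function(model, lfp_hist, spk_hist) {
  p <- model$p
  if (length(lfp_hist) != p || length(spk_hist) != p) {
    stop(sprintf("histories must have length p = %d (most recent first)", p))
  }
  mu_y <- model$c_y + sum(model$a * lfp_hist) + sum(model$b * spk_hist)
  eta_x <- model$c_x + sum(model$d * spk_hist) + sum(model$e * lfp_hist)
  list(mu_y = mu_y, eta_x = eta_x, pi = stats::pnorm(eta_x))
}

#' Log-likelihood of one mixed (binary, continuous) observation
#'
#' Evaluates `log f(y_t) + log P(X = x_t | y_t)` under the latent-threshold
#' Gaussian-copula construction; exact (quadrature-free) for the binary
#' margin. At `rho = 0` this factorizes exactly into the Gaussian density and
#' the Bernoulli-probit pmf.
#'
#' @inheritParams cond_means
#' @param x_t observed spike indicator, 0 or 1.
#' @param y_t observed LFP value.
#' @return Log-likelihood contribution (finite for all finite inputs).
#' @export
mixed_pair_loglik <- function(model, x_t, y_t, lfp_hist, spk_hist) {
  if (abs(model$rho) >= 1) stop("rho must lie in (-1, 1)")
  if (model$sigma <= 0) stop("sigma must be > 0")
  if (!x_t %in% c(0, 1)) stop("x_t must be 0 or 1")
  cm <- cond_means(model, lfp_hist, spk_hist)
  z <- (y_t - cm$mu_y) / model$sigma
  zeta <- (cm$eta_x + model$rho * z) / sqrt(1 - model$rho^2)
  q <- if (x_t == 1) 1 else -1
  stats::dnorm(y_t, cm$mu_y, model$sigma, log = TRUE) +
    stats::pnorm(q * zeta, log.p = TRUE)
}

# Stacked regression design over all trials: rows are (trial, t) pairs with
# t = cond+1 .. n_bins; histories most-recent-first.
.design <- function(ts, p, cond = p) {
  cond <- max(cond, p)
  nb <- ncol(ts$lfp)
  if (nb < cond + 1L) {
    stop(sprintf("trialset has %d bins; need at least %d for order %d", nb, cond + 1L, p))
  }
  idx <- (cond + 1L):nb
  Y <- as.vector(ts$lfp[, idx, drop = FALSE])
  X <- as.integer(ts$spikes[, idx, drop = FALSE])
  n <- length(Y)
  Hy <- matrix(0, n, p)
  Hx <- matrix(0, n, p)
  for (i in seq_len(p)) {
    Hy[, i] <- as.vector(ts$lfp[, idx - i, drop = FALSE])
    Hx[, i] <- as.vector(ts$spikes[, idx - i, drop = FALSE])
  }
  list(Y = Y, X = X, Hy = Hy, Hx = Hx, n_obs = n)
}

.check_binary <- function(ts, require_events = FALSE) {
  if (ts$mode != "binary" || any(ts$spikes > 1L)) {
    stop("the copula model requires a binary spike channel (mode = 'binary')")
  }
  if (require_events) {
    m <- mean(ts$spikes)
    if (m == 0 || m == 1) {
      stop(sprintf("degenerate spike channel: constant at %d (no events to model)",
                   as.integer(m)))
    }
  }
}

# theta layout: (beta_y [ky], log sigma, beta_x [kx], atanh rho)
.model_to_theta <- function(model, restriction) {
  by <- c(model$c_y, model$a, if (restriction != "no_spike_to_lfp") model$b)
  bx <- c(model$c_x, model$d, if (restriction != "no_lfp_to_spike") model$e)
  c(by, log(model$sigma), bx, atanh(model$rho))
}

.theta_to_model <- function(theta, p, restriction) {
  ky <- 1L + p + if (restriction == "no_spike_to_lfp") 0L else p
  kx <- 1L + p + if (restriction == "no_lfp_to_spike") 0L else p
  by <- theta[seq_len(ky)]
  bx <- theta[ky + 1L + seq_len(kx)]
  joint_model(p,
              c_y = by[1], a = by[1 + seq_len(p)],
              b = if (restriction == "no_spike_to_lfp") numeric(p) else by[1 + p + seq_len(p)],
              sigma = exp(theta[ky + 1L]),
              c_x = bx[1], d = bx[1 + seq_len(p)],
              e = if (restriction == "no_lfp_to_spike") numeric(p) else bx[1 + p + seq_len(p)],
              rho = tanh(theta[ky + kx + 2L]))
}

# lean probit IRLS (a few damped-free iterations are enough for a warm start;
# glm.fit's bookkeeping dominated profile time at permutation scale)
.probit_irls <- function(Z, x, iters = 4L) {
  beta <- c(stats::qnorm(max(min(mean(x), 1 - 1e-6), 1e-6)),
            numeric(ncol(Z) - 1L))
  for (it in seq_len(iters)) {
    eta <- pmax(pmin(drop(Z %*% beta), 8), -8)
    p <- pmax(pmin(stats::pnorm(eta), 1 - 1e-10), 1e-10)
    phi <- stats::dnorm(eta)
    w <- phi * phi / (p * (1 - p))
    u <- eta + (x - p) / pmax(phi, 1e-10)
    sw <- sqrt(w)
    f <- .lm.fit(Z * sw, u * sw)
    if (f$rank < ncol(Z)) f <- stats::lm.fit(Z * sw, u * sw)  # unpivoted NAs
    b2 <- f$coefficients
    b2[is.na(b2)] <- 0
    beta <- b2
  }
  beta
}

# two-stage warm start: OLS for the Gaussian margin, then probit IRLS with the
# standardized residual as an extra covariate (its coefficient is rho/s)
.warm_start <- function(Zy, Zx, Y, X) {
  fy <- .lm.fit(Zy, Y)
  if (fy$rank < ncol(Zy)) fy <- stats::lm.fit(Zy, Y)
  by <- fy$coefficients
  by[is.na(by)] <- 0
  res <- Y - drop(Zy %*% by)
  sig <- max(sqrt(mean(res^2)), 1e-6)
  z <- res / sig
  g <- .probit_irls(cbind(Zx, z), X)
  gz <- g[length(g)]
  rho0 <- max(min(gz / sqrt(1 + gz^2), 0.95), -0.95)
  bx <- pmax(pmin(g[-length(g)] * sqrt(1 - rho0^2), 8), -8)
  c(by, log(sig), bx, atanh(rho0))
}

#' Fit the joint copula model by maximum likelihood
#'
#' Conditional likelihood: the first `max(p, cond_bins)` bins of every trial
#' condition only. Optimization is quasi-Newton (BFGS, analytic gradient)
#' from a two-stage warm start (least squares for the continuous margin,
#' probit IRLS for the discrete margin with the standardized continuous
#' residual as covariate); `sigma` is optimized on the log scale and `rho` on
#' the arctanh scale so the constraints hold automatically.
#'
#' @param ts a binary-mode [trialset()].
#' @param p model order.
#' @param restriction `"full"`, `"no_spike_to_lfp"` (fixes `b = 0`) or
#'   `"no_lfp_to_spike"` (fixes `e = 0`) — the nested reduced models used for
#'   directional Granger causality.
#' @param start optional [joint_model()] used as the starting point instead
#'   of the two-stage warm start.
#' @param cond_bins number of initial bins per trial to condition on
#'   (default `p`; order selection uses a common value so AICs compare on
#'   identical observations).
#' @param hessian if `TRUE`, also return standard errors from the inverse
#'   observed information at the optimum (diagnostic use only).
#' @return An object of class `copula_fit`: the estimated `model`, maximized
#'   `loglik`, parameter count `k` (free parameters actually optimized),
#'   `aic = -2 loglik + 2 k`, `converged` flag and effective `n_obs`.
#' @export
fit_copula <- function(ts, p, restriction = c("full", "no_spike_to_lfp", "no_lfp_to_spike"),
                       start = NULL, cond_bins = p, hessian = FALSE) {
  restriction <- match.arg(restriction)
  .check_binary(ts, require_events = TRUE)
  p <- as.integer(p)
  d <- .design(ts, p, cond_bins)
  Zy <- cbind(1, d$Hy, if (restriction != "no_spike_to_lfp") d$Hx)
  Zx <- cbind(1, d$Hx, if (restriction != "no_lfp_to_spike") d$Hy)
  k <- ncol(Zy) + ncol(Zx) + 2L
  if (d$n_obs < 10L * k) {
    warning(sprintf("only %d observations for %d parameters", d$n_obs, k))
  }
  theta0 <- if (is.null(start)) .warm_start(Zy, Zx, d$Y, d$X)
            else .model_to_theta(start, restriction)
  fn <- function(th) cop_nll(th, Zy, Zx, d$Y, d$X)
  gr <- function(th) cop_nll_grad(th, Zy, Zx, d$Y, d$X)
  opt <- tryCatch(
    stats::optim(theta0, fn, gr, method = "BFGS", hessian = hessian,
                 control = list(maxit = 300L, reltol = 1e-9)),
    error = function(e) NULL)
  if (is.null(opt)) {
    opt <- list(par = theta0, value = fn(theta0), convergence = 99L)
  }
  model <- .theta_to_model(opt$par, p, restriction)
  se <- NULL
  if (hessian && !is.null(opt$hessian)) {
    se <- tryCatch(sqrt(diag(solve(opt$hessian))), error = function(e) NULL)
  }
  structure(list(model = model, loglik = -opt$value, k = k,
                 aic = 2 * opt$value + 2 * k,
                 converged = identical(opt$convergence, 0L),
                 n_obs = d$n_obs, restriction = restriction, p = p,
                 cond_bins = max(cond_bins, p), se = se),
            class = "copula_fit")
}

#' @export
print.copula_fit <- function(x, ...) {
  cat(sprintf("<copula_fit> order %d (%s), loglik = %.3f, k = %d, AIC = %.3f%s\n",
              x$p, x$restriction, x$loglik, x$k, x$aic,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$model)
  invisible(x)
}

#' @export
logLik.copula_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n_obs, class = "logLik")
}

#' Akaike information criterion of a fit
#'
#' `-2 loglik + 2 k` with `k` the number of free parameters actually
#' optimized. Errors if the fit did not converge.
#'
#' @param fr a `copula_fit`.
#' @return AIC value.
#' @export
aic <- function(fr) {
  if (!inherits(fr, "copula_fit")) stop("fr must be a copula_fit")
  if (!fr$converged) stop("AIC of a non-converged fit is not meaningful")
  -2 * fr$loglik + 2 * fr$k
}

#' Joint conditional log-likelihood of a trialset under a given model
#'
#' Sums [mixed_pair_loglik()] over `t = p+1 .. n_bins` within every trial
#' (the first `p` bins condition only), over all trials.
#'
#' @param model a [joint_model()].
#' @param ts a binary-mode [trialset()] with at least `p + 1` bins.
#' @return Total log-likelihood.
#' @export
joint_loglik <- function(model, ts) {
  .check_binary(ts)
  d <- .design(ts, model$p)
  theta <- .model_to_theta(model, "full")
  Zy <- cbind(1, d$Hy, d$Hx)
  Zx <- cbind(1, d$Hx, d$Hy)
  -cop_nll(theta, Zy, Zx, d$Y, d$X)
}

#' Select the model order by AIC
#'
#' Fits the full model at every candidate order with a common conditioning
#' length (`max(candidates)` initial bins per trial) so all AICs are computed
#' on identical observations, and returns the AIC-minimizing order. Ties
#' break toward the smaller order (parsimony). Non-converged candidates are
#' recorded as `NA` in the table and never selected.
#'
#' @param ts a binary-mode [trialset()].
#' @param candidates orders to try, e.g. `2:6`.
#' @return List with `best` (selected order) and `table` (named AIC vector,
#'   `NA` for non-converged candidates).
#' @export
select_order <- function(ts, candidates) {
  candidates <- sort(unique(as.integer(candidates)))
  if (!length(candidates)) stop("candidates must be nonempty")
  cond <- max(candidates)
  tab <- stats::setNames(rep(NA_real_, length(candidates)), candidates)
  for (i in seq_along(candidates)) {
    fr <- fit_copula(ts, candidates[i], "full", cond_bins = cond)
    if (fr$converged) tab[i] <- fr$aic
  }
  if (all(is.na(tab))) stop("no candidate order converged")
  best <- candidates[which.min(tab)]   # which.min ignores NA; ties -> first (smaller p)
  list(best = best, table = tab)
}

#' Read and write fitted models as flat text
#'
#' `key=value` lines; coefficient vectors comma-separated; round-trippable at
#' full double precision.
#'
#' @param fr a `copula_fit`.
#' @param path file path.
#' @return `write_fit` returns `path` invisibly; `read_fit` a `copula_fit`.
#' @export
write_fit <- function(fr, path) {
  m <- fr$model
  vec <- function(v) paste(.fmt(v), collapse = ",")
  writeLines(c(
    sprintf("order=%d", m$p),
    sprintf("restriction=%s", fr$restriction),
    sprintf("c_y=%s", .fmt(m$c_y)), sprintf("a=%s", vec(m$a)),
    sprintf("b=%s", vec(m$b)), sprintf("sigma=%s", .fmt(m$sigma)),
    sprintf("c_x=%s", .fmt(m$c_x)), sprintf("d=%s", vec(m$d)),
    sprintf("e=%s", vec(m$e)), sprintf("rho=%s", .fmt(m$rho)),
    sprintf("loglik=%s", .fmt(fr$loglik)), sprintf("k=%d", fr$k),
    sprintf("aic=%s", .fmt(fr$aic)),
    sprintf("converged=%s", fr$converged),
    sprintf("n_obs=%d", fr$n_obs)
  ), path)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, function(x) paste(x[-1], collapse = "="), ""),
                          vapply(kv, `[`, "", 1))
  num <- function(key) as.numeric(strsplit(vals[[key]], ",", fixed = TRUE)[[1]])
  p <- as.integer(vals[["order"]])
  model <- joint_model(p, c_y = num("c_y"), a = num("a"), b = num("b"),
                       sigma = num("sigma"), c_x = num("c_x"), d = num("d"),
                       e = num("e"), rho = num("rho"))
  structure(list(model = model, loglik = num("loglik"),
                 k = as.integer(vals[["k"]]), aic = num("aic"),
                 converged = as.logical(vals[["converged"]]),
                 n_obs = as.integer(vals[["n_obs"]]),
                 restriction = vals[["restriction"]], p = p),
            class = "copula_fit")
}
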