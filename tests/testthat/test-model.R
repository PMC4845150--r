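test_that("cond_means evaluates the linear predictors (trivial and random cases)", {
  m <- joint_model(1)
  cm <- cond_means(m, 0, 0L)
  expect_equal(cm$mu_y, 0)
  expect_equal(cm$pi, 0.5)

  m2 <- joint_model(1, a = 0.5)
  expect_equal(cond_means(m2, 2, 0L)$mu_y, 1)

  expect_error(cond_means(m2, c(1, 2), c(0L, 1L)), "length p = 1")

  # independent dot-product oracle for random draws
  set.seed(11)
  for (i in 1:10) {
    m3 <- random_model(2)
    yh <- rnorm(2); xh <- rbinom(2, 1, 0.5)
    cm3 <- cond_means(m3, yh, xh)
    expect_equal(cm3$mu_y, m3$c_y + m3$a[1] * yh[1] + m3$a[2] * yh[2] +
                   m3$b[1] * xh[1] + m3$b[2] * xh[2])
    expect_equal(cm3$eta_x, m3$c_x + m3$d[1] * xh[1] + m3$d[2] * xh[2] +
                   m3$e[1] * yh[1] + m3$e[2] * yh[2])
  }
})

test_that("mixed_pair_loglik: independence factorization at rho = 0 is exact", {
  set.seed(12)
  for (i in 1:10) {
    m <- random_model(2)
    m$rho <- 0
    yh <- rnorm(2); xh <- rbinom(2, 1, 0.5); y <- rnorm(1)
    cm <- cond_means(m, yh, xh)
    for (x in 0:1) {
      expected <- dnorm(y, cm$mu_y, m$sigma, log = TRUE) +
        pnorm(if (x == 1) cm$eta_x else -cm$eta_x, log.p = TRUE)
      expect_identical(mixed_pair_loglik(m, x, y, yh, xh), expected)
    }
  }
})

test_that("mixed_pair_loglik matches the bivariate-normal conditional oracle", {
  # rho=0.5, sigma=1, mu=0, eta=0, observation (x=1, y=1):
  # log[ Normal pdf(1) * Phi(0.5 * 1 / sqrt(1 - 0.25)) ]
  m <- joint_model(1, rho = 0.5)
  val <- mixed_pair_loglik(m, 1, 1, 0, 0L)
  expect_equal(val, log(dnorm(1) * pnorm(0.5 / sqrt(0.75))), tolerance = 1e-12)

  # guard rails
  expect_error(mixed_pair_loglik(joint_model(1), 2, 0, 0, 0L), "0 or 1")
})

test_that("mixed density integrates to 1 and honors the spike margin (spot check)", {
  set.seed(13)
  for (i in 1:5) {
    m <- random_model(2)
    yh <- rnorm(2); xh <- rbinom(2, 1, 0.5)
    expect_equal(bf_density_mass(m, yh, xh), 1, tolerance = 1e-6)
    expect_equal(bf_margin_mass(m, yh, xh),
                 cond_means(m, yh, xh)$pi, tolerance = 1e-6)
  }
})

test_that("joint_loglik reduces to a single mixed_pair_loglik term and is additive", {
  m <- random_model(2, seed = 14)
  ts1 <- tiny_trialset(n_trials = 1, n_bins = 3)
  expect_equal(joint_loglik(m, ts1),
               mixed_pair_loglik(m, ts1$spikes[1, 3], ts1$lfp[1, 3],
                                 ts1$lfp[1, 2:1], ts1$spikes[1, 2:1]))

  ts <- tiny_trialset(n_trials = 2, n_bins = 8)
  doubled <- ts_subset_trials(ts, c(1, 2, 1, 2))
  expect_equal(joint_loglik(m, doubled), 2 * joint_loglik(m, ts))
})

test_that("joint_loglik matches the brute-force oracle on tiny instances", {
  set.seed(15)
  for (i in 1:20) {
    p <- sample(1:2, 1)
    m <- random_model(p)
    ts <- tiny_trialset(n_trials = sample(1:2, 1), n_bins = sample((p + 2):8, 1),
                        seed = 100 + i)
    expect_equal(joint_loglik(m, ts), bf_joint_loglik(m, ts), tolerance = 1e-10)
  }
})

test_that("the analytic likelihood gradient matches finite differences", {
  m <- random_model(2, seed = 16)
  ts <- simulate_mixed(sim_config(null_model(), n_trials = 4, n_bins = 60,
                                  onset_bin = 1, seed = 16))
  d <- copulagc:::.design(ts, 2)
  Zy <- cbind(1, d$Hy, d$Hx)
  Zx <- cbind(1, d$Hx, d$Hy)
  th <- copulagc:::.model_to_theta(m, "full")
  g <- copulagc:::cop_nll_grad(th, Zy, Zx, d$Y, d$X)
  gn <- vapply(seq_along(th), function(j) {
    h <- 1e-6
    tp <- th; tp[j] <- tp[j] + h
    tm <- th; tm[j] <- tm[j] - h
    (copulagc:::cop_nll(tp, Zy, Zx, d$Y, d$X) -
       copulagc:::cop_nll(tm, Zy, Zx, d$Y, d$X)) / (2 * h)
  }, 0)
  expect_equal(g, gn, tolerance = 1e-5)
})

test_that("fit_copula recovers parameters, counts k correctly, dominates nested fits", {
  gen <- joint_model(2, c_y = 0.1, a = c(0.5, -0.3), b = c(0.4, -0.2), sigma = 1,
                     c_x = -1.3, d = c(-0.5, 0.2), e = c(0.25, -0.1), rho = 0.3)
  ts <- simulate_mixed(sim_config(gen, n_trials = 60, n_bins = 300,
                                  onset_bin = 1, seed = 17))
  fr <- fit_copula(ts, 2)
  expect_true(fr$converged)
  expect_equal(fr$k, 4 * 2 + 4)   # free parameters actually optimized
  expect_equal(fr$n_obs, 60 * (300 - 2))
  m <- fr$model
  expect_lt(abs(m$rho - 0.3), 0.08)
  est <- c(m$c_y, m$a, m$b, m$c_x, m$d, m$e)
  tru <- c(gen$c_y, gen$a, gen$b, gen$c_x, gen$d, gen$e)
  expect_lt(sqrt(mean((est - tru)^2)), 0.08)

  for (restr in c("no_spike_to_lfp", "no_lfp_to_spike")) {
    fr_r <- fit_copula(ts, 2, restr)
    expect_equal(fr_r$k, 3 * 2 + 4)
    expect_lte(fr_r$loglik, fr$loglik)   # nested maximization dominance
    blocked <- if (restr == "no_spike_to_lfp") fr_r$model$b else fr_r$model$e
    expect_identical(blocked, c(0, 0))
  }

  # reported loglik is reproducible from the fitted model
  expect_equal(fr$loglik, joint_loglik(fr$model, ts), tolerance = 1e-8)
})

test_that("fit_copula rejects degenerate and non-binary spike channels", {
  ts <- tiny_trialset(n_bins = 40)
  ts$spikes[] <- 0L
  expect_error(fit_copula(ts, 2), "degenerate spike channel")
  tsc <- trialset(matrix(rnorm(80), 2), matrix(2L, 2, 40), fs = 1000, mode = "count")
  expect_error(fit_copula(tsc, 2), "binary")
})

test_that("null cross-coefficients are recovered as null (3 SE coverage)", {
  # generator with b = e = 0, rho = 0: fitted b, e should sit within 3
  # standard errors of zero in nearly all replicates
  n_rep <- 25
  hits <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    ts <- simulate_mixed(sim_config(null_model(), n_trials = 25, n_bins = 200,
                                    onset_bin = 1, seed = 600 + r))
    fr <- fit_copula(ts, 2, hessian = TRUE)
    th <- copulagc:::.model_to_theta(fr$model, "full")
    idx <- c(4, 5, 10, 11)      # b1, b2, e1, e2 positions in theta
    hits[r] <- all(abs(th[idx]) < 3 * fr$se[idx])
  }
  expect_gte(sum(hits), 22)
})

test_that("aic follows the definition and an independent recomputation", {
  fr <- structure(list(loglik = -100, k = 10, converged = TRUE),
                  class = "copula_fit")
  expect_equal(aic(fr), 220)
  fr2 <- fr; fr2$k <- 11
  expect_equal(aic(fr2) - aic(fr), 2)
  fr$converged <- FALSE
  expect_error(aic(fr), "non-converged")

  ts <- simulate_mixed(sim_config(null_model(), n_trials = 10, n_bins = 100,
                                  onset_bin = 1, seed = 18))
  f <- fit_copula(ts, 2)
  expect_equal(aic(f), -2 * joint_loglik(f$model, ts) + 2 * f$k, tolerance = 1e-8)
})

test_that("select_order returns singletons unconditionally and prefers parsimony under white noise", {
  ts <- simulate_mixed(sim_config(null_model(), n_trials = 10, n_bins = 120,
                                  onset_bin = 1, seed = 19))
  sel <- select_order(ts, 3)
  expect_equal(sel$best, 3L)
  expect_equal(names(sel$table), "3")

  # memoryless generator: all lag coefficients zero -> smallest candidate
  # should win in the majority of replicates
  wn <- joint_model(2, sigma = 1, c_x = -1.5)
  picks <- vapply(1:50, function(r) {
    tsw <- simulate_mixed(sim_config(wn, n_trials = 8, n_bins = 100,
                                     onset_bin = 1, seed = 700 + r))
    select_order(tsw, 1:3)$best
  }, 0L)
  expect_gt(mean(picks == 1L), 0.5)
})

test_that("fit serialization round-trips", {
  ts <- simulate_mixed(sim_config(null_model(), n_trials = 8, n_bins = 80,
                                  onset_bin = 1, seed = 20))
  fr <- fit_copula(ts, 2)
  f <- tempfile()
  write_fit(fr, f)
  back <- read_fit(f)
  expect_equal(back$model, fr$model, tolerance = 1e-15)
  expect_equal(back$loglik, fr$loglik)
  expect_identical(back$k, fr$k)
  expect_identical(back$converged, fr$converged)
})
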