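test_that("gc is nonnegative and permutation p-values stay in their support", {
  for (r in 1:5) {
    ts <- simulate_mixed(sim_config(null_model(), n_trials = 8, n_bins = 100,
                                    onset_bin = 1, seed = 800 + r))
    g <- gc_directional(ts, 2, "spike_to_lfp", n_perm = 19, seed = r)
    expect_gte(g$gc, 0)
    expect_gte(g$p_value, 1 / 20)
    expect_lte(g$p_value, 1)
  }
})

test_that("early stopping never changes the alpha-level decision", {
  for (r in 1:4) {
    ts <- simulate_mixed(sim_config(null_model(), n_trials = 8, n_bins = 100,
                                    onset_bin = 1, seed = 820 + r))
    gf <- gc_directional(ts, 2, "lfp_to_spike", n_perm = 39, seed = r)
    ge <- gc_directional(ts, 2, "lfp_to_spike", n_perm = 39, seed = r,
                         early_stop_alpha = 0.05)
    expect_identical(ge$p_value <= 0.05, gf$p_value <= 0.05)
  }
})

test_that("sliding_gc tiles the trial, rejects short windows, degenerates cleanly", {
  ts <- simulate_mixed(sim_config(null_model(), n_trials = 8, n_bins = 200,
                                  onset_bin = 101, seed = 21))
  expect_error(sliding_gc(ts, 2, window_ms = 10), "need >= 20 bins")

  tc <- sliding_gc(ts, 2, "spike_to_lfp", window_ms = 50, step_ms = 50, n_boot = 0)
  expect_equal(length(tc$gc), 4L)
  expect_true(all(tc$sem == 0))
  expect_true(all(tc$gc >= 0))
  # window gc equals the pooled fit on that window's bins
  direct <- copulagc:::.gc_stat(ts_window_bins(ts, 1, 50), 2, "no_spike_to_lfp")$gc
  expect_equal(tc$gc[1], direct)
  # centers are means of each window's time axis
  expect_equal(tc$window_centers[1], mean(ts$t[1:50]))

  tcb <- sliding_gc(ts, 2, "spike_to_lfp", window_ms = 100, step_ms = 100,
                    n_boot = 5, seed = 1)
  expect_true(all(tcb$sem >= 0))
  tcb2 <- sliding_gc(ts, 2, "spike_to_lfp", window_ms = 100, step_ms = 100,
                     n_boot = 5, seed = 1)
  expect_identical(tcb$sem, tcb2$sem)   # seeded bootstrap is deterministic
})

test_that("normalize_gc: baseline mean 1, scale invariance, idempotence, guards", {
  tc <- structure(list(direction = "spike_to_lfp",
                       window_centers = seq(-250, 250, by = 100),
                       gc = c(2, 2, 2, 4, 6, 4), sem = rep(0.5, 6),
                       n_trials = 10L, window_ms = 100, step_ms = 100,
                       order = 2L, n_boot = 10L),
                  class = "gc_timecourse")
  nz <- normalize_gc(tc, c(-300, 0))
  expect_equal(mean(nz$gc[nz$window_centers < 0]), 1)
  expect_equal(nz$gc, tc$gc / 2)
  expect_equal(nz$sem, tc$sem / 2)

  # constant curve -> all ones
  tcc <- tc; tcc$gc <- rep(3, 6)
  expect_equal(normalize_gc(tcc, c(-300, 0))$gc, rep(1, 6))

  # doubling gc leaves the normalized curve unchanged
  tc2 <- tc; tc2$gc <- 2 * tc$gc; tc2$sem <- 2 * tc$sem
  expect_equal(normalize_gc(tc2, c(-300, 0))$gc, nz$gc)

  # idempotence
  expect_equal(normalize_gc(nz, c(-300, 0))$gc, nz$gc)

  # guards
  tc0 <- tc; tc0$gc[1:3] <- 0
  expect_error(normalize_gc(tc0, c(-300, 0)), "zero or near-zero")
  expect_error(normalize_gc(tc, c(-900, -600)), "no window centers")
})

test_that("compare_conditions: self-comparison, antisymmetry, grid checks", {
  tc <- structure(list(direction = "spike_to_lfp",
                       window_centers = seq(-150, 250, by = 100),
                       gc = c(1, 1, 1.5, 2, 2.5), sem = rep(0.2, 5),
                       n_trials = 10L, window_ms = 100, step_ms = 100,
                       order = 2L, n_boot = 10L),
                  class = c("gc_normalized", "gc_timecourse"))
  expect_equal(compare_conditions(tc, tc, c(0, 300)), 0)

  tb <- tc; tb$gc <- tc$gc + 0.5
  s1 <- compare_conditions(tc, tb, c(0, 300))
  expect_gt(s1, 0)
  expect_equal(compare_conditions(tb, tc, c(0, 300)), -s1)

  tg <- tb; tg$window_centers <- tb$window_centers + 1
  expect_error(compare_conditions(tc, tg, c(0, 300)), "grids differ")

  t0 <- tc; t0$sem <- rep(0, 5)
  expect_equal(compare_conditions(t0, t0, c(0, 300)), 0)
  tb0 <- t0; tb0$gc <- t0$gc + 1
  expect_error(compare_conditions(t0, tb0, c(0, 300)), "pooled SEM is zero")
})

test_that("gc tables round-trip through the delimited format", {
  ts <- simulate_mixed(sim_config(null_model(), n_trials = 8, n_bins = 200,
                                  onset_bin = 101, seed = 22))
  tc <- sliding_gc(ts, 2, "lfp_to_spike", window_ms = 100, step_ms = 50,
                   n_boot = 4, seed = 2)
  nz <- normalize_gc(tc, c(-100, 0))
  f <- tempfile()
  write_gc_table(tc, f, normalized = nz)
  back <- read_gc_table(f)
  expect_equal(back$tc$gc, tc$gc)
  expect_equal(back$tc$sem, tc$sem)
  expect_equal(back$tc$window_centers, tc$window_centers)
  expect_identical(back$tc$direction, "lfp_to_spike")
  expect_equal(back$normalized$gc, nz$gc)
  expect_equal(back$normalized$baseline_window, c(-100, 0))
})
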