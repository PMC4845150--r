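# Directional Granger causality from nested copula fits.
#
# GC is defined on a per-observation deviance scale so the two directions
# (continuous target vs discrete target) are commensurable:
#   gc = (2 / n_obs) * (loglik_full - loglik_reduced)
# where the reduced model drops the cross-history block of the tested
# direction (b for spike->lfp, e for lfp->spike). Nested maximization makes
# gc >= 0; a restart of the full fit from the reduced optimum enforces the
# nesting numerically when the default warm start underperforms.

.gc_stat <- function(ts, p, restriction, cond_bins = p) {
  fr_red <- fit_copula(ts, p, restriction, cond_bins = cond_bins)
  fr_full <- fit_copula(ts, p, "full", cond_bins = cond_bins)
  if (fr_full$loglik < fr_red$loglik) {
    fr2 <- fit_copula(ts, p, "full", start = fr_red$model, cond_bins = cond_bins)
    if (fr2$loglik > fr_full$loglik) fr_full <- fr2
  }
  list(gc = max(0, 2 * (fr_full$loglik - fr_red$loglik) / fr_full$n_obs),
       full = fr_full, reduced = fr_red)
}

.circ_shift_rows <- function(m, shifts) {
  nb <- ncol(m)
  for (r in seq_len(nrow(m))) {
    s <- shifts[r] %% nb
    if (s > 0L) m[r, ] <- m[r, c((s + 1L):nb, 1L:s)]
  }
  m
}

#' Directional Granger causality with permutation inference
#'
#' Likelihood-ratio GC between the full copula fit and the nested fit with
#' the tested direction's cross-history removed. The null distribution is
#' built by per-trial circular shifts of the source channel, which preserve
#' each channel's autocorrelation while breaking their alignment.
#'
#' @param ts a binary-mode [trialset()].
#' @param p model order.
#' @param direction `"spike_to_lfp"` (tests the `b` block) or
#'   `"lfp_to_spike"` (tests the `e` block).
#' @param n_perm number of permutations (0 = no p-value; use >= 200 for
#'   inference).
#' @param seed optional RNG seed for the permutations.
#' @param early_stop_alpha optional significance level; when set, the
#'   permutation loop stops as soon as non-rejection at this level is
#'   certain (enough permuted statistics already exceed the observed one
#'   that the full-run p-value would exceed the level). The reported
#'   p-value is then a lower bound on the full-run value, but the decision
#'   `p_value <= early_stop_alpha` is identical to the full run's.
#' @return `gc_result` with fields `gc` (nonnegative), `p_value`
#'   (`(1 + #\{perm >= obs\}) / (n_perm + 1)`, `NA` if `n_perm = 0`),
#'   `fit_full`, `fit_reduced`.
#' @export
gc_directional <- function(ts, p, direction = c("spike_to_lfp", "lfp_to_spike"),
                           n_perm = 0L, seed = NULL, early_stop_alpha = NULL) {
  direction <- match.arg(direction)
  restriction <- switch(direction, spike_to_lfp = "no_spike_to_lfp",
                        lfp_to_spike = "no_lfp_to_spike")
  st <- .gc_stat(ts, p, restriction)
  if (!st$full$converged) stop("full-model fit failed to converge")
  if (!st$reduced$converged) stop(sprintf("reduced-model (%s) fit failed to converge", restriction))
  p_value <- NA_real_
  if (n_perm > 0L) {
    if (!is.null(seed)) set.seed(seed)
    nb <- ncol(ts$spikes)
    nt <- ts$n_trials
    # K exceedances among all n_perm draws would give p = (1+K)/(n_perm+1);
    # once K reaches kstop, p > early_stop_alpha is certain.
    kstop <- if (is.null(early_stop_alpha)) n_perm + 1L
             else floor(early_stop_alpha * (n_perm + 1) - 1) + 1L
    k <- 0L
    n_done <- 0L
    for (i in seq_len(n_perm)) {
      sh <- sample.int(nb - 1L, nt, replace = TRUE)
      ts2 <- ts
      if (direction == "spike_to_lfp") {
        ts2$spikes <- .circ_shift_rows(ts$spikes, sh)
      } else {
        ts2$lfp <- .circ_shift_rows(ts$lfp, sh)
      }
      if (.gc_stat(ts2, p, restriction)$gc >= st$gc) k <- k + 1L
      n_done <- i
      if (k >= kstop) break
    }
    p_value <- (1 + k) / (n_done + 1)
  }
  structure(list(direction = direction, gc = st$gc, p_value = p_value,
                 n_perm = n_perm, fit_full = st$full, fit_reduced = st$reduced),
            class = "gc_result")
}

#' @export
print.gc_result <- function(x, ...) {
  cat(sprintf("<gc_result> %s: gc = %.5g, p = %s (%d permutations)\n",
              x$direction, x$gc,
              if (is.na(x$p_value)) "NA" else format(x$p_value), x$n_perm))
  invisible(x)
}

#' Time-resolved Granger causality over sliding windows
#'
#' Per window, pools that window's bins across all trials, computes the
#' directional GC, and estimates its SEM by a bootstrap over trials
#' (resampling trials with replacement and recomputing the pooled GC).
#'
#' @inheritParams gc_directional
#' @param window_ms,step_ms window length and step in ms; the window must
#'   hold at least `10 * p` bins.
#' @param n_boot bootstrap resamples per window (0 = SEM reported as 0).
#' @param seed RNG seed for the bootstrap.
#' @return `gc_timecourse` with `window_centers` (ms), `gc`, `sem`,
#'   `n_trials` and the design parameters.
#' @export
sliding_gc <- function(ts, p, direction = c("spike_to_lfp", "lfp_to_spike"),
                       window_ms = 100, step_ms = 10, n_boot = 0L, seed = NULL) {
  direction <- match.arg(direction)
  restriction <- switch(direction, spike_to_lfp = "no_spike_to_lfp",
                        lfp_to_spike = "no_lfp_to_spike")
  nb <- ncol(ts$lfp)
  wb <- round(window_ms * ts$fs / 1000)
  min_wb <- 10L * as.integer(p)
  if (wb < min_wb) {
    stop(sprintf("window too short for order %d: need >= %d bins (%g ms)",
                 p, min_wb, min_wb * 1000 / ts$fs))
  }
  sb <- max(1L, round(step_ms * ts$fs / 1000))
  starts <- seq.int(1L, nb - wb + 1L, by = sb)
  if (!is.null(seed)) set.seed(seed)
  nt <- ts$n_trials
  gc <- sem <- centers <- numeric(length(starts))
  for (w in seq_along(starts)) {
    tw <- ts_window_bins(ts, starts[w], starts[w] + wb - 1L)
    gc[w] <- .gc_stat(tw, p, restriction)$gc
    if (n_boot > 0L) {
      bo <- vapply(seq_len(n_boot), function(i) {
        idx <- sample.int(nt, nt, replace = TRUE)
        .gc_stat(ts_subset_trials(tw, idx), p, restriction)$gc
      }, 0)
      sem[w] <- stats::sd(bo)
    }
    centers[w] <- mean(tw$t)
  }
  structure(list(direction = direction, window_centers = centers, gc = gc,
                 sem = sem, n_trials = nt, window_ms = window_ms,
                 step_ms = step_ms, order = as.integer(p), n_boot = n_boot),
            class = "gc_timecourse")
}

#' @export
print.gc_timecourse <- function(x, ...) {
  norm <- inherits(x, "gc_normalized")
  cat(sprintf("<%s> %s, order %d, %d windows (%g ms / step %g ms), %d trials\n",
              if (norm) "gc_normalized" else "gc_timecourse",
              x$direction, x$order, length(x$gc), x$window_ms, x$step_ms,
              x$n_trials))
  if (norm) cat(sprintf("  baseline [%g, %g) ms\n", x$baseline_window[1], x$baseline_window[2]))
  print(data.frame(center_ms = round(x$window_centers, 2),
                   gc = signif(x$gc, 5), sem = signif(x$sem, 5)))
  invisible(x)
}

#' Normalize a GC timecourse against its pre-stimulus baseline
#'
#' Divisive normalization: every window's GC (and SEM) is divided by the
#' mean GC over windows whose centers fall in `baseline_window` (default the
#' fixation period, `[-300, 0)` ms), so the baseline mean of the normalized
#' curve is 1 and conditions become comparable.
#'
#' @param tc a `gc_timecourse`.
#' @param baseline_window `c(lo, hi)` in ms, half-open `[lo, hi)`.
#' @return `gc_normalized` (also a `gc_timecourse`); values dimensionless.
#' @export
normalize_gc <- function(tc, baseline_window = c(-300, 0)) {
  idx <- tc$window_centers >= baseline_window[1] & tc$window_centers < baseline_window[2]
  if (!any(idx)) stop("baseline window contains no window centers")
  base <- mean(tc$gc[idx])
  if (!is.finite(base) || base <= 1e-12 * max(abs(tc$gc), 1)) {
    stop("baseline mean is zero or near-zero; divisive normalization undefined")
  }
  out <- tc
  out$gc <- tc$gc / base
  out$sem <- tc$sem / base
  out$baseline_window <- as.numeric(baseline_window)
  class(out) <- unique(c("gc_normalized", class(tc)))
  out
}

#' Standardized contrast between two normalized GC timecourses
#'
#' `separation = mean over the evaluation window of (b - a), divided by the
#' pooled bootstrap SEM over the same window`; positive when `tc_b` exceeds
#' `tc_a` (so with "1-bar" as `tc_a` and "7-bar" as `tc_b`, a positive value
#' means the contour condition carries the stronger normalized GC).
#'
#' @param tc_a,tc_b `gc_normalized` curves on identical window grids.
#' @param eval_window `c(lo, hi)` ms, half-open.
#' @return Scalar standardized separation.
#' @export
compare_conditions <- function(tc_a, tc_b, eval_window = c(0, 500)) {
  if (!isTRUE(all.equal(tc_a$window_centers, tc_b$window_centers))) {
    stop("window grids differ between the two timecourses")
  }
  idx <- tc_a$window_centers >= eval_window[1] & tc_a$window_centers < eval_window[2]
  if (!any(idx)) stop("evaluation window contains no window centers")
  dbar <- mean(tc_b$gc[idx] - tc_a$gc[idx])
  pooled <- sqrt(mean(tc_a$sem[idx]^2) + mean(tc_b$sem[idx]^2))
  if (pooled == 0) {
    if (dbar == 0) return(0)
    stop("pooled SEM is zero (run the bootstrap); separation undefined")
  }
  dbar / pooled
}

#' Read and write GC timecourse tables
#'
#' Delimited text: `#key=value` header lines recording direction, order,
#' window, step, n_trials, n_boot (and baseline for normalized curves), then
#' tab-separated columns `window_center_ms`, `gc`, `sem` and, when a
#' normalized companion is given, `gc_norm`, `sem_norm`.
#'
#' @param tc a `gc_timecourse`.
#' @param path file path.
#' @param normalized optional `gc_normalized` companion on the same grid.
#' @return `write_gc_table` returns `path` invisibly; `read_gc_table` a list
#'   with elements `tc` and (possibly `NULL`) `normalized`.
#' @export
write_gc_table <- function(tc, path, normalized = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(sprintf("#direction=%s", tc$direction),
           sprintf("#order=%d", tc$order),
           sprintf("#window_ms=%s", .fmt(tc$window_ms)),
           sprintf("#step_ms=%s", .fmt(tc$step_ms)),
           sprintf("#n_trials=%d", tc$n_trials),
           sprintf("#n_boot=%d", tc$n_boot))
  if (!is.null(normalized)) {
    hdr <- c(hdr, sprintf("#baseline=%s:%s", .fmt(normalized$baseline_window[1]),
                          .fmt(normalized$baseline_window[2])))
  }
  writeLines(hdr, con)
  cols <- c("window_center_ms", "gc", "sem")
  m <- cbind(tc$window_centers, tc$gc, tc$sem)
  if (!is.null(normalized)) {
    cols <- c(cols, "gc_norm", "sem_norm")
    m <- cbind(m, normalized$gc, normalized$sem)
  }
  writeLines(paste(cols, collapse = "\t"), con)
  utils::write.table(matrix(.fmt(m), nrow(m)), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gc_table
#' @export
read_gc_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getf <- function(key, default = NA) {
    m <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (!length(m)) return(default)
    sub(paste0("^#", key, "="), "", m[1])
  }
  body <- lines[!grepl("^#", lines)]
  cols <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  m <- do.call(rbind, lapply(strsplit(body[-1], "\t", fixed = TRUE), as.numeric))
  colnames(m) <- cols
  tc <- structure(list(direction = getf("direction"),
                       window_centers = m[, "window_center_ms"],
                       gc = m[, "gc"], sem = m[, "sem"],
                       n_trials = as.integer(getf("n_trials", "0")),
                       window_ms = as.numeric(getf("window_ms", "NA")),
                       step_ms = as.numeric(getf("step_ms", "NA")),
                       order = as.integer(getf("order", "0")),
                       n_boot = as.integer(getf("n_boot", "0"))),
                  class = "gc_timecourse")
  normalized <- NULL
  if ("gc_norm" %in% cols) {
    normalized <- tc
    normalized$gc <- m[, "gc_norm"]
    normalized$sem <- m[, "sem_norm"]
    bl <- getf("baseline")
    if (!is.na(bl)) {
      normalized$baseline_window <- as.numeric(strsplit(bl, ":", fixed = TRUE)[[1]])
    }
    class(normalized) <- c("gc_normalized", "gc_timecourse")
  }
  list(tc = tc, normalized = normalized)
}

#' Plot a GC timecourse with its SEM band
#'
#' @param x a `gc_timecourse`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gc_timecourse <- function(x, ...) {
  ylab <- if (inherits(x, "gc_normalized")) "normalized GC" else "GC"
  graphics::plot(x$window_centers, x$gc, type = "l",
                 xlab = "time from stimulus onset (ms)", ylab = ylab, ...)
  if (any(x$sem > 0)) {
    graphics::polygon(c(x$window_centers, rev(x$window_centers)),
                      c(x$gc - x$sem, rev(x$gc + x$sem)),
                      border = NA, col = grDevices::adjustcolor("grey", 0.5))
    graphics::lines(x$window_centers, x$gc)
  }
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}
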