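# Spike-artifact removal from the LFP channel.
#
# Stand-in for Bayesian waveform-removal approaches: the artifact is modeled
# as a single trial-invariant template entering the LFP linearly at every
# spike time, and is estimated by least squares — the LFP regressed on
# shifted copies of the spike train over the artifact window. This
# "deconvolved spike-triggered average" is exact under linear superposition
# even when artifact windows of nearby spikes overlap.

#' Estimate the spike-artifact template by least squares
#'
#' @param ts a [trialset()] whose LFP may carry spike-locked leakage.
#' @param window_ms artifact extent in ms from the spike bin (lags
#'   `0 .. round(window_ms * fs / 1000) - 1`).
#' @return `artifact_model` with fields `template`, `window_ms`,
#'   `n_spikes_used`. Errors when the trialset has no spikes; warns below 20
#'   spikes (template poorly determined).
#' @export
estimate_artifact_template <- function(ts, window_ms = 5) {
  n_spk <- sum(ts$spikes)
  if (n_spk == 0L) stop("cannot estimate an artifact template without spikes")
  if (n_spk < 20L) warning(sprintf("only %d spikes; artifact template is poorly determined", n_spk))
  L <- max(1L, round(window_ms * ts$fs / 1000))
  nb <- ncol(ts$spikes)
  n <- nrow(ts$spikes) * nb
  S <- matrix(0, n, L)
  for (j in seq_len(L)) {
    Sj <- matrix(0, nrow(ts$spikes), nb)
    Sj[, j:nb] <- ts$spikes[, 1:(nb - j + 1L), drop = FALSE]
    S[, j] <- as.vector(Sj)
  }
  fit <- stats::lm.fit(S, as.vector(ts$lfp))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  structure(list(template = unname(beta), window_ms = window_ms,
                 n_spikes_used = n_spk),
            class = "artifact_model")
}

#' @export
print.artifact_model <- function(x, ...) {
  cat(sprintf("<artifact_model> %d-bin template (%g ms) from %d spikes\n",
              length(x$template), x$window_ms, x$n_spikes_used))
  print(signif(x$template, 5))
  invisible(x)
}

#' Subtract the spike-locked artifact from the LFP
#'
#' `lfp' = lfp - (spikes convolved with template)`; spikes unchanged. Exact
#' inverse of [inject_spike_artifacts()] when the template matches.
#'
#' @param ts a [trialset()].
#' @param am an `artifact_model` (or a bare numeric template).
#' @return The despiked `trialset`.
#' @export
remove_spike_artifacts <- function(ts, am) {
  template <- if (inherits(am, "artifact_model")) am$template else as.numeric(am)
  if (!all(is.finite(template))) stop("template must be finite")
  ts$lfp <- ts$lfp - .conv_spikes(ts$spikes, template)
  ts
}
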