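#' Generative configuration for the mixed spike/LFP simulator
#'
#' The defaults emulate the recorded V4 trial structure: 1 kHz sampling,
#' 300 ms fixation + 500 ms stimulus + 300 ms delay (1100 bins, onset at bin
#' 301 so `t = 0` is stimulus onset) and 146 trials.
#'
#' @param model generating [joint_model()] (used before `onset_bin` and, if
#'   no `post_onset_model` is given, throughout).
#' @param n_trials,n_bins,fs trial count, bins per trial, sampling rate (Hz).
#' @param onset_bin 1-based index of the first post-onset bin; from this bin
#'   on, `post_onset_model` (if given) replaces `model`.
#' @param post_onset_model optional [joint_model()] active from `onset_bin`.
#' @param contamination optional `list(template =, gain =)` spike-waveform
#'   leakage added to the LFP after generation (see
#'   [inject_spike_artifacts()]).
#' @param condition condition label.
#' @param seed integer seed; fully determines the output.
#' @return A `sim_config` object.
#' @export
sim_config <- function(model, n_trials = 146L, n_bins = 1100L, fs = 1000,
                       onset_bin = 301L, post_onset_model = NULL,
                       contamination = NULL, condition = "unlabeled",
                       seed = 1L) {
  stopifnot(inherits(model, "joint_model"),
            is.null(post_onset_model) || inherits(post_onset_model, "joint_model"))
  if (!is.null(post_onset_model) && post_onset_model$p != model$p) {
    stop("pre- and post-onset models must share the order p")
  }
  if (!is.null(contamination)) {
    stopifnot(is.list(contamination), all(is.finite(contamination$template)),
              is.finite(contamination$gain))
  }
  structure(list(model = model, n_trials = as.integer(n_trials),
                 n_bins = as.integer(n_bins), fs = fs,
                 onset_bin = as.integer(onset_bin),
                 post_onset_model = post_onset_model,
                 contamination = contamination, condition = condition,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.spectral_radius <- function(a) {
  p <- length(a)
  comp <- if (p == 1L) matrix(a, 1, 1) else rbind(a, cbind(diag(p - 1L), 0))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

.check_stable <- function(model, label) {
  sr <- .spectral_radius(model$a)
  if (sr >= 1) {
    stop(sprintf("unstable continuous AR in %s model: spectral radius %.4f >= 1",
                 label, sr))
  }
  invisible(sr)
}

#' Simulate a trial set from the joint copula generative process
#'
#' Per bin a latent bivariate standard normal pair with correlation `rho` is
#' drawn; `y_t = mu_t + sigma z_y` and `x_t = 1` iff `z_x > -eta_t`.
#' Histories start at zero and a burn-in of `10 p` bins per trial is
#' discarded so trial starts are near-stationary. From `onset_bin` onward the
#' post-onset model (if any) takes over — the mechanism for onset-locked
#' coupling changes.
#'
#' @param cfg a [sim_config()].
#' @return A binary-mode [trialset()] with `t = 0` at `onset_bin`.
#' @export
simulate_mixed <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  m <- cfg$model
  .check_stable(m, "pre-onset")
  if (!is.null(cfg$post_onset_model)) .check_stable(cfg$post_onset_model, "post-onset")
  p <- m$p
  burn <- 10L * p
  total <- burn + cfg$n_bins
  nt <- cfg$n_trials
  set.seed(cfg$seed)
  Y <- matrix(0, nt, total + p)     # p leading zero-history columns
  X <- matrix(0L, nt, total + p)
  for (t in seq_len(total)) {
    col <- t + p
    mm <- if (!is.null(cfg$post_onset_model) && (t - burn) >= cfg$onset_bin)
      cfg$post_onset_model else m
    hy <- Y[, col - seq_len(p), drop = FALSE]
    hx <- X[, col - seq_len(p), drop = FALSE]
    mu <- mm$c_y + drop(hy %*% mm$a) + drop(hx %*% mm$b)
    eta <- mm$c_x + drop(hx %*% mm$d) + drop(hy %*% mm$e)
    zy <- stats::rnorm(nt)
    zx <- mm$rho * zy + sqrt(1 - mm$rho^2) * stats::rnorm(nt)
    Y[, col] <- mu + mm$sigma * zy
    X[, col] <- as.integer(zx > -eta)
  }
  keep <- (p + burn + 1L):(p + total)
  t_ms <- (seq_len(cfg$n_bins) - cfg$onset_bin) * 1000 / cfg$fs
  ts <- trialset(Y[, keep, drop = FALSE], X[, keep, drop = FALSE], t = t_ms,
                 fs = cfg$fs, condition = cfg$condition, mode = "binary")
  if (!is.null(cfg$contamination)) {
    ts <- inject_spike_artifacts(ts, cfg$contamination$template,
                                 cfg$contamination$gain)
  }
  ts
}

# causal convolution of each trial's spike train with a short template:
# out[t] = sum_j template[j] * spikes[t - j + 1]
.conv_spikes <- function(spikes, template) {
  nb <- ncol(spikes)
  out <- matrix(0, nrow(spikes), nb)
  for (j in seq_along(template)) {
    if (template[j] != 0) {
      out[, j:nb] <- out[, j:nb] + template[j] * spikes[, 1:(nb - j + 1L), drop = FALSE]
    }
  }
  out
}

#' Default spike-artifact template: a 3 ms biphasic pulse at 1 kHz
#'
#' @return Numeric length-3 template (positive then negative lobe).
#' @export
default_artifact_template <- function() c(2, -1.2, 0.4)

#' Add spike-waveform leakage to the LFP channel
#'
#' `lfp' = lfp + gain * (spikes convolved with template)` per trial, with the
#' template anchored at the spike bin (lag 0). Spikes are unchanged. Linear:
#' injecting at gains g1 then g2 equals one injection at g1 + g2.
#'
#' @param ts a [trialset()].
#' @param template short finite numeric template (per-bin artifact shape).
#' @param gain scalar multiplier.
#' @return The contaminated `trialset`.
#' @export
inject_spike_artifacts <- function(ts, template = default_artifact_template(),
                                   gain = 1) {
  if (!all(is.finite(template))) stop("template must be finite")
  if (gain == 0) return(ts)
  ts$lfp <- ts$lfp + gain * .conv_spikes(ts$spikes, template)
  ts
}

#' Generate a matched "1-bar" / "7-bar" condition pair
#'
#' Two trial sets identical in every generator parameter except the
#' post-onset cross-coupling magnitude in the chosen direction: the
#' post-onset `b` (spike history to LFP; or `e` for `"lfp_to_spike"`) is
#' replaced by `coupling * shape`. Seeds are `seed` and `seed + 1`; labels
#' are `"1-bar"` (weak, the noise stimulus) and `"7-bar"` (strong, the
#' contour pattern).
#'
#' @param base_cfg a [sim_config()]; its `post_onset_model` (or `model`) is
#'   the template whose cross-coupling is replaced.
#' @param coupling_weak,coupling_strong coupling magnitudes for the two
#'   conditions.
#' @param which direction whose coupling is varied.
#' @param shape length-`p` unit pattern multiplied by the coupling value;
#'   default puts all coupling at lag 1.
#' @return List with elements `"1-bar"` and `"7-bar"`, each a [trialset()].
#' @export
make_condition_pair <- function(base_cfg, coupling_weak, coupling_strong,
                                which = c("spike_to_lfp", "lfp_to_spike"),
                                shape = NULL) {
  which <- match.arg(which)
  stopifnot(inherits(base_cfg, "sim_config"))
  p <- base_cfg$model$p
  if (is.null(shape)) shape <- c(1, numeric(p - 1L))
  if (length(shape) != p) stop("shape must have length p")
  one <- function(coupling, label, seed) {
    post <- if (is.null(base_cfg$post_onset_model)) base_cfg$model
            else base_cfg$post_onset_model
    if (which == "spike_to_lfp") post$b <- coupling * shape else post$e <- coupling * shape
    cfg <- base_cfg
    cfg$post_onset_model <- post
    cfg$condition <- label
    cfg$seed <- as.integer(seed)
    simulate_mixed(cfg)
  }
  list("1-bar" = one(coupling_weak, "1-bar", base_cfg$seed),
       "7-bar" = one(coupling_strong, "7-bar", base_cfg$seed + 1L))
}
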