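#' Raw wideband trace and spike-time list constructors
#'
#' @param samples finite numeric vector (arbitrary units, e.g. uV).
#' @param fs sampling rate in Hz.
#' @param channel_id opaque channel label.
#' @return A `raw_trace` object.
#' @export
raw_trace <- function(samples, fs, channel_id = "ch0") {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be > 0")
  samples <- as.numeric(samples)
  if (!length(samples)) stop("samples must have length >= 1")
  if (!all(is.finite(samples))) stop("samples must be finite")
  structure(list(samples = samples, fs = fs, channel_id = channel_id),
            class = "raw_trace")
}

#' @param times nondecreasing spike times in seconds, all `>= 0`.
#' @param unit_id opaque unit label (from spike sorting, accepted as given).
#' @rdname raw_trace
#' @export
spike_times <- function(times, unit_id = "u0") {
  times <- as.numeric(times)
  if (length(times) && any(times < 0)) stop("spike times must be >= 0")
  if (is.unsorted(times)) stop("spike times must be nondecreasing")
  structure(list(times = times, unit_id = unit_id), class = "spike_times")
}

# ---- Butterworth low-pass design (bilinear transform) -----------------------
# No signal-processing package ships with the target environment, so the
# standard design is implemented here and validated in tests against the
# filter's analytic frequency response.

.poly_from_roots <- function(r) {
  co <- 1 + 0i
  for (x in r) co <- c(co, 0) - x * c(0, co)
  co
}

#' Design a digital Butterworth low-pass filter
#'
#' Analog Butterworth prototype, frequency pre-warped and mapped by the
#' bilinear transform; DC gain exactly 1.
#'
#' @param cutoff_hz -3 dB cutoff in Hz, must lie below `fs/2`.
#' @param fs sampling rate in Hz.
#' @param order filter order (default 4, standard for LFP separation).
#' @return List with numerator `b` and denominator `a` coefficients
#'   (descending powers of z, `a[1] = 1`).
#' @export
butter_lowpass <- function(cutoff_hz, fs, order = 4L) {
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    stop("cutoff must lie in (0, fs/2)")
  }
  n <- as.integer(order)
  k <- seq_len(n)
  sp <- exp(1i * pi * (2 * k + n - 1) / (2 * n))      # prototype poles, LHP
  warped <- 2 * fs * tan(pi * cutoff_hz / fs)          # pre-warped analog cutoff
  pa <- warped * sp
  pz <- (1 + pa / (2 * fs)) / (1 - pa / (2 * fs))      # bilinear map
  a <- Re(.poly_from_roots(pz))
  gain <- Re(prod(1 - pz)) / 2^n                        # H(z=1) = 1
  b <- gain * choose(n, 0:n)                            # zeros at z = -1
  list(b = b, a = a, order = n, cutoff_hz = cutoff_hz, fs = fs)
}

# steady-state filter state for a unit-step input (scipy-style lfilter_zi),
# so that constant signals pass through filtfilt exactly
.lfilter_zi <- function(b, a) {
  n <- length(a)
  if (n == 1L) return(numeric(0))
  if (n == 2L) {
    A <- matrix(-a[2], 1, 1)
  } else {
    A <- rbind(-a[-1], cbind(diag(n - 2), 0))
  }
  B <- b[-1] - b[1] * a[-1]
  solve(diag(n - 1) - t(A), B)
}

# direct form II transposed with initial state
.df2t <- function(b, a, x, zi) {
  nf <- length(b)
  z <- zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (nf > 2L) for (j in 1:(nf - 2L)) z[j] <- b[j + 1] * xi + z[j + 1] - a[j + 1] * yi
    z[nf - 1L] <- b[nf] * xi - a[nf] * yi
    y[i] <- yi
  }
  y
}

#' Zero-phase (forward-backward) IIR filtering
#'
#' Applies the filter forward then backward with odd-reflection edge padding
#' and steady-state initial conditions, so the net filter has zero group
#' delay and squared magnitude response; event times stay aligned.
#'
#' @param filt a filter from [butter_lowpass()].
#' @param x numeric signal.
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt_iir <- function(filt, x) {
  b <- filt$b
  a <- filt$a
  n <- length(x)
  pad <- min(n - 1L, 15L * (length(a) - 1L))
  if (pad > 0L) {
    xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  } else {
    xp <- x
  }
  zi <- .lfilter_zi(b, a)
  y <- .df2t(b, a, xp, zi * xp[1])
  y <- rev(.df2t(b, a, rev(y), zi * y[length(y)]))
  if (pad > 0L) y[pad + seq_len(n)] else y
}

#' Low-pass filter and downsample a raw trace
#'
#' Reproduces the LFP conditioning stage: zero-phase Butterworth low-pass
#' followed by decimation to `fs_out` (rational-factor resampling by
#' interpolation when the rate ratio is non-integer). Output length is
#' `floor(n * fs_out / fs)`.
#'
#' @param raw a [raw_trace()].
#' @param cutoff_hz low-pass cutoff in Hz; must satisfy
#'   `0 < cutoff_hz < fs_out/2 < raw$fs/2`.
#' @param fs_out output sampling rate in Hz (e.g. 1000).
#' @return A `raw_trace` at `fs_out`.
#' @export
lowpass_downsample <- function(raw, cutoff_hz, fs_out) {
  if (!inherits(raw, "raw_trace")) stop("raw must be a raw_trace")
  if (fs_out > raw$fs) stop("fs_out exceeds the input sampling rate")
  if (fs_out >= raw$fs) stop("fs_out must be strictly below the input rate")
  if (cutoff_hz <= 0 || cutoff_hz >= fs_out / 2) {
    stop("cutoff must lie below the output Nyquist frequency fs_out/2")
  }
  filt <- butter_lowpass(cutoff_hz, raw$fs)
  xf <- filtfilt_iir(filt, raw$samples)
  m <- floor(length(xf) * fs_out / raw$fs)
  r <- raw$fs / fs_out
  if (abs(r - round(r)) < 1e-9) {
    y <- xf[seq.int(1L, by = round(r), length.out = m)]
  } else {
    tin <- (seq_along(xf) - 1) / raw$fs
    tout <- (seq_len(m) - 1) / fs_out
    y <- stats::approx(tin, xf, xout = tout)$y
  }
  raw_trace(y, fs_out, raw$channel_id)
}

#' Bin spike times at a target rate
#'
#' Bin `b` (0-based) covers the half-open interval
#' `[t_start_s + b/fs_out, t_start_s + (b+1)/fs_out)`. In binary mode a bin
#' holding more than one spike is clipped to 1 with a warning; count mode
#' conserves events.
#'
#' @param spk a [spike_times()].
#' @param fs_out bin rate in Hz.
#' @param t_start_s,t_end_s range in seconds, `t_end_s > t_start_s`.
#' @param mode `"binary"` (default, appropriate at 1 kHz) or `"count"`.
#' @return Integer vector of length `round((t_end_s - t_start_s) * fs_out)`.
#' @export
binarize_spikes <- function(spk, fs_out, t_start_s, t_end_s,
                            mode = c("binary", "count")) {
  mode <- match.arg(mode)
  if (fs_out <= 0) stop("fs_out must be > 0")
  if (t_end_s <= t_start_s) stop("t_end_s must exceed t_start_s")
  nb <- round((t_end_s - t_start_s) * fs_out)
  tt <- spk$times
  keep <- tt >= t_start_s & tt < t_end_s
  idx <- floor((tt[keep] - t_start_s) * fs_out + 1e-9) + 1L
  idx <- idx[idx >= 1L & idx <= nb]
  counts <- tabulate(idx, nbins = nb)
  if (mode == "binary" && any(counts > 1L)) {
    warning(sprintf("binary mode: clipped %d multi-spike bin(s) to 1",
                    sum(counts > 1L)))
    counts <- pmin(counts, 1L)
  }
  as.integer(counts)
}

#' Cut a continuous trace and spike list into stimulus-aligned trials
#'
#' @param lfp_trace a [raw_trace()] already at the analysis rate.
#' @param spk a [spike_times()].
#' @param onsets_s stimulus onset times in seconds.
#' @param window_ms `c(pre, post)` with `pre < 0 <= post`; each trial covers
#'   `[onset + pre, onset + post)` ms, so time 0 is stimulus onset.
#' @param condition condition label attached to the result.
#' @param mode spike binning mode, see [binarize_spikes()].
#' @return A [trialset()] with `length(onsets_s)` trials. A window exceeding
#'   the trace bounds is an error naming the offending onset (1-based);
#'   trials are never silently dropped.
#' @export
align_trials <- function(lfp_trace, spk, onsets_s, window_ms = c(-300, 800),
                         condition = "unlabeled", mode = c("binary", "count")) {
  mode <- match.arg(mode)
  pre <- window_ms[1]
  post <- window_ms[2]
  if (!(pre < 0 && post >= 0)) stop("window must satisfy pre < 0 <= post")
  fs <- lfp_trace$fs
  n_pre <- round(-pre * fs / 1000)
  n_post <- round(post * fs / 1000)
  nb <- n_pre + n_post
  nt <- length(onsets_s)
  if (!nt) stop("need at least one onset")
  lfp <- matrix(0, nt, nb)
  spikes <- matrix(0L, nt, nb)
  nsamp <- length(lfp_trace$samples)
  for (i in seq_len(nt)) {
    s0 <- round(onsets_s[i] * fs)            # 0-based sample at onset
    from <- s0 - n_pre + 1L
    to <- s0 + n_post
    if (from < 1L || to > nsamp) {
      stop(sprintf("trial window out of trace bounds for onset %d (t = %g s)",
                   i, onsets_s[i]))
    }
    lfp[i, ] <- lfp_trace$samples[from:to]
    spikes[i, ] <- binarize_spikes(spk, fs, onsets_s[i] + pre / 1000,
                                   onsets_s[i] + post / 1000, mode)
  }
  t <- (seq_len(nb) - 1L - n_pre) * 1000 / fs
  trialset(lfp, spikes, t = t, fs = fs, condition = condition, mode = mode)
}
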