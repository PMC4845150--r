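#' Trial-aligned mixed spike/LFP container
#'
#' A `trialset` holds one continuous channel (LFP) and one discrete channel
#' (binned spikes) for a set of trials aligned to stimulus onset: two
#' `n_trials x n_bins` matrices sharing a uniform time axis in milliseconds
#' (0 = stimulus onset) at sampling rate `fs`.
#'
#' @param lfp numeric matrix, `n_trials x n_bins`.
#' @param spikes nonnegative integer matrix, same shape; in `"binary"` mode
#'   entries must be 0/1 (the default at 1 kHz bins, where multi-spike bins
#'   are physiologically near-impossible).
#' @param t time axis in ms relative to stimulus onset; defaults to
#'   `0, 1000/fs, ...`. Must be uniform with step `1000/fs`.
#' @param fs sampling rate in Hz.
#' @param condition condition label, e.g. `"1-bar"` or `"7-bar"`.
#' @param mode `"binary"` or `"count"`.
#' @return An object of class `trialset`.
#' @export
trialset <- function(lfp, spikes, t = NULL, fs, condition = "unlabeled",
                     mode = c("binary", "count")) {
  mode <- match.arg(mode)
  lfp <- as.matrix(lfp)
  spikes <- as.matrix(spikes)
  if (!all(dim(lfp) == dim(spikes))) {
    stop(sprintf("lfp and spikes shapes differ: %dx%d vs %dx%d",
                 nrow(lfp), ncol(lfp), nrow(spikes), ncol(spikes)))
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  if (!all(is.finite(lfp))) stop("lfp must be finite")
  nb <- ncol(lfp)
  if (is.null(t)) t <- (seq_len(nb) - 1) * 1000 / fs
  if (length(t) != nb) {
    stop(sprintf("time axis length %d does not match %d bins", length(t), nb))
  }
  if (nb > 1L) {
    dt <- diff(t)
    if (any(abs(dt - 1000 / fs) > 1e-6 * 1000 / fs)) {
      stop("time axis must be strictly increasing with uniform step 1000/fs ms")
    }
  }
  if (any(spikes < 0)) stop("spike counts must be nonnegative")
  if (any(spikes != round(spikes))) stop("spike counts must be integers")
  if (mode == "binary" && any(spikes > 1)) {
    stop("binary mode requires spikes in {0,1}")
  }
  storage.mode(spikes) <- "integer"
  structure(list(lfp = unname(lfp), spikes = unname(spikes), t = as.numeric(t),
                 fs = fs, condition = as.character(condition), mode = mode,
                 n_trials = nrow(lfp)),
            class = "trialset")
}

#' @export
print.trialset <- function(x, ...) {
  cat(sprintf("<trialset> %d trials x %d bins @ %g Hz, condition '%s', %s spikes\n",
              x$n_trials, ncol(x$lfp), x$fs, x$condition, x$mode))
  cat(sprintf("  t: [%g, %g] ms, spike rate %.4f/bin\n",
              x$t[1], x$t[length(x$t)], mean(x$spikes)))
  invisible(x)
}

#' @export
dim.trialset <- function(x) dim(x$lfp)

#' Subset a trialset by time-bin index or by trial index
#'
#' @param ts a `trialset`.
#' @param from,to first and last bin (1-based, inclusive).
#' @return A `trialset` restricted to the requested bins/trials.
#' @export
ts_window_bins <- function(ts, from, to) {
  nb <- ncol(ts$lfp)
  if (from < 1L || to > nb || from > to) stop("bin window out of range")
  trialset(ts$lfp[, from:to, drop = FALSE], ts$spikes[, from:to, drop = FALSE],
           t = ts$t[from:to], fs = ts$fs, condition = ts$condition, mode = ts$mode)
}

#' @param idx trial indices (may repeat, as in bootstrap resampling).
#' @rdname ts_window_bins
#' @export
ts_subset_trials <- function(ts, idx) {
  trialset(ts$lfp[idx, , drop = FALSE], ts$spikes[idx, , drop = FALSE],
           t = ts$t, fs = ts$fs, condition = ts$condition, mode = ts$mode)
}

#' Restrict a trialset to a time window in ms
#'
#' Keeps bins with `from_ms <= t < to_ms` (half-open, matching the bin
#' convention).
#' @inheritParams ts_window_bins
#' @param from_ms,to_ms window bounds in ms relative to stimulus onset.
#' @export
ts_window <- function(ts, from_ms, to_ms) {
  keep <- which(ts$t >= from_ms & ts$t < to_ms)
  if (!length(keep)) stop("time window contains no bins")
  ts_window_bins(ts, min(keep), max(keep))
}

.fmt <- function(x) sprintf("%.17g", x)

#' Read and write trial sets
#'
#' The delimited format is plain text: header lines `#fs=`, `#condition=`,
#' `#t0_ms=`, `#mode=`, `#t_ms=` (the explicit time axis, comma-separated),
#' then a block `LFP` (tab-separated floats, one row per trial), a separator
#' line `==`, and a block `SPIKES` (integers, same shape). The `rds` format
#' is R's portable binary array container.
#'
#' @param ts a `trialset`.
#' @param path file path.
#' @param format `"delimited"` (plain text) or `"rds"`.
#' @return `write_trialset` returns `path` invisibly; `read_trialset` returns
#'   a `trialset`. Write then read is the identity up to floating-point
#'   round-trip (the text format stores full double precision).
#' @export
write_trialset <- function(ts, path, format = c("delimited", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(ts, path)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#fs=%s", .fmt(ts$fs)),
               sprintf("#condition=%s", ts$condition),
               sprintf("#t0_ms=%s", .fmt(ts$t[1])),
               sprintf("#mode=%s", ts$mode),
               sprintf("#t_ms=%s", paste(.fmt(ts$t), collapse = ",")),
               "LFP"), con)
  utils::write.table(matrix(.fmt(ts$lfp), nrow(ts$lfp)), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines("==", con)
  writeLines("SPIKES", con)
  utils::write.table(ts$spikes, con, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trialset
#' @export
read_trialset <- function(path, format = c("delimited", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    ts <- readRDS(path)
    if (!inherits(ts, "trialset")) stop("rds file does not hold a trialset")
    return(ts)
  }
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getf <- function(key, default = NULL) {
    m <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (!length(m)) return(default)
    sub(paste0("^#", key, "="), "", m[1])
  }
  fs <- as.numeric(getf("fs"))
  if (!length(fs) || is.na(fs)) stop("missing or malformed #fs header")
  condition <- getf("condition", "unlabeled")
  mode <- getf("mode", "binary")
  t0 <- as.numeric(getf("t0_ms", "0"))
  t_ms <- getf("t_ms")
  body <- lines[!grepl("^#", lines)]
  i_lfp <- match("LFP", body)
  i_sep <- match("==", body)
  i_spk <- match("SPIKES", body)
  if (is.na(i_lfp) || is.na(i_sep) || is.na(i_spk)) {
    stop("malformed trialset file: need LFP block, '==' separator, SPIKES block")
  }
  parse_block <- function(rows) {
    rows <- rows[nzchar(rows)]
    do.call(rbind, lapply(strsplit(rows, "\t", fixed = TRUE), as.numeric))
  }
  lfp <- parse_block(body[(i_lfp + 1):(i_sep - 1)])
  spikes <- parse_block(body[(i_spk + 1):length(body)])
  t <- if (!is.null(t_ms)) as.numeric(strsplit(t_ms, ",", fixed = TRUE)[[1]])
       else t0 + (seq_len(ncol(lfp)) - 1) * 1000 / fs
  trialset(lfp, spikes, t = t, fs = fs, condition = condition, mode = mode)
}
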