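#' Downsample an ECG to the 8 Hz symbol rate
#'
#' Output sample `j` (0-based) is the mean of all input samples whose time
#' falls in the half-open 125 ms window `[j/8, (j+1)/8)`. Only complete
#' windows are emitted, so a 10 s record yields exactly 80 values. Window
#' averaging is the simplest anti-aliasing consistent with treating each
#' symbol as a 125 ms section of signal; because 500/8 is not an integer the
#' windows alternate between 62 and 63 samples.
#'
#' @param x an `ecg_record` or a numeric amplitude vector.
#' @param fs sampling rate in Hz (taken from the record when `x` is one).
#' @param rate output rate in Hz (default 8).
#' @return Numeric vector of window means.
#' @export
#' @examples
#' downsample_to_8hz(rep(1, 5000), fs = 500)[1:5]
downsample_to_8hz <- function(x, fs = NULL, rate = 8) {
  if (inherits(x, "ecg_record")) {
    fs <- x$fs
    x <- x$samples
  }
  if (is.null(fs)) stop_("fs is required when x is a plain numeric vector")
  if (fs < rate) stop_("cannot downsample: fs = %g Hz is below the %g Hz symbol rate", fs, rate)
  if (!all(is.finite(x))) stop_("samples must be finite")
  n <- length(x)
  # window index of each sample; a window is complete iff its right edge
  # lies within the record
  win <- floor((seq_len(n) - 1) / fs * rate)
  n_out <- floor(n / fs * rate)
  keep <- win < n_out
  if (n_out < 1) stop_("record too short for one %g ms window", 1000 / rate)
  means <- rowsum(x[keep], win[keep]) / tabulate(win[keep] + 1L, n_out)
  as.numeric(means)
}

#' Detect R peaks
#'
#' Fixed, fully documented detection recipe: band-pass 5-20 Hz (order-2
#' Butterworth, zero-phase), squared first difference, 150 ms moving-average
#' envelope, adaptive threshold at 0.4 times a rolling 95th envelope
#' percentile (1 s chunks, linearly interpolated), candidate per
#' supra-threshold run at the envelope maximum, local-maximum refinement on
#' the raw signal within +/-50 ms, and a 250 ms refractory rule keeping the
#' larger-envelope peak. The threshold is signal-relative, so amplitude
#' scaling does not change detected peak times.
#'
#' @param record an `ecg_record` (duration must be at least 2 s).
#' @return An object of class `rpeak_series` with `indices` (1-based sample
#'   positions) and `times` (seconds); successive times are at least 0.25 s
#'   apart.
#' @export
#' @examples
#' spec <- cohort_spec()
#' rec <- synthesize_ecg(make_subject_params(spec, "control", 1), spec)
#' detect_r_peaks(rec)
detect_r_peaks <- function(record) {
  x <- record$samples
  fs <- record$fs
  if (length(x) / fs < 2) stop_("record shorter than 2 s; R peak detection undefined")
  if (fs <= 45) stop_("sampling rate too low for the 5-20 Hz band-pass stage")

  bf <- signal::butter(2, c(5, 20) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x)
  e <- c(diff(xf), 0)^2

  # centered 150 ms moving average with edge truncation
  k <- max(1L, round(0.15 * fs))
  cs <- cumsum(c(0, e))
  n <- length(e)
  half <- k %/% 2
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  env <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)

  # rolling 95th percentile: per-second chunk quantiles, interpolated
  chunk <- pmin(floor((seq_len(n) - 1) / fs) + 1L, ceiling(n / fs))
  q95 <- tapply(env, chunk, stats::quantile, probs = 0.95, names = FALSE)
  centers <- (as.numeric(names(q95)) - 0.5) * fs
  thr_curve <- if (length(q95) > 1) {
    stats::approx(centers, as.numeric(q95), xout = seq_len(n), rule = 2)$y
  } else rep(as.numeric(q95), n)
  thr <- 0.4 * thr_curve

  above <- env > thr
  if (!any(above)) stop_("insufficient beats: no supra-threshold activity")
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- integer(0)
  for (r in which(runs$values)) {
    seg <- starts[r]:ends[r]
    cand <- c(cand, seg[which.max(env[seg])])
  }

  # refine on the raw signal within +/- 50 ms
  w <- max(1L, round(0.05 * fs))
  cand <- vapply(cand, function(i) {
    seg <- max(1L, i - w):min(n, i + w)
    seg[which.max(x[seg])]
  }, integer(1))

  # refractory: greedily keep larger-envelope peaks at >= 250 ms spacing
  ord <- cand[order(env[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(i - kept) >= 0.25 * fs)) kept <- c(kept, i)
  }
  kept <- sort(unique(kept))
  if (length(kept) < 2) stop_("insufficient beats: fewer than 2 R peaks found")

  structure(list(indices = kept, times = (kept - 1) / fs),
            class = "rpeak_series")
}

#' @export
print.rpeak_series <- function(x, ...) {
  cat(sprintf("R peak series: %d peaks over %.2f s (mean RR %.3f s)\n",
              length(x$times), diff(range(x$times)), mean(diff(x$times))))
  invisible(x)
}

#' Write / read an R peak series as CSV
#'
#' @param peaks an `rpeak_series`.
#' @param path file path.
#' @return `write_rpeaks_csv` returns `path` invisibly; `read_rpeaks_csv`
#'   returns an `rpeak_series`.
#' @export
write_rpeaks_csv <- function(peaks, path) {
  utils::write.csv(data.frame(index = peaks$indices, time_s = peaks$times),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rpeaks_csv
#' @export
read_rpeaks_csv <- function(path) {
  dat <- utils::read.csv(path)
  structure(list(indices = dat$index, times = dat$time_s), class = "rpeak_series")
}
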