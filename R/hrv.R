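#' Instantaneous heart rate from an R peak series
#'
#' Element `i` is `60 / (times[i+1] - times[i])` in beats per minute; the
#' series has one element fewer than there are peaks.
#'
#' @param peaks an `rpeak_series` (or anything with a `times` field), or a
#'   numeric vector of peak times in seconds.
#' @return Numeric vector of instantaneous HR values (bpm).
#' @export
#' @examples
#' instantaneous_hr(c(0, 1, 2, 3))
instantaneous_hr <- function(peaks) {
  times <- if (is.numeric(peaks)) peaks else peaks$times
  if (length(times) < 2) stop_("insufficient beats: need at least 2 R peaks")
  60 / diff(times)
}

#' The nine heart-rate characteristics
#'
#' Computes mean, median, standard deviation (the SDNN analogue on the HR
#' scale, sample SD with n-1 denominator), kurtosis, skewness, minimum,
#' maximum, range and coefficient of variation (percent) of an instantaneous
#' HR series. Moment conventions are fixed: skewness is the adjusted
#' Fisher-Pearson standardized third moment; kurtosis is the plain
#' (non-excess) standardized fourth moment, for which a normal distribution
#' gives 3. For a constant series the SD-based moments are undefined and
#' returned as `NA`.
#'
#' @param hr numeric HR series (bpm), length at least 2.
#' @return Named numeric vector with elements `mean`, `median`, `sd`,
#'   `kurtosis`, `skewness`, `minimum`, `maximum`, `range`, `cv`.
#' @export
#' @examples
#' hr_characteristics(c(58, 60, 62))
hr_characteristics <- function(hr) {
  n <- length(hr)
  if (n < 2) stop_("need at least 2 HR values")
  if (any(!is.finite(hr)) || any(hr <= 0)) stop_("HR values must be finite and positive")
  m <- mean(hr)
  s <- stats::sd(hr)
  m2 <- mean((hr - m)^2)
  kurt <- if (s > 0) mean((hr - m)^4) / m2^2 else NA_real_
  skew <- if (s > 0 && n > 2) {
    g1 <- mean((hr - m)^3) / m2^1.5
    g1 * sqrt(n * (n - 1)) / (n - 2)
  } else if (s == 0) NA_real_ else NA_real_
  c(mean = m, median = stats::median(hr), sd = s,
    kurtosis = kurt, skewness = skew,
    minimum = min(hr), maximum = max(hr), range = max(hr) - min(hr),
    cv = 100 * s / m)
}

#' Names of the nine HR characteristics
#' @export
hr_feature_names <- c("mean", "median", "sd", "kurtosis", "skewness",
                      "minimum", "maximum", "range", "cv")
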