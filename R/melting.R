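#' @include AllGenerics.R
NULL

#' Group reduction of a data series
#'
#' Replaces consecutive non-overlapping blocks of `window` points by
#' their (mean x, mean y); a trailing partial block is averaged as-is.
#' This is the classic smoothing used to de-noise melting curves before
#' differentiation.
#'
#' @param x,y numeric vectors of equal length (or a two-column
#'   data.frame as `x`).
#' @param window block size, >= 1.
#' @return data.frame with columns `x`, `y` of length
#'   `ceiling(length(x) / window)`.
#' @examples
#' groupReduce(1:100, rnorm(100))  # 10 points with window 10
#' @export
groupReduce <- function(x, y = NULL, window = 10L) {
  if (is.null(y)) {
    d <- as.data.frame(x)
    x <- as.numeric(d[[1L]]); y <- as.numeric(d[[2L]])
  }
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("'window' must be >= 1")
  if (length(x) != length(y)) stop("lengths differ")
  if (length(x) < window) stop("series shorter than one window")
  blk <- (seq_along(x) - 1L) %/% window
  data.frame(x = as.numeric(tapply(x, blk, mean)),
             y = as.numeric(tapply(y, blk, mean)))
}

#' Normalize a melting signal to percent change
#'
#' Linear rescale between the pre- and post-transition baseline levels
#' (means of the first and last 10% of points) to the 0-100% scale;
#' works for either sign of the raw signal change.
#'
#' @param temp temperatures (degrees Celsius), strictly increasing; or a
#'   two-column data.frame.
#' @param signal raw signal (e.g. ellipticity at 210 nm).
#' @return data.frame with columns `temp_C`, `pct`.
#' @export
percentChange <- function(temp, signal = NULL) {
  if (is.null(signal)) {
    d <- as.data.frame(temp)
    temp <- as.numeric(d[[1L]]); signal <- as.numeric(d[[2L]])
  }
  if (length(temp) != length(signal)) stop("lengths differ")
  n <- length(temp)
  if (n < 20L) stop("a melting curve needs at least 20 samples")
  if (any(diff(temp) <= 0)) stop("temperature must be strictly increasing")
  if (sd(signal) == 0) stop("constant signal: no transition to normalize")
  k <- max(2L, floor(0.1 * n))
  base0 <- mean(signal[seq_len(k)])
  base1 <- mean(signal[(n - k + 1L):n])
  if (isTRUE(all.equal(base0, base1)))
    stop("baseline levels are equal: cannot normalize")
  data.frame(temp_C = temp, pct = 100 * (signal - base0) / (base1 - base0))
}

#' Melting temperature by the first-derivative-maximum method
#'
#' Pipeline: percent-change normalization, group reduction (default
#' window 10), central-difference first derivative, and 3-point parabolic
#' interpolation of the derivative maximum. A curve whose maximum
#' derivative does not clearly exceed the mean slope of a straight line
#' over the same range is reported as "no transition".
#'
#' @param curve data.frame with columns `temp_C` and `signal` (or any
#'   temperature/signal pair in the first two columns).
#' @param window group-reduction window.
#' @return A [TmResult-class] object.
#' @export
meltingTemperature <- function(curve, window = 10L) {
  d <- as.data.frame(curve)
  tcol <- if ("temp_C" %in% names(d)) "temp_C" else names(d)[1L]
  scol <- if ("signal" %in% names(d)) "signal" else names(d)[2L]
  pc <- percentChange(d[[tcol]], d[[scol]])
  red <- groupReduce(pc$temp_C, pc$pct, window = window)
  m <- nrow(red)
  if (m < 5L) stop("too few points after group reduction; lower 'window'")
  dydt <- c(NA_real_,
            (red$y[3:m] - red$y[1:(m - 2)]) / (red$x[3:m] - red$x[1:(m - 2)]),
            NA_real_)
  deriv <- data.frame(temp = red$x, dydt = dydt)
  inner <- 2:(m - 1L)
  i <- inner[which.max(abs(dydt[inner]))]
  # a pure linear drift has |dy/dt| == 100 / range everywhere
  line_slope <- 100 / (max(red$x) - min(red$x))
  if (!is.finite(dydt[i]) || abs(dydt[i]) < 2 * line_slope) {
    return(new("TmResult", tm = NA_real_, derivative = deriv,
               window = as.integer(window), transition = FALSE))
  }
  # parabolic refinement of the maximum (quadratic through 3 points)
  idx <- (i - 1L):(i + 1L)
  xx <- red$x[idx]; yy <- abs(dydt[idx])
  fit <- lm(yy ~ poly(xx, 2, raw = TRUE))
  b <- coef(fit)
  tm <- if (is.na(b[3]) || b[3] >= 0) red$x[i] else -b[2] / (2 * b[3])
  if (tm < min(red$x) || tm > max(red$x)) tm <- red$x[i]
  new("TmResult", tm = unname(tm), derivative = deriv,
      window = as.integer(window), transition = TRUE)
}

#' Read a melting-curve CSV
#'
#' @param path CSV with columns `temp_C`, `signal`.
#' @return data.frame.
#' @export
readMeltCsv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("temp_C", "signal") %in% names(d)))
    stop("melt CSV must have columns 'temp_C' and 'signal'")
  d
}
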