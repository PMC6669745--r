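#' @include AllGenerics.R
NULL

.moving_average <- function(y, k = 5L) {
  if (length(y) < k) return(y)
  sm <- as.numeric(stats::filter(y, rep(1 / k, k), sides = 2L))
  half <- k %/% 2L
  n <- length(y)
  for (i in seq_len(half)) {
    sm[i] <- mean(y[seq_len(i + half)])
    sm[n - i + 1L] <- mean(y[(n - i + 1L - half):n])
  }
  sm
}

#' Lag time and maximum lysis velocity of a hemolysis trace
#'
#' The trace is lightly smoothed (5-point moving average); the maximum
#' turbidity descent rate defines the maximum velocity of hemolysis, and
#' the intersection of the tangent at that point with the initial
#' baseline level defines the lag time. vmax is normalized by the total
#' turbidity drop (fraction lysed per second), which makes it invariant
#' to absorbance offset and gain.
#'
#' @param trace data.frame with columns `time_s` and `a700` (or any
#'   time/absorbance pair in the first two columns).
#' @param minDrop minimum relative turbidity drop (fraction of the
#'   initial level) below which the trace is declared non-lysing.
#' @param smoothWindow moving-average window (points).
#' @return A [KineticsResult-class] object; non-lysing traces return
#'   `lysed = FALSE` with `NA` lag.
#' @export
analyzeTrace <- function(trace, minDrop = 0.05, smoothWindow = 5L) {
  d <- as.data.frame(trace)
  tcol <- if ("time_s" %in% names(d)) "time_s" else names(d)[1L]
  acol <- if ("a700" %in% names(d)) "a700" else names(d)[2L]
  t <- as.numeric(d[[tcol]]); a <- as.numeric(d[[acol]])
  if (length(t) < 10L) stop("a trace needs at least 10 samples")
  if (any(diff(t) <= 0)) stop("time must be strictly increasing")
  sm <- .moving_average(a, smoothWindow)
  k0 <- max(3L, ceiling(0.05 * length(t)))
  # the pre-lysis baseline is the highest smoothed level: robust also for
  # traces already descending at t = 0
  a_init <- max(sm)
  a_fin <- median(sm[(length(sm) - k0 + 1L):length(sm)])
  amplitude <- a_init - a_fin
  if (!is.finite(amplitude) || amplitude < minDrop * abs(a_init) ||
      amplitude <= 0) {
    return(new("KineticsResult", lagTime = NA_real_, vmax = NA_real_,
               lysed = FALSE,
               diagnostics = list(a_init = a_init, a_fin = a_fin,
                                  amplitude = amplitude)))
  }
  # smoothing the derivative as well keeps read noise from inflating the
  # maximum-slope pick
  slope <- .moving_average(-diff(sm) / diff(t), smoothWindow)
  tmid <- (t[-1L] + t[-length(t)]) / 2
  amid <- (sm[-1L] + sm[-length(sm)]) / 2
  i <- which.max(slope)
  s <- slope[i]
  lag <- max(0, tmid[i] - (a_init - amid[i]) / s)
  new("KineticsResult",
      lagTime = lag, vmax = s / amplitude, lysed = TRUE,
      diagnostics = list(a_init = a_init, a_fin = a_fin,
                         amplitude = amplitude, t_at_vmax = tmid[i],
                         raw_slope = s))
}

#' Power-law fit of lag time versus toxin concentration
#'
#' Fits lag = tau * c^-x by least squares on the log-log linearization
#' log(lag) = log(tau) - x log(c); deterministic and exact on noise-free
#' power-law data.
#'
#' @param conc concentrations (nM), all positive; alternatively a
#'   two-column data.frame (conc, lag).
#' @param lag lag times (s), all positive.
#' @return A [PowerLawFit-class] object.
#' @examples
#' fitPowerLaw(c(1, 2, 4, 8), 800 / c(1, 2, 4, 8))  # tau 800, x 1
#' @export
fitPowerLaw <- function(conc, lag = NULL) {
  if (is.null(lag)) {
    d <- as.data.frame(conc)
    conc <- as.numeric(d[[1L]]); lag <- as.numeric(d[[2L]])
  }
  if (length(conc) != length(lag)) stop("lengths differ")
  if (length(conc) < 3L) stop("at least 3 points are required")
  if (any(conc <= 0) || any(lag <= 0))
    stop("concentrations and lag times must be positive")
  fit <- lm(log(lag) ~ log(conc))
  new("PowerLawFit",
      tau = unname(exp(coef(fit)[1L])),
      exponent = unname(-coef(fit)[2L]),
      residuals = unname(stats::residuals(fit)))
}

#' Percent hemolysis from endpoint absorbances
#'
#' Hemolysis (%) = (A412 - Afin) / (Amax - Afin) x 100, where Afin and
#' Amax are the no-toxin and water-lysed controls. The value is not
#' clipped; values outside [-5, 105] trigger a warning (and attribute
#' `flagged`).
#'
#' @param a412 sample absorbance(s) at 412 nm.
#' @param aFin 0%-hemolysis control absorbance.
#' @param aMax 100%-hemolysis control absorbance.
#' @return Percent hemolysis (vectorized over `a412`).
#' @examples
#' hemolysisPercent(0.35, aFin = 0.1, aMax = 0.6)  # 50
#' @export
hemolysisPercent <- function(a412, aFin, aMax) {
  if (isTRUE(all.equal(aMax, aFin)))
    stop("degenerate controls: aMax equals aFin")
  pct <- (a412 - aFin) / (aMax - aFin) * 100
  out_of_band <- pct < -5 | pct > 105
  if (any(out_of_band)) {
    warning(sum(out_of_band), " value(s) outside [-5, 105]%")
    attr(pct, "flagged") <- out_of_band
  }
  pct
}

#' Hill dose-response fit for HC50
#'
#' Nonlinear least squares of H(c) = plateau * c^n / (hc50^n + c^n).
#' The plateau is fixed at 100% by default (hemolysis is normalized to
#' controls) and can be freed. Initial values: hc50 at the concentration
#' whose response is nearest 50%, n = 1.
#'
#' @param conc concentrations (nM); alternatively a two-column data.frame.
#' @param response percent hemolysis.
#' @param plateau fixed plateau (percent) when `freePlateau = FALSE`;
#'   otherwise the starting value.
#' @param freePlateau estimate the plateau as a third parameter.
#' @return A [HillFit-class] object; if the data never cross 50% the fit
#'   is flagged `extrapolated` with a warning.
#' @export
fitHill <- function(conc, response = NULL, plateau = 100,
                    freePlateau = FALSE) {
  if (is.null(response)) {
    d <- as.data.frame(conc)
    conc <- as.numeric(d[[1L]]); response <- as.numeric(d[[2L]])
  }
  if (length(conc) != length(response)) stop("lengths differ")
  if (length(conc) < 4L) stop("at least 4 points are required")
  if (any(conc <= 0)) stop("concentrations must be positive")
  half <- plateau / 2
  extrapolated <- !(any(response < half) && any(response > half))
  if (extrapolated)
    warning("responses never cross 50%; HC50 is extrapolated")
  h0 <- conc[which.min(abs(response - half))]
  d <- data.frame(c = conc, y = response)
  if (freePlateau) {
    fit <- minpack.lm::nlsLM(
      y ~ P * c^n / (h^n + c^n), data = d,
      start = list(h = h0, n = 1, P = plateau),
      lower = c(1e-12, 1e-6, 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- coef(fit)
    return(new("HillFit", hc50 = unname(cf["h"]), hillN = unname(cf["n"]),
               plateau = unname(cf["P"]), extrapolated = extrapolated))
  }
  fit <- minpack.lm::nlsLM(
    y ~ plateau * c^n / (h^n + c^n), data = d,
    start = list(h = h0, n = 1), lower = c(1e-12, 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  new("HillFit", hc50 = unname(cf["h"]), hillN = unname(cf["n"]),
      plateau = plateau, extrapolated = extrapolated)
}

#' Read a hemolysis trace CSV
#'
#' @param path CSV with columns `time_s`, `a700` (optionally `conc_nM`).
#' @return data.frame.
#' @export
readTraceCsv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "a700") %in% names(d)))
    stop("trace CSV must have columns 'time_s' and 'a700'")
  d
}
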