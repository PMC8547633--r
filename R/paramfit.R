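#' Fit an exponential distribution by log-survival regression
#'
#' Evaluates the empirical survivor function S(t) = fraction of samples
#' strictly greater than t at the observed values, drops the terminal
#' S = 0 point, and fits a least-squares line to log S(t) against t. The
#' absolute slope is the exponential rate; its inverse is the scale
#' (mean). This mirrors the survival-curve fits used to obtain the
#' refractory periods and mimetic coefficients from latency samples.
#'
#' @param samples numeric vector of nonnegative latencies (>= 5 values).
#' @return List of class \code{"expFit"}: \code{rate} (per minute),
#'   \code{scale} (minutes, = 1/rate), \code{rSquared} of the log-survival
#'   regression, \code{nSamples}.
#' @export
#' @examples
#' set.seed(1)
#' fitExponentialSurvival(rexp(200, rate = 1 / 25))$scale  # about 25
fitExponentialSurvival <- function(samples) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 5L) stop("need at least 5 samples")
  if (any(samples < 0)) stop("latency samples must be >= 0")
  t <- sort(unique(samples))
  n <- length(samples)
  s <- vapply(t, function(v) sum(samples > v), numeric(1)) / n
  keep <- s > 0
  if (sum(keep) < 2L)
    stop("degenerate sample: survivor function has fewer than 2 positive points")
  fit <- stats::lm(log(s[keep]) ~ t[keep])
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop("degenerate sample: log-survival slope is not negative")
  structure(list(rate = abs(slope), scale = 1 / abs(slope),
                 rSquared = summary(fit)$r.squared, nSamples = n),
            class = "expFit")
}

#' Estimate refractory periods from phase-start latencies
#'
#' Splits the latency samples by destination state and fits each class with
#' \code{\link{fitExponentialSurvival}}; the fitted scale is the refractory
#' period Delta-T01 for that state (minutes). A state with no samples is
#' reported as NA.
#'
#' @param samples data.frame from \code{\link{phaseStartLatencies}}
#'   (columns \code{destination}, \code{value}).
#' @return List with elements \code{resting} and \code{moving}, each either
#'   an \code{expFit} or NA, plus \code{t01R}/\code{t01M} shortcuts
#'   (minutes).
#' @export
estimateRefractory <- function(samples) {
  fitState <- function(state) {
    v <- samples$value[samples$destination == state]
    if (length(v) < 5L) return(NA)
    tryCatch(fitExponentialSurvival(v), error = function(e) NA)
  }
  r <- fitState("resting"); m <- fitState("moving")
  list(resting = r, moving = m,
       t01R = if (is.list(r)) r$scale else NA_real_,
       t01M = if (is.list(m)) m$scale else NA_real_)
}

#' Estimate mimetic coefficients from joiner latencies
#'
#' The mimetic coefficient C is the rate of the exponential fitted to the
#' latencies between consecutive joiners (C = 1 / mean joiner gap), per
#' destination state.
#'
#' @param samples data.frame from \code{\link{joinerLatencies}} (columns
#'   \code{destination}, \code{value}).
#' @return List with \code{resting}/\code{moving} fits and \code{cR} /
#'   \code{cM} shortcuts (per minute).
#' @export
estimateMimeticCoefficient <- function(samples) {
  fitState <- function(state) {
    v <- samples$value[samples$destination == state]
    if (length(v) < 5L) return(NA)
    tryCatch(fitExponentialSurvival(v), error = function(e) NA)
  }
  r <- fitState("resting"); m <- fitState("moving")
  list(resting = r, moving = m,
       cR = if (is.list(r)) r$rate else NA_real_,
       cM = if (is.list(m)) m$rate else NA_real_)
}

#' Individual baseline rate from the herd-level rate
#'
#' The herd-level probability per minute that some individual starts state
#' s is Psi1_s = N * lambda_s, so the individual baseline rate is
#' lambda_s = Psi1_s / N.
#'
#' @param psi1 herd-level per-minute probability (> 0).
#' @param n herd size (>= 1).
#' @return lambda, per minute.
#' @export
#' @examples
#' lambdaFromPsi(0.04, 123)  # 0.00033 (2 s.f.)
lambdaFromPsi <- function(psi1, n) {
  if (!is.numeric(psi1) || any(psi1 <= 0)) stop("psi1 must be > 0")
  if (!is.numeric(n) || any(n < 1)) stop("n must be >= 1")
  psi1 / n
}

#' Quadratic fit through the origin
#'
#' Least-squares fit of the two-parameter family a x^2 + b x (no
#' intercept), the curve used to describe how many individuals change
#' state as a synchronization phase unfolds.
#'
#' @param deltaN data.frame from \code{\link{deltaN}}, or any data.frame
#'   with columns \code{window} and \code{count}.
#' @param window window length in minutes (x = window end time, minutes
#'   from phase start).
#' @return List of class \code{"quadFit"}: \code{a}, \code{b},
#'   \code{rSquared}, \code{nPoints}.
#' @export
#' @examples
#' pts <- data.frame(window = 1:4, count = (1:4 * 30)^2)
#' fitQuadraticOrigin(pts, window = 30)  # a = 1, b = 0
fitQuadraticOrigin <- function(deltaN, window = 30) {
  stopifnot(all(c("window", "count") %in% names(deltaN)))
  x <- deltaN$window * window
  y <- deltaN$count
  if (length(x) < 3L) stop("need at least 3 points for the quadratic fit")
  fit <- stats::lm(y ~ 0 + I(x^2) + x)
  co <- stats::coef(fit)
  ssRes <- sum(stats::resid(fit)^2)
  ssTot <- sum((y - mean(y))^2)
  structure(list(a = unname(co[["I(x^2)"]]), b = unname(co[["x"]]),
                 rSquared = if (ssTot > 0) 1 - ssRes / ssTot else NA_real_,
                 nPoints = length(x)),
            class = "quadFit")
}

#' Re-estimate model parameters from an observed state record
#'
#' Convenience wrapper chaining phase detection, latency extraction and the
#' survival fits: refractory periods from phase-start latencies, mimetic
#' coefficients from joiner latencies, baseline rates from
#' lambda_s = Psi1_s / N with Psi1_s = 1 / Delta-T01_s. Falls back to the
#' corresponding value of \code{defaults} whenever a sample class is too
#' small to fit.
#'
#' @param sm a \linkS4class{StateMatrix}.
#' @param nAgents herd size N.
#' @param defaults a \linkS4class{ModelParams} supplying values that cannot
#'   be estimated from \code{sm}.
#' @return A \linkS4class{ModelParams}.
#' @export
estimateParamsFromStates <- function(sm, nAgents = ncol(stateMatrix(sm)),
                                     defaults = modelParams()) {
  phases <- detectPhases(sm)
  refr <- estimateRefractory(phaseStartLatencies(sm, phases))
  mim <- estimateMimeticCoefficient(joinerLatencies(sm, phases))
  t01R <- if (is.na(refr$t01R)) defaults@t01R else refr$t01R
  t01M <- if (is.na(refr$t01M)) defaults@t01M else refr$t01M
  modelParams(
    lambdaR = lambdaFromPsi(1 / t01R, nAgents),
    lambdaM = lambdaFromPsi(1 / t01M, nAgents),
    cR = if (is.na(mim$cR)) defaults@cR else mim$cR,
    cM = if (is.na(mim$cM)) defaults@cM else mim$cM,
    t01R = t01R, t01M = t01M, nAgents = nAgents,
    initRestingFraction = defaults@initRestingFraction, dt = defaults@dt
  )
}
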