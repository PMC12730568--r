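#' Time-periodic coefficient functions
#'
#' Every coefficient of the eco-epidemic model is a positive, continuous,
#' bounded, omega-periodic function of time.  Three forms are supported:
#' a constant, a sinusoid mean + amplitude*sin(w*t + phase), and a tabulated
#' profile interpolated linearly and extended periodically.
#'
#' @param mean mean (constant value for the constant form).
#' @param amplitude sinusoid amplitude.
#' @param angularFrequency sinusoid angular frequency w, radians per unit time.
#' @param phase sinusoid phase, radians.
#' @param period the function's own period.  For the sinusoid form it defaults
#'   to \code{2*pi/angularFrequency}; any explicit period must be commensurate
#'   with the angular frequency (\code{w * period} an integer multiple of
#'   \code{2*pi}, tolerance 1e-9).
#' @return an object of class \code{periodicFn}.
#' @examples
#' r1 <- periodicSinusoid(10, 1, pi)
#' evalPeriodic(r1, 0.5)        # 11
#' extremaPeriodic(r1)          # c(9, 11)
#' @name periodicFn
NULL

newPeriodicFn <- function(form, period, ...) {
  structure(c(list(form = form, period = period), list(...)),
            class = "periodicFn")
}

#' @rdname periodicFn
#' @export
periodicConstant <- function(mean) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean))
  newPeriodicFn("constant", period = Inf, mean = mean)
}

#' @rdname periodicFn
#' @export
periodicSinusoid <- function(mean, amplitude, angularFrequency, phase = 0,
                             period = NULL) {
  stopifnot(is.finite(mean), is.finite(amplitude),
            is.finite(angularFrequency), angularFrequency > 0,
            is.finite(phase))
  if (is.null(period)) period <- 2 * pi / angularFrequency
  stopifnot(is.finite(period), period > 0)
  # commensurability: w * period must be a whole number of turns
  turns <- angularFrequency * period / (2 * pi)
  if (abs(turns - round(turns)) > 1e-9)
    stop("sinusoid angular frequency is not commensurate with the period ",
         "(angularFrequency * period must be a multiple of 2*pi)")
  newPeriodicFn("sinusoid", period = period, mean = mean,
                amplitude = amplitude, angularFrequency = angularFrequency,
                phase = phase)
}

#' @rdname periodicFn
#' @param times,values ordered sample times/values over one period
#'   (\code{times[1]} is reused at \code{times[1] + period}).
#' @export
periodicTabulated <- function(times, values, period) {
  stopifnot(length(times) == length(values), length(times) >= 2L,
            all(is.finite(times)), all(is.finite(values)),
            is.finite(period), period > 0,
            !is.unsorted(times, strictly = TRUE),
            times[length(times)] - times[1] < period + 1e-12)
  newPeriodicFn("tabulated", period = period,
                times = as.numeric(times), values = as.numeric(values))
}

#' Evaluate a periodic coefficient
#'
#' @param spec a \code{periodicFn}.
#' @param t time (vectorised).
#' @return numeric vector of values, one per element of \code{t}.
#' @export
evalPeriodic <- function(spec, t) {
  stopifnot(inherits(spec, "periodicFn"))
  switch(spec$form,
    constant = rep_len(spec$mean, length(t)),
    sinusoid = spec$mean +
      spec$amplitude * sin(spec$angularFrequency * t + spec$phase),
    tabulated = {
      tt <- spec$times - spec$times[1]
      tp <- (t - spec$times[1]) %% spec$period
      # close the period: value at period wraps to the first sample
      xs <- c(tt, spec$period)
      ys <- c(spec$values, spec$values[1])
      stats::approx(xs, ys, xout = tp, rule = 2)$y
    },
    stop("unknown periodic form: ", spec$form))
}

#' Infimum and supremum of a periodic coefficient over one period
#'
#' Closed form for constants and sinusoids (mean +/- |amplitude|); for
#' tabulated profiles a dense scan at 10^4 points with local three-point
#' quadratic refinement.
#'
#' @param spec a \code{periodicFn}.
#' @return named numeric \code{c(inf = , sup = )}.
#' @export
extremaPeriodic <- function(spec) {
  stopifnot(inherits(spec, "periodicFn"))
  if (spec$form == "constant")
    return(c(inf = spec$mean, sup = spec$mean))
  if (spec$form == "sinusoid")
    return(c(inf = spec$mean - abs(spec$amplitude),
             sup = spec$mean + abs(spec$amplitude)))
  numericExtrema(spec)
}

# dense sampling + quadratic refinement; also serves as the numeric oracle
# for the closed forms in tests
numericExtrema <- function(spec, n = 1e4) {
  p <- if (is.finite(spec$period)) spec$period else 1
  t <- seq(0, p, length.out = n + 1L)
  v <- evalPeriodic(spec, t)
  refine <- function(idx) {
    # three-point quadratic through the local extremum and its neighbours
    if (idx <= 1L || idx >= length(v)) return(v[idx])
    y0 <- v[idx - 1L]; y1 <- v[idx]; y2 <- v[idx + 1L]
    den <- y0 - 2 * y1 + y2
    if (abs(den) < .Machine$double.eps) return(y1)
    y1 - (y0 - y2)^2 / (8 * den)
  }
  c(inf = refine(which.min(v)), sup = refine(which.max(v)))
}

#' @export
print.periodicFn <- function(x, ...) {
  desc <- switch(x$form,
    constant = sprintf("constant %g", x$mean),
    sinusoid = sprintf("%g %+g*sin(%g*t %+g)", x$mean, x$amplitude,
                       x$angularFrequency, x$phase),
    tabulated = sprintf("tabulated (%d samples, period %g)",
                        length(x$times), x$period))
  cat("<periodicFn>", desc, "\n")
  invisible(x)
}

# Exact sum/difference where the closed form stays in the family
# (same frequency and phase, or one side constant); otherwise a tabulated
# profile sampled over the common period.
combinePeriodic <- function(a, b, op = c("+", "-"), nSamples = 2048L) {
  op <- match.arg(op)
  f <- if (op == "+") `+` else `-`
  if (a$form == "constant" && b$form == "constant")
    return(periodicConstant(f(a$mean, b$mean)))
  if (a$form == "sinusoid" && b$form == "constant")
    return(periodicSinusoid(f(a$mean, b$mean), a$amplitude,
                            a$angularFrequency, a$phase, a$period))
  if (a$form == "constant" && b$form == "sinusoid")
    return(periodicSinusoid(f(a$mean, b$mean),
                            f(0, b$amplitude), b$angularFrequency,
                            b$phase, b$period))
  if (a$form == "sinusoid" && b$form == "sinusoid" &&
      isTRUE(all.equal(a$angularFrequency, b$angularFrequency)) &&
      isTRUE(all.equal(a$phase, b$phase)))
    return(periodicSinusoid(f(a$mean, b$mean), f(a$amplitude, b$amplitude),
                            a$angularFrequency, a$phase, a$period))
  p <- commonPeriod(a$period, b$period)
  t <- seq(0, p, length.out = nSamples + 1L)[-(nSamples + 1L)]
  periodicTabulated(t, f(evalPeriodic(a, t), evalPeriodic(b, t)), p)
}

commonPeriod <- function(pa, pb) {
  if (!is.finite(pa)) return(pb)
  if (!is.finite(pb)) return(pa)
  # smallest common multiple up to a modest factor; fall back to the larger
  for (k in 1:64) {
    m <- k * max(pa, pb)
    if (abs(m / pa - round(m / pa)) < 1e-9 &&
        abs(m / pb - round(m / pb)) < 1e-9) return(m)
  }
  stop("periods are not commensurate")
}

periodOf <- function(spec) spec$period
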