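# reaction coefficients of the simplified model, in fixed order
reactionCoefNames <- c("r1", "b", "beta", "delta", "c", "psi",
                       "alpha", "a", "e", "gamma", "r2", "d")
diffusivityNames <- c("D1", "D2", "D3")
extensionNames <- c("alphaS", "gammaS")

#' Eco-epidemic model with periodic coefficients
#'
#' The simplified susceptible-prey / infected-prey / predator system:
#' \deqn{X_S' = X_S [ r_1 - b (X_S + X_I) - \beta X_I ]}
#' \deqn{X_I' = X_I [ -\delta - c X_I + \psi X_S - \alpha Y / (1 + a X_I + e Y) ]}
#' \deqn{Y'   = Y [ -r_2 - d Y + \gamma X_I / (1 + a X_I + e Y) ]}
#' with diffusivities \code{D1..D3} for the spatial version and common period
#' \code{omega}.  The optional extension adds weak Beddington-DeAngelis
#' predation on the susceptible prey: \code{-alphaS*Y/(1 + a*XS + e*Y)} on the
#' susceptible equation and \code{+gammaS*XS/(1 + a*XS + e*Y)} on the predator
#' equation (same interference coefficients \code{a}, \code{e}).
#'
#' Construction checks that every coefficient's own period divides
#' \code{omega}, that evaluation on a 10^4-point grid of \code{[0, omega]} is
#' finite, and records (as warnings listed in \code{$warnings}, not errors)
#' any coefficient that dips non-positive on that grid -- the worked
#' interference coefficient \code{a(t)} does.
#'
#' @param r1,b,beta,delta,c,psi,alpha,a,e,gamma,r2,d reaction coefficients,
#'   each a \code{periodicFn} or a single number (promoted to a constant).
#' @param D1,D2,D3 diffusivities, same convention.
#' @param omega common period of the forcing.
#' @param alphaS,gammaS optional extension coefficients (both or neither).
#' @return object of class \code{ecoEpidemicModel}.
#' @export
ecoEpidemicModel <- function(r1, b, beta, delta, c, psi, alpha, a, e, gamma,
                             r2, d, D1 = 1, D2 = 1, D3 = 1, omega,
                             alphaS = NULL, gammaS = NULL) {
  stopifnot(is.numeric(omega), length(omega) == 1L, is.finite(omega),
            omega > 0)
  coefs <- list(r1 = r1, b = b, beta = beta, delta = delta, c = c, psi = psi,
                alpha = alpha, a = a, e = e, gamma = gamma, r2 = r2, d = d,
                D1 = D1, D2 = D2, D3 = D3)
  coefs <- lapply(coefs, asPeriodicFn)
  hasExtension <- !is.null(alphaS) || !is.null(gammaS)
  if (hasExtension) {
    if (is.null(alphaS) || is.null(gammaS))
      stop("extension requires both alphaS and gammaS")
    coefs$alphaS <- asPeriodicFn(alphaS)
    coefs$gammaS <- asPeriodicFn(gammaS)
  }
  for (nm in names(coefs)) {
    p <- periodOf(coefs[[nm]])
    if (is.finite(p)) {
      ratio <- omega / p
      if (abs(ratio - round(ratio)) > 1e-9)
        stop("coefficient '", nm, "' has period ", p,
             " which does not divide omega = ", omega)
    }
  }
  grid <- seq(0, omega, length.out = 1e4)
  warnings <- character()
  for (nm in names(coefs)) {
    v <- evalPeriodic(coefs[[nm]], grid)
    if (!all(is.finite(v)))
      stop("coefficient '", nm, "' is not finite on [0, omega]")
    if (any(v <= 0))
      warnings <- c(warnings, sprintf(
        "coefficient '%s' dips non-positive on [0, omega] (min %.6g)",
        nm, min(v)))
  }
  m <- structure(list(coefs = coefs, omega = omega,
                      hasExtension = hasExtension, warnings = warnings),
                 class = "ecoEpidemicModel")
  m$fast <- makeFastEvaluator(m)
  m
}

asPeriodicFn <- function(x) {
  if (inherits(x, "periodicFn")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(periodicConstant(x))
  stop("coefficient must be a periodicFn or a single number")
}

# When every coefficient is constant or sinusoidal the whole coefficient
# vector at time t is mean + amp * sin(w t + phase) in one vectorised sweep;
# the PDE stepper leans on this.
makeFastEvaluator <- function(model) {
  cf <- model$coefs
  if (!all(vapply(cf, function(f) f$form %in% c("constant", "sinusoid"),
                  logical(1))))
    return(NULL)
  get <- function(f, field, default)
    if (f$form == "sinusoid") f[[field]] else default
  list(mean = vapply(cf, `[[`, numeric(1), "mean"),
       amp  = vapply(cf, get, numeric(1), "amplitude", 0),
       w    = vapply(cf, get, numeric(1), "angularFrequency", 0),
       ph   = vapply(cf, get, numeric(1), "phase", 0))
}

#' Evaluate all model coefficients at one time
#'
#' @param model an \code{ecoEpidemicModel}.
#' @param t a single time.
#' @return named numeric vector over the model's coefficients (reaction
#'   coefficients, diffusivities, extension coefficients when present).
#' @export
modelCoefs <- function(model, t) {
  stopifnot(inherits(model, "ecoEpidemicModel"), length(t) == 1L)
  if (!is.null(model$fast)) {
    f <- model$fast
    v <- f$mean + f$amp * sin(f$w * t + f$ph)
    names(v) <- names(model$coefs)
    return(v)
  }
  vapply(model$coefs, evalPeriodic, numeric(1), t = t)
}

#' Raw (unsimplified) model parameters
#'
#' The raw formulation carries the infected-prey intraspecific competition
#' split into a cross term \code{epsilon(t)} (competition with the whole prey
#' population) and a self term \code{cStar(t)}, and the raw transmission rate
#' \code{beta(t)}.  \code{simplifyRaw} folds these into the simplified model's
#' \code{c = epsilon + cStar} and \code{psi = beta - epsilon}.
#'
#' @param r1,b,beta,delta,epsilon,cStar,alpha,a,e,gamma,r2,d,D1,D2,D3
#'   coefficients (\code{periodicFn} or numbers).
#' @param omega common period.
#' @return object of class \code{rawModelParameters}.
#' @export
rawModelParameters <- function(r1, b, beta, delta, epsilon, cStar, alpha, a,
                               e, gamma, r2, d, D1 = 1, D2 = 1, D3 = 1,
                               omega) {
  coefs <- lapply(list(r1 = r1, b = b, beta = beta, delta = delta,
                       epsilon = epsilon, cStar = cStar, alpha = alpha,
                       a = a, e = e, gamma = gamma, r2 = r2, d = d,
                       D1 = D1, D2 = D2, D3 = D3), asPeriodicFn)
  structure(list(coefs = coefs, omega = omega),
            class = "rawModelParameters")
}

#' Reduce raw parameters to the simplified model
#'
#' Sets \code{c = epsilon + cStar} and \code{psi = beta - epsilon} (exact
#' in-family combinations where both operands share a sinusoidal form, else a
#' tabulated profile) and copies the remaining coefficients.  Rejects
#' parameter sets whose \code{psi} would be non-positive anywhere on a dense
#' grid of one period, since positivity of the effective transmission rate
#' underlies every persistence argument.
#'
#' @param raw a \code{rawModelParameters}.
#' @return an \code{ecoEpidemicModel}.
#' @export
simplifyRaw <- function(raw) {
  stopifnot(inherits(raw, "rawModelParameters"))
  cf <- raw$coefs
  cc <- combinePeriodic(cf$epsilon, cf$cStar, "+")
  psi <- combinePeriodic(cf$beta, cf$epsilon, "-")
  grid <- seq(0, raw$omega, length.out = 1e4)
  if (any(evalPeriodic(psi, grid) <= 0))
    stop("psi = beta - epsilon is non-positive on [0, omega]; ",
         "the simplified model requires epsilon < beta pointwise")
  ecoEpidemicModel(r1 = cf$r1, b = cf$b, beta = cf$beta, delta = cf$delta,
                   c = cc, psi = psi, alpha = cf$alpha, a = cf$a, e = cf$e,
                   gamma = cf$gamma, r2 = cf$r2, d = cf$d,
                   D1 = cf$D1, D2 = cf$D2, D3 = cf$D3, omega = raw$omega)
}

#' Beddington-DeAngelis functional response
#'
#' Predation pressure \code{alpha*pred / (1 + a*prey + e*pred)} per unit prey.
#' Returns exactly 0 when \code{pred == 0}.  A non-positive denominator
#' (possible when the interference coefficient \code{a(t)} dips negative, as
#' in the worked coefficient set) raises a condition of class
#' \code{ecoepiDegenerateDenominator} carrying the offending time and state.
#'
#' @param alphaVal,aVal,eVal coefficient values at the evaluation time.
#' @param prey,pred densities entering the response.
#' @param t,state optional context attached to the error.
#' @return the response value (vectorised over densities).
#' @export
bdResponse <- function(alphaVal, aVal, eVal, prey, pred, t = NA,
                       state = NULL) {
  den <- 1 + aVal * prey + eVal * pred
  if (any(den <= 0))
    stop(degenerateDenominatorError(t, state, min(den)))
  out <- alphaVal * pred / den
  out[pred == 0] <- 0
  out
}

degenerateDenominatorError <- function(t, state, den) {
  structure(class = c("ecoepiDegenerateDenominator", "error", "condition"),
            list(message = sprintf(
                   "Beddington-DeAngelis denominator %.6g <= 0 at t = %s",
                   den, format(t)),
                 call = sys.call(-1), t = t, state = state))
}

#' Per-capita growth rates
#'
#' The bracketed terms of the simplified system: \code{Delta1} for
#' susceptible prey, \code{Delta2} for infected prey, \code{Delta3} for the
#' predator, evaluated at state \code{s = c(XS, XI, Y)} and time \code{t}.
#' The signs of these brackets drive positivity: a component's derivative is
#' the component times its bracket.
#'
#' @param model an \code{ecoEpidemicModel}.
#' @param s state vector \code{c(XS, XI, Y)}.
#' @param t time.
#' @return named numeric \code{c(Delta1, Delta2, Delta3)}.
#' @export
perCapitaRates <- function(model, s, t) {
  v <- modelCoefs(model, t)
  r <- perCapitaRatesVec(model, v, s[1], s[2], s[3], t)
  c(Delta1 = r[[1]], Delta2 = r[[2]], Delta3 = r[[3]])
}

# vectorised core: XS, XI, Y may be node vectors; v is the coefficient vector
# at time t.  Used by both the scalar API and the PDE stepper.
perCapitaRatesVec <- function(model, v, XS, XI, Y, t) {
  denI <- 1 + v[["a"]] * XI + v[["e"]] * Y
  if (any(denI <= 0)) stop(degenerateDenominatorError(t, c(XS, XI, Y)[1:3],
                                                      min(denI)))
  d1 <- v[["r1"]] - v[["b"]] * (XS + XI) - v[["beta"]] * XI
  d2 <- -v[["delta"]] - v[["c"]] * XI + v[["psi"]] * XS -
    v[["alpha"]] * Y / denI
  d3 <- -v[["r2"]] - v[["d"]] * Y + v[["gamma"]] * XI / denI
  if (model$hasExtension) {
    denS <- 1 + v[["a"]] * XS + v[["e"]] * Y
    if (any(denS <= 0)) stop(degenerateDenominatorError(t, NULL, min(denS)))
    d1 <- d1 - v[["alphaS"]] * Y / denS
    d3 <- d3 + v[["gammaS"]] * XS / denS
  }
  list(d1, d2, d3)
}

#' Right-hand side of the reduced (non-spatial) system
#'
#' Componentwise \code{state * perCapitaRates}; exact zeros are preserved
#' (extinct components stay extinct -- the coordinate faces are invariant).
#'
#' @inheritParams perCapitaRates
#' @return named numeric \code{c(dXS, dXI, dY)}.
#' @export
odeRhs <- function(model, s, t) {
  r <- perCapitaRates(model, s, t)
  out <- unname(s[1:3]) * unname(r)
  out[s[1:3] == 0] <- 0
  c(dXS = out[1], dXI = out[2], dY = out[3])
}

#' @export
print.ecoEpidemicModel <- function(x, ...) {
  cat("<ecoEpidemicModel> period omega =", x$omega,
      if (x$hasExtension) "(with susceptible-predation extension)" else "",
      "\n")
  for (nm in names(x$coefs)) {
    cat(sprintf("  %-7s ", nm)); print(x$coefs[[nm]])
  }
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
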