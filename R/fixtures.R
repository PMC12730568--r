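sinpi2 <- function(mean, amplitude)
  periodicSinusoid(mean, amplitude, angularFrequency = pi, phase = 0,
                   period = 2)

example1Coefs <- function(psi = sinpi2(1.5, 0.1), c = sinpi2(10.46, 0.11)) {
  list(r1 = sinpi2(10, 1), b = sinpi2(4.4, 0.1), beta = sinpi2(1.5, 0.1),
       delta = sinpi2(2, 0.01), c = c, psi = psi, alpha = sinpi2(0.5, 0.01),
       a = sinpi2(0.007, 0.01), e = sinpi2(0.04, 0.01),
       gamma = sinpi2(3.65, 0.02), r2 = sinpi2(0.08, 0.01),
       d = sinpi2(3.85, 0.01), D1 = 1, D2 = 1, D3 = 1, omega = 2)
}

#' Worked coefficient sets
#'
#' \code{example1()} is the two-periodic worked model: all coefficients of
#' the form mean + amplitude*sin(pi*t), diffusivities 1, domain (0, 2*pi),
#' spatially constant initial data (2.5, 0.1, 0.085).  Its conversion
#' coefficient is the reconciled \code{psi = 1.5 + 0.1 sin(pi*t)}: every
#' derived constant of the worked example (and the matching coefficient of
#' the weak-predation variant) requires sup psi = 1.6 and inf psi = 1.4,
#' whereas the literal printed reading \code{1.49 + 0.99 sin(pi*t)}
#' reproduces none of them.  That literal reading is kept as
#' \code{example1Literal()} for transparency.
#'
#' \code{example2WeakPredation()} adds weak Beddington-DeAngelis predation on
#' the susceptible prey (\code{alphaS = 0.01 + 0.001 sin},
#' \code{gammaS = 2.65 + 0.02 sin}, sharing \code{a} and \code{e}) and uses
#' \code{c = 10.45 + 0.1 sin} as printed for that variant.
#'
#' @param N grid intervals for the bundled domain.
#' @return list with \code{$model}, \code{$grid} (L = 2*pi), \code{$initial}.
#' @export
example1 <- function(N = 128) {
  cf <- example1Coefs()
  list(model = do.call(ecoEpidemicModel, cf),
       grid = grid1d(2 * pi, N), initial = c(XS = 2.5, XI = 0.1, Y = 0.085))
}

#' @rdname example1
#' @export
example1Literal <- function(N = 128) {
  cf <- example1Coefs(psi = sinpi2(1.49, 0.99))
  list(model = do.call(ecoEpidemicModel, cf),
       grid = grid1d(2 * pi, N), initial = c(XS = 2.5, XI = 0.1, Y = 0.085))
}

#' @rdname example1
#' @export
example2WeakPredation <- function(N = 128) {
  cf <- example1Coefs(c = sinpi2(10.45, 0.1))
  cf$alphaS <- sinpi2(0.01, 0.001)
  cf$gammaS <- sinpi2(2.65, 0.02)
  list(model = do.call(ecoEpidemicModel, cf),
       grid = grid1d(2 * pi, N), initial = c(XS = 2.5, XI = 0.1, Y = 0.085))
}

#' Seeded random sinusoidal models
#'
#' Deterministically draws a two-periodic model (all coefficients
#' sinusoidal, angular frequency pi): each reaction-coefficient mean is the
#' worked value scaled log-uniformly in [2/3, 3/2], amplitudes are uniform
#' in [0, 0.2] of the mean, diffusivities are constants uniform in
#' [0.5, 2].  With a \code{target} other than "unconstrained" the draw is
#' rejection-sampled until the criteria report matches:
#' \itemize{
#'   \item \code{permanent}: (H1)--(H5) all hold (certifying bounds);
#'   \item \code{stable}: (H1)--(H8) all hold;
#'   \item \code{violating}: at least one of (H1)--(H8) fails;
#'   \item \code{unconstrained}: first draw.
#' }
#'
#' @param seed integer seed; the global RNG state is restored on exit.
#' @param target sampling target.
#' @param maxDraws rejection budget.
#' @return an \code{ecoEpidemicModel}.
#' @export
randomModel <- function(seed,
                        target = c("unconstrained", "permanent", "stable",
                                   "violating"),
                        maxDraws = 1e5) {
  target <- match.arg(target)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  base <- example1Coefs()
  draw <- function() {
    cf <- list()
    for (nm in reactionCoefNames) {
      m0 <- base[[nm]]$mean * exp(stats::runif(1, log(2 / 3), log(3 / 2)))
      cf[[nm]] <- sinpi2(m0, stats::runif(1, 0, 0.2) * m0)
    }
    for (nm in diffusivityNames) cf[[nm]] <- stats::runif(1, 0.5, 2)
    cf$omega <- 2
    do.call(ecoEpidemicModel, cf)
  }
  for (i in seq_len(maxDraws)) {
    m <- draw()
    if (target == "unconstrained") return(m)
    rep <- tryCatch(suppressMessages(criteriaReport(m)$report),
                    error = function(e) NULL)
    hit <- !is.null(rep) && switch(target,
      permanent = rep$permanent && rep$certifying,
      stable    = rep$globallyStable && rep$certifying,
      violating = any(!rep$satisfied))
    if (hit) return(m)
  }
  stop("randomModel: target '", target, "' not found within ", maxDraws,
       " draws")
}
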