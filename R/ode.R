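#' Integrate the reduced (spatially homogeneous) system
#'
#' Adaptive embedded Runge-Kutta (Dormand-Prince via
#' \code{deSolve::ode(method = "ode45")}) on the reduced three-species
#' system.  Strictly positive components are propagated in log coordinates
#' (\code{d log x / dt} = per-capita rate), which preserves positivity
#' without clipping; components whose initial value is exactly zero sit on an
#' invariant face and are frozen at zero.
#'
#' @param model an \code{ecoEpidemicModel}.
#' @param initial nonnegative state \code{c(XS, XI, Y)}.
#' @param t0,t1 integration window, \code{t1 > t0}.
#' @param relTol,absTol integrator tolerances (absTol acts on the log scale
#'   for positive components).
#' @param denseStep output sampling step.
#' @param method a \code{deSolve} method name.
#' @return object of class \code{odeTrajectory}: \code{$times},
#'   \code{$states} (rows aligned with times, columns XS, XI, Y),
#'   \code{$relTol}, \code{$absTol}.
#' @export
integrateOde <- function(model, initial, t0 = 0, t1, relTol = 1e-8,
                         absTol = 1e-10, denseStep = 0.01,
                         method = "ode45") {
  stopifnot(inherits(model, "ecoEpidemicModel"), length(initial) == 3L,
            all(is.finite(initial)), all(initial >= 0), t1 > t0)
  initial <- unname(as.numeric(initial))
  pos <- initial > 0
  times <- seq(t0, t1, by = denseStep)
  if (times[length(times)] < t1) times <- c(times, t1)
  if (!any(pos)) {
    states <- matrix(0, length(times), 3,
                     dimnames = list(NULL, c("XS", "XI", "Y")))
    return(structure(list(times = times, states = states, relTol = relTol,
                          absTol = absTol), class = "odeTrajectory"))
  }
  func <- function(t, y, parms) {
    x <- numeric(3)
    x[pos] <- exp(y)
    if (any(x > 1e12))
      stop("blow-up detected: component exceeded 1e12 at t = ", t)
    v <- modelCoefs(model, t)
    r <- perCapitaRatesVec(model, v, x[1], x[2], x[3], t)
    list(unlist(r)[pos])
  }
  # cap the internal step at a fraction of the forcing period so trial
  # steps cannot jump across the guarded response denominator
  hmax <- min(model$omega / 8, t1 - t0)
  sol <- deSolve::ode(y = log(initial[pos]), times = times, func = func,
                      parms = NULL, method = method, rtol = relTol,
                      atol = absTol, hmax = hmax, hini = min(1e-3, hmax))
  states <- matrix(0, length(times), 3,
                   dimnames = list(NULL, c("XS", "XI", "Y")))
  states[, pos] <- exp(sol[, -1, drop = FALSE])
  if (!all(is.finite(states))) stop("integration produced non-finite states")
  structure(list(times = times, states = states, relTol = relTol,
                 absTol = absTol), class = "odeTrajectory")
}

#' Poincare (period-advance) map
#'
#' The state at \code{t0 + omega} of the solution through \code{(t0, s)}.
#' Fixed points of this map are omega-periodic solutions of the reduced
#' system.
#'
#' @param model an \code{ecoEpidemicModel}.
#' @param s positive state \code{c(XS, XI, Y)}.
#' @param t0 starting phase.
#' @param relTol,absTol integrator tolerances.
#' @return the mapped state (named numeric).
#' @export
poincareMap <- function(model, s, t0 = 0, relTol = 1e-10, absTol = 1e-12) {
  stopifnot(all(s > 0))
  traj <- integrateOde(model, s, t0 = t0, t1 = t0 + model$omega,
                       relTol = relTol, absTol = absTol,
                       denseStep = model$omega)
  traj$states[nrow(traj$states), ]
}

#' Locate the positive periodic orbit
#'
#' Plain fixed-point iteration of the Poincare map (the map is a contraction
#' in the globally stable regime), declared converged when successive
#' iterates differ by less than \code{tol} in sup norm; an optional
#' finite-difference-Jacobian Newton polish is available for slowly
#' contracting cases.  The converged orbit is densely sampled over one
#' period, reported with start phase 0.
#'
#' @param model an \code{ecoEpidemicModel}.
#' @param guess positive starting state; default is the midpoint of the
#'   persistence bands when these are positive, else \code{c(1, 0.1, 0.1)}.
#' @param tol sup-norm fixed-point tolerance.
#' @param maxIter iteration budget.
#' @param nSamples samples over one period.
#' @param newtonPolish use a Newton step on \code{P(s) - s} once the plain
#'   iteration stalls.
#' @param relTol,absTol integrator tolerances.
#' @return object of class \code{periodicOrbit}: \code{$period},
#'   \code{$times}, \code{$states}, \code{$residual}, \code{$startPhase},
#'   \code{$iterations}.
#' @export
findPeriodicOrbit <- function(model, guess = NULL, tol = 1e-10,
                              maxIter = 500, nSamples = 400,
                              newtonPolish = FALSE, relTol = 1e-11,
                              absTol = 1e-13) {
  if (is.null(guess)) {
    b <- tryCatch(ultimateBounds(extremaTable(model)), error = function(e) NULL)
    guess <- if (!is.null(b) && all(unlist(b[c("m1", "m2", "m3")]) > 0))
      c((b$m1 + b$M1) / 2, (b$m2 + b$M2) / 2, (b$m3 + b$M3) / 2)
    else c(1, 0.1, 0.1)
  }
  stopifnot(all(guess > 0))
  s <- unname(as.numeric(guess))
  defect <- Inf
  for (k in seq_len(maxIter)) {
    sNew <- unname(poincareMap(model, s, relTol = relTol, absTol = absTol))
    defect <- max(abs(sNew - s))
    s <- sNew
    if (defect < tol) break
    if (newtonPolish && k > 5 && defect < 1e-3) {
      s <- newtonStep(model, s, relTol, absTol)
    }
  }
  if (defect >= tol) {
    cond <- structure(class = c("ecoepiOrbitNotConverged", "error",
                                "condition"),
                      list(message = sprintf(
                             "Poincare iteration did not converge in %d iterations (defect %.3g); expected when (H6)-(H8) fail",
                             maxIter, defect),
                           call = sys.call(-1), lastIterate = s,
                           defect = defect))
    stop(cond)
  }
  residual <- max(abs(unname(poincareMap(model, s, relTol = relTol,
                                         absTol = absTol)) - s))
  traj <- integrateOde(model, s, t0 = 0, t1 = model$omega, relTol = relTol,
                       absTol = absTol, denseStep = model$omega / nSamples)
  states <- traj$states
  states[nrow(states), ] <- states[1, ]  # close the loop for interpolation
  structure(list(period = model$omega, times = traj$times, states = states,
                 residual = residual, startPhase = 0, iterations = k),
            class = "periodicOrbit")
}

newtonStep <- function(model, s, relTol, absTol) {
  g <- function(x) unname(poincareMap(model, x, relTol = relTol,
                                      absTol = absTol)) - x
  g0 <- g(s)
  J <- matrix(0, 3, 3)
  h <- pmax(1e-7 * abs(s), 1e-9)
  for (j in 1:3) {
    sp <- s; sp[j] <- sp[j] + h[j]
    J[, j] <- (g(sp) - g0) / h[j]
  }
  step <- tryCatch(solve(J, -g0), error = function(e) rep(0, 3))
  out <- s + step
  if (all(out > 0)) out else s
}

#' Orbit state at arbitrary phases
#'
#' Periodic-spline interpolation of the sampled orbit, evaluated at
#' \code{t mod period}.
#'
#' @param orbit a \code{periodicOrbit}.
#' @param t times (vectorised).
#' @return matrix with one row per time, columns XS, XI, Y.
#' @export
orbitStates <- function(orbit, t) {
  stopifnot(inherits(orbit, "periodicOrbit"))
  ph <- (t - orbit$startPhase) %% orbit$period
  out <- vapply(1:3, function(j) {
    f <- stats::splinefun(orbit$times, orbit$states[, j],
                          method = "periodic")
    f(ph)
  }, numeric(length(ph)))
  out <- matrix(out, nrow = length(ph), ncol = 3,
                dimnames = list(NULL, c("XS", "XI", "Y")))
  out
}

#' Lyapunov function of the stability argument
#'
#' Sum of absolute log ratios between a state and the periodic reference:
#' \code{|log XS - log XS*| + |log XI - log XI*| + |log Y - log Y*|}.
#'
#' @param s,ref strictly positive states.
#' @return nonnegative scalar.
#' @export
lyapunovV <- function(s, ref) {
  s <- unname(as.numeric(s)); ref <- unname(as.numeric(ref))
  if (any(s <= 0) || any(ref <= 0))
    stop("lyapunovV requires strictly positive states")
  sum(abs(log(s) - log(ref)))
}

#' Empirical Lyapunov decay report
#'
#' Evaluates the Lyapunov function along a trajectory against the periodic
#' orbit at matched phases and checks the decay inequality
#' \code{dV/dt <= -alpha * sum_i |x_i - x_i*|}: between consecutive samples,
#' \code{V(t2) - V(t1)} must not exceed \code{-alpha} times the trapezoid
#' approximation of the integrated componentwise distance, within
#' \code{tol}.
#'
#' @param traj an \code{odeTrajectory} (same model as the orbit).
#' @param orbit a \code{periodicOrbit}.
#' @param alpha positive decay rate (from \code{hypothesisMargins}).
#' @param tol slack allowed on each decrement.
#' @return list: \code{$V} (series), \code{$times},
#'   \code{$fractionDecreasing}, \code{$decayInequalityFraction} (fraction
#'   of steps satisfying the integrated inequality), \code{$VEnd}.
#' @export
checkDecay <- function(traj, orbit, alpha, tol = 1e-6) {
  stopifnot(inherits(traj, "odeTrajectory"), inherits(orbit, "periodicOrbit"),
            alpha > 0)
  ref <- orbitStates(orbit, traj$times)
  V <- vapply(seq_along(traj$times),
              function(i) lyapunovV(traj$states[i, ], ref[i, ]),
              numeric(1))
  absDist <- rowSums(abs(traj$states - ref))
  dt <- diff(traj$times)
  integ <- dt * (absDist[-length(absDist)] + absDist[-1]) / 2
  dV <- diff(V)
  ok <- dV <= -alpha * integ + tol
  list(times = traj$times, V = V,
       fractionDecreasing = mean(dV < 0),
       decayInequalityFraction = mean(ok),
       VEnd = V[length(V)])
}

#' @export
print.periodicOrbit <- function(x, ...) {
  rng <- apply(x$states, 2, range)
  cat(sprintf("<periodicOrbit> period %g, residual %.3g (%d iterations)\n",
              x$period, x$residual, x$iterations))
  cat(sprintf("  XS in [%.4f, %.4f], XI in [%.4f, %.4f], Y in [%.4f, %.4f]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3],
              rng[2, 3]))
  invisible(x)
}

#' @export
print.odeTrajectory <- function(x, ...) {
  cat(sprintf("<odeTrajectory> %d samples on [%g, %g]\n", length(x$times),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}
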