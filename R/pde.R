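#' One-dimensional node-centred grid
#'
#' Nodes \code{x_j = j*h}, \code{j = 0..N}, \code{h = L/N}; endpoints
#' included.  The worked domain is the interval \code{(0, 2*pi)}.
#'
#' @param L domain length.
#' @param N number of intervals (>= 8).
#' @return object of class \code{grid1d} with \code{$L}, \code{$N},
#'   \code{$h}, \code{$x}.
#' @export
grid1d <- function(L, N) {
  stopifnot(L > 0, N >= 8, N == round(N))
  h <- L / N
  structure(list(L = L, N = as.integer(N), h = h, x = (0:N) * h),
            class = "grid1d")
}

#' Discrete Laplacian with zero-flux boundaries
#'
#' Standard second-order three-point Laplacian; the Neumann (zero normal
#' derivative) boundaries are realised with mirrored ghost nodes
#' \code{u[-1] = u[1]} and \code{u[N+1] = u[N-1]}, which keeps second-order
#' accuracy and makes the trapezoid-weighted sum of the discrete Laplacian
#' vanish exactly (discrete flux conservation).
#'
#' @param u values at the \code{N+1} nodes.
#' @param h grid spacing.
#' @return the discrete Laplacian at every node.
#' @export
laplacianNeumann <- function(u, h) {
  n <- length(u)
  stopifnot(n >= 3L, h > 0)
  out <- numeric(n)
  out[2:(n - 1)] <- (u[1:(n - 2)] - 2 * u[2:(n - 1)] + u[3:n]) / h^2
  out[1] <- 2 * (u[2] - u[1]) / h^2
  out[n] <- 2 * (u[n - 1] - u[n]) / h^2
  out
}

#' CFL-limited explicit time step
#'
#' \code{dt = safety * h^2 / (2 * maxD)} where \code{maxD} is the largest
#' diffusivity supremum across the three species.
#'
#' @param model an \code{ecoEpidemicModel}.
#' @param grid a \code{grid1d}.
#' @param safety safety factor in (0, 1].
#' @return the time step.
#' @export
stableTimestep <- function(model, grid, safety = 0.4) {
  stopifnot(inherits(grid, "grid1d"), safety > 0)
  maxD <- max(vapply(diffusivityNames,
                     function(nm) extremaPeriodic(model$coefs[[nm]])[["sup"]],
                     numeric(1)))
  safety * grid$h^2 / (2 * maxD)
}

# reaction + diffusion right-hand side over all nodes; fields is an
# (N+1) x 3 matrix.  Exact zeros have zero reaction (invariant faces).
pdeRhs <- function(model, fields, t, h) {
  v <- modelCoefs(model, t)
  XS <- fields[, 1]; XI <- fields[, 2]; Y <- fields[, 3]
  r <- perCapitaRatesVec(model, v, XS, XI, Y, t)
  cbind(XS * r[[1]] + v[["D1"]] * laplacianNeumann(XS, h),
        XI * r[[2]] + v[["D2"]] * laplacianNeumann(XI, h),
        Y  * r[[3]] + v[["D3"]] * laplacianNeumann(Y,  h))
}

#' Simulate the reaction-diffusion system
#'
#' Method of lines: nodewise reaction terms with time-dependent
#' coefficients, diffusion through \code{\link{laplacianNeumann}}, advanced
#' by classical four-stage Runge-Kutta at the CFL-limited step (the step is
#' shrunk so snapshot times are hit exactly).  A step whose result dips
#' below \code{-1e-12} in any node is rejected and retried with a halved
#' step, up to 10 halvings; values in \code{[-1e-12, 0)} are snapped to 0.
#'
#' @param model an \code{ecoEpidemicModel}.
#' @param grid a \code{grid1d}.
#' @param initial either a length-3 nonnegative vector (spatially constant
#'   initial data) or an \code{(N+1) x 3} matrix of nodal values.
#' @param tEnd final time.
#' @param snapshotEvery snapshot spacing.
#' @param safety CFL safety factor.
#' @return object of class \code{pdeTrajectory}: \code{$times},
#'   \code{$snapshots} (list of \code{(N+1) x 3} matrices), \code{$grid},
#'   \code{$dtHistory}, \code{$initial}.
#' @export
simulatePde <- function(model, grid, initial, tEnd, snapshotEvery = 0.05,
                        safety = 0.4) {
  stopifnot(inherits(model, "ecoEpidemicModel"), inherits(grid, "grid1d"),
            tEnd > 0, snapshotEvery > 0)
  nn <- grid$N + 1L
  if (is.matrix(initial)) {
    stopifnot(nrow(initial) == nn, ncol(initial) == 3L)
    fields <- unname(initial)
  } else {
    stopifnot(length(initial) == 3L)
    fields <- matrix(rep(as.numeric(initial), each = nn), nn, 3)
  }
  stopifnot(all(is.finite(fields)), all(fields >= 0))
  colnames(fields) <- c("XS", "XI", "Y")
  dt0 <- stableTimestep(model, grid, safety)
  snapTimes <- seq(0, tEnd, by = snapshotEvery)
  if (snapTimes[length(snapTimes)] < tEnd - 1e-12)
    snapTimes <- c(snapTimes, tEnd)
  snapshots <- vector("list", length(snapTimes))
  snapshots[[1]] <- fields
  dtHistory <- numeric(0)
  t <- 0
  for (k in 2:length(snapTimes)) {
    target <- snapTimes[k]
    nSub <- max(1L, ceiling((target - t) / dt0 - 1e-12))
    dt <- (target - t) / nSub
    i <- 0L
    while (i < nSub) {
      res <- rk4Step(model, fields, t, dt, grid$h)
      if (min(res) < -1e-12) {
        # reject: halve the step (rebalancing the remaining substeps)
        halvings <- 0L
        repeat {
          dt <- dt / 2; nSub <- 2L * nSub; i <- 2L * i
          halvings <- halvings + 1L
          res <- rk4Step(model, fields, t, dt, grid$h)
          if (min(res) >= -1e-12) break
          if (halvings >= 10L)
            stop("PDE step kept producing negative values after 10 halvings",
                 " at t = ", t)
        }
      }
      res[res < 0] <- 0  # snap tiny negatives in [-1e-12, 0)
      if (max(res) > 1e12)
        stop("blow-up detected: nodal value exceeded 1e12 at t = ", t)
      fields <- res
      t <- t + dt
      i <- i + 1L
      dtHistory <- c(dtHistory, dt)
    }
    t <- target  # kill accumulated round-off
    snapshots[[k]] <- fields
  }
  structure(list(times = snapTimes, snapshots = snapshots, grid = grid,
                 dtHistory = dtHistory, initial = snapshots[[1]]),
            class = "pdeTrajectory")
}

rk4Step <- function(model, fields, t, dt, h) {
  k1 <- pdeRhs(model, fields, t, h)
  k2 <- pdeRhs(model, fields + dt / 2 * k1, t + dt / 2, h)
  k3 <- pdeRhs(model, fields + dt / 2 * k2, t + dt / 2, h)
  k4 <- pdeRhs(model, fields + dt * k3, t + dt, h)
  fields + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Spatial spread of a field
#'
#' Nodewise max minus min per species; zero means spatial homogeneity.
#'
#' @param field an \code{(N+1) x 3} matrix (or one snapshot of a
#'   \code{pdeTrajectory}).
#' @return named numeric \code{c(XS, XI, Y)}.
#' @export
spatialSpread <- function(field) {
  stopifnot(is.matrix(field), ncol(field) == 3L)
  out <- apply(field, 2, function(u) max(u) - min(u))
  names(out) <- c("XS", "XI", "Y")
  out
}

#' Envelope check against the coupled upper/lower comparison system
#'
#' The PDE solution is bracketed componentwise between an ordered pair of
#' upper/lower solutions started from the nodewise maxima and minima of the
#' initial field.  Because the reaction terms are mixed quasimonotone (more
#' infected prey depresses susceptible prey but feeds the predator), the
#' bracketing pair is not two independent runs of the reduced system: the
#' upper susceptible-prey equation must carry the \emph{lower} infected-prey
#' density and vice versa, and the infected-prey equations carry the
#' opposite predator bound.  \code{envelopeCheck} integrates that coupled
#' six-dimensional comparison system and reports the fraction of
#' (snapshot, node, species) points with
#' \code{lower - tol <= PDE <= upper + tol}.
#'
#' @param pde a \code{pdeTrajectory}.
#' @param model the model it was simulated from.
#' @param tol comparison tolerance.
#' @param relTol,absTol integrator tolerances for the comparison system.
#' @return list: \code{$fraction}, \code{$times}, \code{$lower},
#'   \code{$upper} (matrices at the snapshot times), \code{$worstViolation}.
#' @export
envelopeCheck <- function(pde, model, tol = 1e-8, relTol = 1e-10,
                          absTol = 1e-12) {
  stopifnot(inherits(pde, "pdeTrajectory"))
  lo0 <- apply(pde$initial, 2, min)
  hi0 <- apply(pde$initial, 2, max)
  env <- envelopeSystem(model, lo0, hi0, pde$times, relTol, absTol)
  ok <- 0L; total <- 0L; worst <- 0
  for (k in seq_along(pde$times)) {
    lo <- env$lower[k, ]; hi <- env$upper[k, ]
    f <- pde$snapshots[[k]]
    below <- sweep(f, 2, lo - tol, `<`)
    above <- sweep(f, 2, hi + tol, `>`)
    bad <- below | above
    ok <- ok + sum(!bad); total <- total + length(bad)
    viol <- max(c(0, sweep(f, 2, hi, `-`)[above],
                  -sweep(f, 2, lo, `-`)[below]))
    worst <- max(worst, viol)
  }
  list(fraction = ok / total, times = pde$times, lower = env$lower,
       upper = env$upper, worstViolation = worst)
}

# coupled mixed-quasimonotone comparison system: tilde (upper) and hat
# (lower) triples, integrated in log coordinates.  Zero components are
# frozen (invariant faces); the pair stays ordered when initially ordered.
envelopeSystem <- function(model, lo0, hi0, times, relTol = 1e-10,
                           absTol = 1e-12) {
  stopifnot(all(lo0 >= 0), all(hi0 >= lo0))
  y0 <- c(hi0, lo0)                      # tilde XS,XI,Y then hat XS,XI,Y
  pos <- y0 > 0
  func <- function(t, y, parms) {
    x <- numeric(6); x[pos] <- exp(y)
    v <- modelCoefs(model, t)
    tS <- x[1]; tI <- x[2]; tY <- x[3]; hS <- x[4]; hI <- x[5]; hY <- x[6]
    denT <- 1 + v[["a"]] * tI + v[["e"]] * hY
    denT2 <- 1 + v[["a"]] * tI + v[["e"]] * tY
    denH <- 1 + v[["a"]] * hI + v[["e"]] * tY
    denH2 <- 1 + v[["a"]] * hI + v[["e"]] * hY
    if (min(denT, denT2, denH, denH2) <= 0)
      stop(degenerateDenominatorError(t, x, min(denT, denT2, denH, denH2)))
    r <- c(
      v[["r1"]] - v[["b"]] * (tS + hI) - v[["beta"]] * hI,
      -v[["delta"]] - v[["c"]] * tI + v[["psi"]] * tS -
        v[["alpha"]] * hY / denT,
      -v[["r2"]] - v[["d"]] * tY + v[["gamma"]] * tI / denT2,
      v[["r1"]] - v[["b"]] * (hS + tI) - v[["beta"]] * tI,
      -v[["delta"]] - v[["c"]] * hI + v[["psi"]] * hS -
        v[["alpha"]] * tY / denH,
      -v[["r2"]] - v[["d"]] * hY + v[["gamma"]] * hI / denH2)
    if (model$hasExtension) {
      dT <- 1 + v[["a"]] * tS + v[["e"]] * hY
      dT2 <- 1 + v[["a"]] * tS + v[["e"]] * tY
      dH <- 1 + v[["a"]] * hS + v[["e"]] * tY
      dH2 <- 1 + v[["a"]] * hS + v[["e"]] * hY
      r[1] <- r[1] - v[["alphaS"]] * hY / dT
      r[4] <- r[4] - v[["alphaS"]] * tY / dH
      r[3] <- r[3] + v[["gammaS"]] * tS / dT2
      r[6] <- r[6] + v[["gammaS"]] * hS / dH2
    }
    list(r[pos])
  }
  hmax <- min(model$omega / 8, diff(range(times)))
  sol <- deSolve::ode(y = log(y0[pos]), times = times, func = func,
                      parms = NULL, method = "ode45", rtol = relTol,
                      atol = absTol, hmax = hmax, hini = min(1e-3, hmax))
  states <- matrix(0, length(times), 6)
  states[, pos] <- exp(sol[, -1, drop = FALSE])
  list(upper = states[, 1:3, drop = FALSE],
       lower = states[, 4:6, drop = FALSE])
}

#' Estimate the oscillation period by peak spacing
#'
#' Local maxima are located by three-point comparison and refined by a
#' quadratic fit through the maximum and its neighbours; the period is the
#' mean spacing between consecutive refined peaks and the spread its
#' standard deviation.
#'
#' @param times sample times (even spacing assumed for the refinement).
#' @param values sampled scalar series.
#' @param burnIn discard samples with \code{times < burnIn}.
#' @return list \code{$period}, \code{$spread}, \code{$peaks}.
#' @export
estimatePeriod <- function(times, values, burnIn = 0) {
  keep <- times >= burnIn
  t <- times[keep]; v <- values[keep]
  n <- length(v)
  stopifnot(n >= 3L)
  idx <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  if (length(idx) < 3L)
    stop("insufficient oscillations: fewer than 3 local maxima after burn-in")
  peaks <- vapply(idx, function(i) {
    y0 <- v[i - 1]; y1 <- v[i]; y2 <- v[i + 1]
    den <- y0 - 2 * y1 + y2
    off <- if (abs(den) < .Machine$double.eps) 0 else (y0 - y2) / (2 * den)
    t[i] + off * (t[i + 1] - t[i])
  }, numeric(1))
  gaps <- diff(peaks)
  list(period = mean(gaps), spread = stats::sd(gaps), peaks = peaks)
}

#' Distance of a simulated field to the periodic orbit
#'
#' At each snapshot, the maximum over nodes of the summed componentwise
#' absolute difference between the field and the orbit at the matched phase
#' (\code{t mod omega}, orbit start phase 0).
#'
#' @param pde a \code{pdeTrajectory}.
#' @param orbit a \code{periodicOrbit} of the same model.
#' @return numeric series aligned with \code{pde$times}.
#' @export
distanceToOrbit <- function(pde, orbit) {
  stopifnot(inherits(pde, "pdeTrajectory"), inherits(orbit, "periodicOrbit"))
  ref <- orbitStates(orbit, pde$times)
  vapply(seq_along(pde$times), function(k) {
    diffs <- abs(sweep(pde$snapshots[[k]], 2, ref[k, ], `-`))
    max(rowSums(diffs))
  }, numeric(1))
}

#' Persistence-band entry time
#'
#' The earliest snapshot time after which every species at every node stays
#' inside its band \code{[m_i, M_i]} for all later snapshots, or "never"
#' with the violating extrema.
#'
#' @param traj a \code{pdeTrajectory} or \code{odeTrajectory}.
#' @param bounds a \code{persistenceBounds} with positive bands.
#' @param slack tolerance subtracted/added to the bands.
#' @return list: \code{$entryTime} (NA if never), \code{$never},
#'   \code{$violating} (per-species observed range after the last
#'   violation, when never).
#' @export
persistenceBandReport <- function(traj, bounds, slack = 0) {
  stopifnot(inherits(bounds, "persistenceBounds"))
  lo <- c(bounds$m1, bounds$m2, bounds$m3) - slack
  hi <- c(bounds$M1, bounds$M2, bounds$M3) + slack
  stopifnot(all(lo > -Inf), all(hi > 0))
  if (inherits(traj, "odeTrajectory")) {
    times <- traj$times
    inside <- vapply(seq_along(times), function(k)
      all(traj$states[k, ] >= lo & traj$states[k, ] <= hi), logical(1))
    ranges <- function() apply(traj$states, 2, range)
  } else {
    times <- traj$times
    inside <- vapply(seq_along(times), function(k) {
      f <- traj$snapshots[[k]]
      all(sweep(f, 2, lo, `>=`) & sweep(f, 2, hi, `<=`))
    }, logical(1))
    ranges <- function() apply(traj$snapshots[[length(times)]], 2, range)
  }
  if (!inside[length(inside)] || !any(inside))
    return(list(entryTime = NA_real_, never = TRUE, violating = ranges()))
  lastOut <- max(c(0L, which(!inside)))
  list(entryTime = times[lastOut + 1L], never = FALSE, violating = NULL)
}

#' @export
print.pdeTrajectory <- function(x, ...) {
  cat(sprintf("<pdeTrajectory> %d snapshots on [0, %g], N = %d nodes\n",
              length(x$times), x$times[length(x$times)], x$grid$N + 1L))
  invisible(x)
}

#' Extract a scalar series at a spatial location
#'
#' Series of one species at the node nearest \code{x}; the worked figures
#' sample at \code{x = 0.6*pi}.
#'
#' @param pde a \code{pdeTrajectory}.
#' @param species one of "XS", "XI", "Y".
#' @param x spatial location.
#' @return list \code{$times}, \code{$values}, \code{$node}.
#' @export
probeSeries <- function(pde, species = c("XI", "XS", "Y"), x = 0.6 * pi) {
  species <- match.arg(species)
  j <- which.min(abs(pde$grid$x - x))
  col <- match(species, c("XS", "XI", "Y"))
  list(times = pde$times,
       values = vapply(pde$snapshots, function(f) f[j, col], numeric(1)),
       node = j)
}
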