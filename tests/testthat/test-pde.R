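test_that("discrete Laplacian is second-order accurate with zero flux", {
  g <- grid1d(2 * pi, 256)
  expect_equal(laplacianNeumann(rep(3.2, g$N + 1), g$h),
               rep(0, g$N + 1))
  u <- cos(g$x)   # compatible: du/dx = 0 at both ends
  err <- max(abs(laplacianNeumann(u, g$h) + cos(g$x)))
  expect_lt(err, 1e-3)
  # trapezoid-weighted sum of the discrete Laplacian telescopes to zero
  set.seed(8)
  w <- c(g$h / 2, rep(g$h, g$N - 1), g$h / 2)
  for (i in 1:5) {
    v <- stats::runif(g$N + 1)
    expect_lt(abs(sum(w * laplacianNeumann(v, g$h))), 1e-10)
  }
})

test_that("CFL time step follows the h^2 law", {
  m <- constantModel()   # D = 1
  g <- grid1d(1, 10)     # h = 0.1
  expect_equal(stableTimestep(m, g, safety = 0.5), 0.0025)
  ex <- example1()
  g1 <- grid1d(2 * pi, 128)
  expect_equal(stableTimestep(ex$model, g1, safety = 0.4),
               0.4 * g1$h^2 / 2)
  expect_equal(stableTimestep(ex$model, grid1d(2 * pi, 256), 0.4),
               stableTimestep(ex$model, g1, 0.4) / 4)
})

test_that("uniform initial data reproduces the reduced dynamics", {
  ex <- example1(N = 32)
  pde <- simulatePde(ex$model, ex$grid, ex$initial, tEnd = 20,
                     snapshotEvery = 0.1)
  ode <- integrateOde(ex$model, ex$initial, 0, 20, denseStep = 0.1)
  expect_lt(odePdeRelErr(pde, ode), 1e-6)
  # diffusion of a constant is zero: fields stay spatially flat
  spreads <- vapply(pde$snapshots, function(f) max(spatialSpread(f)),
                    numeric(1))
  expect_lt(max(spreads), 1e-10)
})

test_that("zero initial data stays identically zero", {
  ex <- example1(N = 16)
  pde <- simulatePde(ex$model, ex$grid, c(0, 0, 0), tEnd = 2,
                     snapshotEvery = 0.5)
  expect_true(all(vapply(pde$snapshots, function(f) all(f == 0),
                         logical(1))))
})

test_that("perturbed fields homogenise and stay nonnegative", {
  ex <- example1(N = 32)
  init <- cosPerturbedInitial(ex$grid)
  pde <- simulatePde(ex$model, ex$grid, init, tEnd = 60,
                     snapshotEvery = 0.1)
  expect_true(all(vapply(pde$snapshots, min, numeric(1)) >= 0))
  final <- spatialSpread(pde$snapshots[[length(pde$times)]])
  expect_lt(max(final), 1e-4)
  # spread decays monotonically (within slack) after the transient
  spreads <- vapply(pde$snapshots, function(f) max(spatialSpread(f)),
                    numeric(1))
  late <- pde$times >= 5
  expect_true(all(diff(spreads[late]) < 1e-6))
  # the long-time oscillation has period 2 at the probe point
  ps <- probeSeries(pde, "XI", x = 0.6 * pi)
  est <- estimatePeriod(ps$times, ps$values, burnIn = 40)
  expect_equal(est$period, 2, tolerance = 0.01)
  expect_lt(est$spread, 0.01)
})

test_that("the coupled comparison envelope brackets the PDE solution", {
  ex <- example1(N = 32)
  # degenerate envelope: uniform data
  pdeU <- simulatePde(ex$model, ex$grid, ex$initial, tEnd = 5,
                      snapshotEvery = 0.1)
  envU <- envelopeCheck(pdeU, ex$model, tol = 1e-6)
  expect_equal(envU$fraction, 1)
  # cos-perturbed data
  pde <- simulatePde(ex$model, ex$grid, cosPerturbedInitial(ex$grid),
                     tEnd = 20, snapshotEvery = 0.1)
  env <- envelopeCheck(pde, ex$model)
  expect_equal(env$fraction, 1)
  expect_equal(env$worstViolation, 0)
  # randomised initial fields
  set.seed(21)
  for (i in 1:5) {
    init <- cbind(stats::runif(ex$grid$N + 1, 1, 3),
                  stats::runif(ex$grid$N + 1, 0.05, 0.2),
                  stats::runif(ex$grid$N + 1, 0.05, 0.15))
    p <- simulatePde(ex$model, ex$grid, init, tEnd = 10, snapshotEvery = 0.2)
    e <- envelopeCheck(p, ex$model)
    expect_equal(e$fraction, 1, label = sprintf("random field %d", i))
  }
})

test_that("period estimation recovers known sinusoids and fails gracefully", {
  t <- seq(0, 20, by = 0.01)
  est <- estimatePeriod(t, sin(pi * t))
  expect_equal(est$period, 2, tolerance = 0.01)
  est3 <- estimatePeriod(t, sin(2 * pi * t / 3))
  expect_equal(est3$period, 3, tolerance = 0.01)
  expect_error(estimatePeriod(t, sin(pi * t), burnIn = 19),
               "insufficient oscillations")
})

test_that("spatial spread is the nodewise range per species", {
  f <- cbind(c(1, 3, 2), c(5, 5, 5), c(0, 0.5, 0.1))
  expect_equal(spatialSpread(f), c(XS = 2, XI = 0, Y = 0.5))
})

test_that("persistence-band entry times are detected", {
  ex <- example1()
  b <- ultimateBounds(extremaTable(ex$model))
  tr <- integrateOde(ex$model, ex$initial, 0, 100, denseStep = 0.1)
  rep <- persistenceBandReport(tr, b)
  expect_false(rep$never)
  expect_true(is.finite(rep$entryTime))
  # initial state already inside all bands -> entry at the first sample
  expect_equal(rep$entryTime, 0)
  # impossible predator floor -> never
  bBad <- explicitBounds(extremaTable(ex$model), M1 = b$M1, M2 = b$M2,
                         M3 = b$M3, m1 = b$m1, m2 = b$m2, m3 = 10)
  repBad <- persistenceBandReport(tr, bBad)
  expect_true(repBad$never)
  expect_false(is.null(repBad$violating))
})

test_that("halving the grid spacing converges at second order", {
  ex <- example1()
  sols <- lapply(c(16, 32, 64), function(N) {
    g <- grid1d(2 * pi, N)
    simulatePde(ex$model, g, cosPerturbedInitial(g), tEnd = 1,
                snapshotEvery = 1)$snapshots[[2]]
  })
  e1 <- max(abs(sols[[1]] - sols[[2]][seq(1, 33, 2), ]))
  e2 <- max(abs(sols[[2]] - sols[[3]][seq(1, 65, 2), ]))
  order <- log2(e1 / e2)
  expect_gt(order, 1.8)
  expect_lt(order, 2.3)
})
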