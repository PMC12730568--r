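tabEx1 <- extremaTable(example1()$model)

test_that("extrema table covers every reaction coefficient", {
  expect_named(tabEx1, c("r1", "b", "beta", "delta", "c", "psi", "alpha",
                         "a", "e", "gamma", "r2", "d"))
  expect_equal(tabEx1$r1, c(inf = 9, sup = 11))
  expect_equal(tabEx1$d, c(inf = 3.84, sup = 3.86))
  tabC <- extremaTable(constantModel())
  for (nm in names(tabC))
    expect_equal(tabC[[nm]][["inf"]], tabC[[nm]][["sup"]])
})

test_that("worked ultimate bounds reproduce the published constants", {
  b <- ultimateBounds(tabEx1)
  expect_equal(b$M1star, 11 / 4.3)
  expect_equal(round(b$M1star, 4), 2.5581)
  expect_equal(b$M1, 2.5582)
  expect_equal(b$m1, 1.7243)
  expect_true(b$certifying)
  # chained starred bounds with the published band values as inputs
  s <- starredBounds(tabEx1, M1 = 2.5582, M2 = 0.2032, M3 = 0.1762,
                     m1 = 1.7243, m2 = 0.0300)
  expect_equal(s$M3star, 0.1761, tolerance = 2e-3)
  expect_equal(s$m1star, 1.7244, tolerance = 2e-4)
  expect_equal(s$m3star, 0.0046, tolerance = 2e-2)
  # band ordering invariant (Eq.-style): m_i < m_i* and M_i* < M_i
  for (i in 1:3) {
    expect_lt(b[[paste0("m", i)]], b[[paste0("m", i, "star")]])
    expect_lt(b[[paste0("M", i, "star")]], b[[paste0("M", i)]])
    expect_gt(b[[paste0("m", i)]], 0)
  }
})

test_that("hypothesis margins match the published example and certify", {
  b <- explicitBounds(tabEx1, M1 = 2.5582, M2 = 0.2032, M3 = 0.1762,
                      m1 = 1.7243, m2 = 0.0300, m3 = 0.0045)
  rep <- hypothesisMargins(tabEx1, b)
  expect_equal(rep$margins[["H1"]], 2.1032, tolerance = 1e-4)
  expect_equal(rep$margins[["H2"]], 0.6761, tolerance = 1e-3)
  expect_equal(rep$margins[["H6"]], 4.3 - 1.6)
  expect_equal(rep$margins[["H8"]], 3.3328, tolerance = 1e-3)
  expect_true(rep$permanent)
  expect_true(rep$globallyStable)
  expect_equal(rep$decayRateAlpha, min(rep$margins[6:8]))
  # default-policy bounds also certify the worked model
  repD <- criteriaReport(example1()$model)$report
  expect_true(repD$globallyStable)
})

test_that("constant-coefficient bounds have closed forms", {
  tab <- extremaTable(constantModel(r1 = 1, b = 1))
  s <- starredBounds(tab)
  expect_equal(s$M1star, 1)
})

test_that("a lowered predator death rate breaks (H8)", {
  cf <- ecoepi:::example1Coefs()
  cf$d <- periodicSinusoid(0.5, 0.01, pi)
  m <- do.call(ecoEpidemicModel, cf)
  cr <- suppressMessages(criteriaReport(m))
  expect_lt(cr$report$margins[["H8"]], 0)
  expect_false(cr$report$globallyStable)
  # a transmission supremum at/above the crowding infimum breaks (H6)
  cf2 <- ecoepi:::example1Coefs(psi = periodicSinusoid(4.5, 0.3, pi))
  m2 <- do.call(ecoEpidemicModel, cf2)
  cr2 <- suppressMessages(criteriaReport(m2))
  expect_lte(cr2$report$margins[["H6"]], 0)
  expect_false(cr2$report$globallyStable)
})

test_that("margins agree with an independent transcription to 1e-12", {
  models <- c(list(example1()$model, example2WeakPredation()$model),
              lapply(1:5, randomModel))
  for (m in models) {
    tab <- extremaTable(m)
    b <- suppressMessages(ultimateBounds(tab))
    rep <- hypothesisMargins(tab, b)
    expect_equal(rep$margins, oracleMargins(tab, b), tolerance = 1e-12)
    s <- starredBounds(tab, M1 = b$M1, M2 = b$M2, M3 = b$M3, m1 = b$m1,
                       m2 = b$m2)
    expect_equal(unlist(s), oracleStars(tab, b$M1, b$M2, b$M3, b$m1, b$m2),
                 tolerance = 1e-12)
  }
})

test_that("widening the margin widens bands and shifts margins as expected", {
  bA <- ultimateBounds(tabEx1, margin = 1e-4)
  bB <- ultimateBounds(tabEx1, margin = 1e-3)
  for (i in 1:3) {
    expect_gt(bB[[paste0("M", i)]], bA[[paste0("M", i)]])
    expect_lt(bB[[paste0("m", i)]], bA[[paste0("m", i)]])
  }
  rA <- hypothesisMargins(tabEx1, bA)$margins
  rB <- hypothesisMargins(tabEx1, bB)$margins
  expect_gt(rB[["H1"]], rA[["H1"]])       # grows with M1
  for (k in c("H3", "H4", "H7", "H8"))    # shrink as bands widen
    expect_lt(rB[[k]], rA[[k]])
  expect_identical(rA[["H6"]], rB[["H6"]])  # band-independent
})

test_that("reports are deterministic", {
  r1 <- criteriaReport(example1()$model)
  r2 <- criteriaReport(example1()$model)
  expect_identical(r1$bounds, r2$bounds)
  expect_identical(r1$report, r2$report)
})

test_that("permanent random models keep long simulations inside the bands", {
  for (s in 1:20) {
    m <- randomModel(s, "permanent")
    b <- suppressMessages(ultimateBounds(extremaTable(m)))
    set.seed(5000 + s)
    init <- c(stats::runif(1, 0.2, 3), stats::runif(1, 0.02, 0.5),
              stats::runif(1, 0.02, 0.5))
    tr <- integrateOde(m, init, 0, 200, denseStep = 0.1)
    rep <- persistenceBandReport(tr, b, slack = 1e-6)
    expect_false(rep$never, label = sprintf("seed %d", s))
    expect_lt(rep$entryTime, 150)
  }
})
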