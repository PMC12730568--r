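test_that("the worked fixture carries the printed coefficients", {
  ex <- example1()
  expect_equal(evalPeriodic(ex$model$coefs$r1, 0.5), 11)
  expect_equal(unname(ex$initial), c(2.5, 0.1, 0.085))
  expect_equal(ex$model$omega, 2)
  expect_equal(ex$grid$L, 2 * pi)
  expect_equal(extremaPeriodic(ex$model$coefs$psi), c(inf = 1.4, sup = 1.6))
  rep <- criteriaReport(ex$model)$report
  expect_true(rep$permanent)
  expect_true(rep$globallyStable)
})

test_that("the literal coefficient reading is kept and flagged", {
  lit <- example1Literal()
  expect_equal(extremaPeriodic(lit$model$coefs$psi),
               c(inf = 0.5, sup = 2.48))
  rep <- suppressMessages(criteriaReport(lit$model)$report)
  # H6 = b^l - psi^m still holds under this reading ...
  expect_equal(rep$margins[["H6"]], 4.3 - 2.48)
  # ... but the bound chain departs from the published constants
  b <- suppressMessages(ultimateBounds(extremaTable(lit$model)))
  expect_gt(abs(b$M2 - 0.2032), 0.01)
  # the system still integrates positively
  tr <- integrateOde(lit$model, lit$initial, 0, 60, denseStep = 0.1)
  expect_true(all(tr$states > 0))
})

test_that("weak susceptible predation boosts predators, culls infection", {
  e1 <- example1(); e2 <- example2WeakPredation()
  expect_true(e2$model$hasExtension)
  expect_equal(evalPeriodic(e2$model$coefs$c, 0.5), 10.55)  # 10.45 + 0.1
  tr1 <- integrateOde(e1$model, e1$initial, 0, 100, denseStep = 0.05)
  tr2 <- integrateOde(e2$model, e2$initial, 0, 100, denseStep = 0.05)
  expect_true(all(tr2$states > 0))
  late <- tr1$times >= 80
  expect_gt(mean(tr2$states[late, "Y"]), mean(tr1$states[late, "Y"]))
  expect_lt(mean(tr2$states[late, "XI"]), mean(tr1$states[late, "XI"]))
})

test_that("random models are reproducible and hit their targets", {
  mA <- randomModel(123)
  mB <- randomModel(123)
  t <- seq(0, 2, by = 0.1)
  for (nm in names(mA$coefs))
    expect_equal(evalPeriodic(mA$coefs[[nm]], t),
                 evalPeriodic(mB$coefs[[nm]], t))
  repS <- suppressMessages(criteriaReport(randomModel(9, "stable"))$report)
  expect_true(all(repS$satisfied))
  repV <- suppressMessages(criteriaReport(randomModel(9, "violating"))$report)
  expect_true(any(!repV$satisfied))
  repP <- suppressMessages(criteriaReport(randomModel(9, "permanent"))$report)
  expect_true(repP$permanent)
})

test_that("random model generation leaves the global RNG state alone", {
  set.seed(77)
  before <- .Random.seed
  invisible(randomModel(5, "permanent"))
  expect_identical(.Random.seed, before)
})

test_that("config files round-trip every fixture", {
  reg <- list(example1()$model, example1Literal()$model,
              example2WeakPredation()$model)
  set.seed(13)
  tt <- stats::runif(100, 0, 20)
  for (m in reg) {
    for (fmt in c("yaml", "json")) {
      path <- withr::local_tempfile(fileext = paste0(".", fmt))
      writeModelConfig(m, path)
      m2 <- readModelConfig(path)
      expect_equal(m2$omega, m$omega)
      expect_identical(m2$hasExtension, m$hasExtension)
      for (nm in names(m$coefs))
        expect_equal(evalPeriodic(m2$coefs[[nm]], tt),
                     evalPeriodic(m$coefs[[nm]], tt), tolerance = 1e-12)
    }
  }
  # the shipped config files match the in-code fixtures
  shipped <- readModelConfig(system.file("extdata", "example1.yaml",
                                         package = "ecoepi"))
  expect_equal(modelCoefs(shipped, 0.37), modelCoefs(example1()$model, 0.37))
})

test_that("a tabulated coefficient survives the config round-trip", {
  tt <- seq(0, 2, length.out = 32)[-32]
  cf <- ecoepi:::example1Coefs()
  cf$r1 <- periodicTabulated(tt, 10 + sin(pi * tt), period = 2)
  m <- do.call(ecoEpidemicModel, cf)
  path <- withr::local_tempfile(fileext = ".yaml")
  writeModelConfig(m, path)
  m2 <- readModelConfig(path)
  probe <- seq(0, 4, by = 0.03)
  expect_equal(evalPeriodic(m2$coefs$r1, probe),
               evalPeriodic(m$coefs$r1, probe), tolerance = 1e-12)
})

test_that("the command-line dispatcher checks a model file", {
  path <- system.file("extdata", "example1.yaml", package = "ecoepi")
  out <- capture.output(ecoepiMain(c("check", path, "--json")))
  parsed <- jsonlite::fromJSON(paste(out, collapse = "\n"))
  expect_true(parsed$permanent)
  expect_true(parsed$globallyStable)
  expect_equal(parsed$bounds$M1, 2.5582)
  listed <- capture.output(ecoepiMain(c("fixtures", "list")))
  expect_true(any(grepl("example2_weak_predation", listed)))
  # trajectory export
  csv <- withr::local_tempfile(fileext = ".csv")
  ecoepiMain(c("simulate-ode", path, "--init", "2.5,0.1,0.085",
               "--t-end", "5", "--step", "0.1", "--out", csv))
  df <- utils::read.csv(csv)
  expect_named(df, c("t", "XS", "XI", "Y"))
  expect_true(all(df[nrow(df), -1] > 0))
})
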