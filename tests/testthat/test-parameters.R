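test_that("analytic graph extremes match the published values", {
  ga <- groupAnchors("L")
  expect_equal(unname(graphExtremes(buildModel(ga$archetype, ga$anchors))),
               c(35, 82))
  fl <- buildModel("flat", list(rho0 = 25, x_max = 3.25))
  expect_equal(unname(graphExtremes(fl)), c(25, 25))
  h50 <- buildModel("linear_ramp", list(rho0 = 19, rho_max = 34,
                                        x_max = 3.25))
  expect_equal(unname(graphExtremes(h50)), c(19, 34))
  ## interior vertex beats both interval endpoints
  v <- buildModel("valley", list(rho0 = 50, x_m = 2, rho_min = 10,
                                 x_max = 3.25, rho_max = 45))
  expect_equal(unname(graphExtremes(v)), c(10, 50))
})

test_that("envelope extremes are the raw-profile range", {
  p <- new("ReflectivityProfile", x = 1:6, rho = c(60, 58, 91, 70, 65, 62),
           kind = "raw")
  expect_equal(unname(envelopeExtremes(p)), c(58, 91))
  cst <- new("ReflectivityProfile", x = 1:6, rho = rep(77, 6), kind = "raw")
  expect_equal(unname(envelopeExtremes(cst)), c(77, 77))
})

test_that("differences and ratios follow their defining formulas", {
  expect_equal(deltaRho(82, 35), 47)
  expect_equal(deltaRho(25, 25), 0)
  expect_equal(deltaRhoPeak(91, 58), 33)
  expect_equal(round(ratioK(82, 35), 2), 2.34)
  expect_equal(ratioK(25, 25), 1)
  expect_equal(round(ratioKPeak(91, 58), 2), 1.57)
  expect_equal(round(ratioKPeak(28, 16), 2), 1.75)
  expect_error(deltaRho(35, 82), "rho_max >= rho_min")
  expect_error(ratioK(5, 0), "rho_min must be > 0")
})

test_that("derivative maxima match the published model values", {
  gaL <- groupAnchors("L", "table")
  mL <- buildModel(gaL$archetype, gaL$anchors)
  expect_equal(round(maxGradient(mL), 2), 53.71)
  expect_equal(round(maxCurvature(mL), 2), 30.69)
  gaN <- groupAnchors("N", "table")
  mN <- buildModel(gaN$archetype, gaN$anchors)
  expect_equal(round(maxGradient(mN), 2), 24)
  expect_equal(round(maxCurvature(mN), 2), 19.2)
  gaH30 <- groupAnchors("H30", "table")
  expect_equal(maxCurvature(buildModel(gaH30$archetype, gaH30$anchors)),
               20.44, tolerance = 5e-4)
  fl <- buildModel("flat", list(rho0 = 25, x_max = 3.25))
  expect_equal(maxGradient(fl), 0)
  expect_equal(maxCurvature(fl), 0)
})

test_that("analytic gradient maxima agree with a dense numeric search", {
  for (g in studyGroups()) {
    ga <- groupAnchors(g, "table")
    m <- buildModel(ga$archetype, ga$anchors)
    num <- numericGradMax(m)
    if (num > 0)
      expect_equal(maxGradient(m), num, tolerance = 1e-3)
    else expect_lt(maxGradient(m), 1e-9)
  }
})

test_that("parameters are homogeneous under intensity scaling", {
  ga <- groupAnchors("L")
  m <- buildModel(ga$archetype, ga$anchors)
  x <- seq(0, 3.25, length.out = 101)
  raw <- new("ReflectivityProfile", x = x, rho = evaluateModel(m, x),
             kind = "raw")
  p1 <- computeParameters(raw, m)
  for (s in c(0.5, 1.5)) {
    ms <- m
    ms@segments$a <- m@segments$a * s
    ms@segments$b <- m@segments$b * s
    ms@segments$c <- m@segments$c * s
    raws <- new("ReflectivityProfile", x = x, rho = rho(raw) * s,
                kind = "raw")
    ps <- computeParameters(raws, ms)
    expect_equal(ps@deltaRho, p1@deltaRho * s)
    expect_equal(ps@deltaRhoPeak, p1@deltaRhoPeak * s)
    expect_equal(ps@gradMax, p1@gradMax * s)
    expect_equal(ps@curvMax, p1@curvMax * s)
    expect_equal(ps@meanLevel, p1@meanLevel * s)
    expect_equal(ps@k, p1@k)          # scale-free
    expect_equal(ps@kPeak, p1@kPeak)
  }
})

test_that("k equals 1 exactly when the graph contrast vanishes", {
  fl <- buildModel("flat", list(rho0 = 25, x_max = 3.25))
  x <- seq(0, 3.25, length.out = 51)
  raw <- profileFromModel(fl, x, kind = "raw")
  ps <- computeParameters(raw, fl)
  expect_identical(ps@k, 1)
  expect_identical(ps@deltaRho, 0)
  ## an invalid mixed state is rejected by the class validity
  expect_error(new("ParameterSet", rhoMin = 10, rhoMax = 10,
                   rhoMinPeak = 10, rhoMaxPeak = 10, deltaRho = 0,
                   deltaRhoPeak = 0, k = 1.2, kPeak = 1, gradMax = 0,
                   curvMax = 0, meanLevel = 10), "k == 1")
})

test_that("noise-free envelope collapses onto the graph extremes", {
  ga <- groupAnchors("N")
  m <- buildModel(ga$archetype, ga$anchors)
  raw <- profileFromModel(m, seq(0, 3.25, length.out = 201), kind = "raw")
  ps <- computeParameters(raw, m)
  expect_lte(abs(ps@rhoMinPeak - ps@rhoMin), 0.5)
  expect_lte(abs(ps@rhoMaxPeak - ps@rhoMax), 0.5)
})

test_that("parameter tables are rounded to two decimals with one row per label", {
  fl <- buildModel("flat", list(rho0 = 25, x_max = 3.25))
  raw <- profileFromModel(fl, seq(0, 3.25, length.out = 51), kind = "raw")
  tab <- parameterTable(list(list(label = "flat", raw = raw, model = fl)))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$k, 1)
  expect_equal(tab$grad_max, 0)
  expect_equal(tab$curv_max, 0)
  expect_error(parameterTable(list()), "at least one")
})
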