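refCfg <- function(material = "pressed", ...)
  assessThresholds(reference_level = normalReferenceLevel(material), ...)

paramsFor <- function(group) {
  ga <- groupAnchors(group)
  m <- buildModel(ga$archetype, ga$anchors)
  raw <- profileFromModel(m, seq(0, 3.25, length.out = 201), kind = "raw")
  list(params = computeParameters(raw, m), model = m)
}

test_that("normally fired samples are called normal", {
  pN <- paramsFor("N")
  r <- assess(pN$params, pN$model, refCfg("pressed"))
  expect_identical(verdict(r), "normal")
  expect_identical(severity(r), "n/a")
  fl <- paramsFor("N_metal")
  rf <- assess(fl$params, fl$model, refCfg("metal"))
  expect_identical(verdict(rf), "normal")
  expect_true("flat_graph" %in% evidence(rf))
})

test_that("deviated groups are flagged with the right direction", {
  pL <- paramsFor("L")
  rL <- assess(pL$params, pL$model, refCfg("pressed"))
  expect_identical(verdict(rL), "under_fired")
  expect_identical(severity(rL), "severe")   # |k - 1| = 1.34 > 1
  expect_true("low_mean_level" %in% evidence(rL))

  pH <- paramsFor("H")
  rH <- assess(pH$params, pH$model, refCfg("pressed"))
  expect_identical(verdict(rH), "over_fired")
  expect_true("banded_alternation" %in% evidence(rH))

  pU <- paramsFor("L100")
  rU <- assess(pU$params, pU$model, refCfg("metal"))
  expect_identical(verdict(rU), "under_fired")
})

test_that("a tilted linear graph forces over-fired severe regardless of k", {
  m <- buildModel("linear_ramp", list(rho0 = 19, rho_max = 34,
                                      x_max = 3.25))
  raw <- profileFromModel(m, seq(0, 3.25, length.out = 201), kind = "raw")
  ps <- computeParameters(raw, m)
  expect_equal(round(ps@k, 2), 1.79)
  r <- assess(ps, m, refCfg("metal"))
  expect_identical(verdict(r), "over_fired")
  expect_identical(severity(r), "severe")
  expect_true("tilted_linear_graph" %in% evidence(r))
  ## even a shallow ramp whose k sits inside the normal band
  m2 <- buildModel("linear_ramp", list(rho0 = 25, rho_max = 34,
                                       x_max = 3.25))
  ps2 <- computeParameters(
    profileFromModel(m2, seq(0, 3.25, length.out = 201), kind = "raw"), m2)
  expect_lt(abs(ps2@k - 1), 0.45)
  expect_identical(verdict(assess(ps2, m2, refCfg("metal"))), "over_fired")
})

test_that("relative mean-level cuts require a reference level", {
  pL <- paramsFor("L")
  expect_error(assess(pL$params, pL$model, assessThresholds()),
               "reference_level")
  ## normal-band decisions do not need the reference
  pN <- paramsFor("N")
  expect_identical(verdict(assess(pN$params, pN$model,
                                  assessThresholds())), "normal")
})

test_that("k responds monotonically to contrast and the verdict flips once", {
  cfgT <- refCfg("pressed")
  prevK <- -Inf
  states <- character(0)
  for (rmin in seq(60, 20, by = -5)) {
    m <- buildModel("valley", list(rho0 = 60, x_m = 1.5, rho_min = rmin,
                                   x_max = 3.25, rho_max = 60))
    raw <- profileFromModel(m, seq(0, 3.25, length.out = 101),
                            kind = "raw")
    ps <- computeParameters(raw, m)
    expect_gte(ps@k, prevK)
    prevK <- ps@k
    states <- c(states, verdict(assess(ps, m, cfgT)))
  }
  expect_identical(states[1L], "normal")
  flips <- sum(states[-1L] != states[-length(states)])
  expect_equal(flips, 1L)                  # one transition, no flip-flop
  expect_true(all(states[states != "normal"] != "normal"))
})

test_that("k is ranked above the curvature across the study cohorts", {
  tab <- reproduceTables()
  stats <- publishedGroupStats()
  tab$offset <- stats$offset[match(tab$group, stats$group)]
  cohorts <- split(tab, tab$material)
  rk <- rankByConsistency(cohorts,
                          parameters = c("delta_rho", "k", "grad_max",
                                         "curv_max"))
  expect_lt(which(rk$parameter == "k"), which(rk$parameter == "curv_max"))
  expect_gt(rk$concordance[rk$parameter == "k"],
            rk$concordance[rk$parameter == "curv_max"])
  expect_error(rankByConsistency(cohorts[1L]), "at least two")
})

test_that("perfectly monotone cohorts tie at full concordance, alphabetical order", {
  co <- data.frame(offset = c(0, 30, 50),
                   b_par = c(1, 2, 3), a_par = c(10, 20, 30))
  rk <- rankByConsistency(list(co, co))
  expect_equal(rk$concordance, c(1, 1))
  expect_identical(rk$parameter, c("a_par", "b_par"))
})

test_that("shuffled cohorts show near-zero concordance", {
  set.seed(1)
  vals <- replicate(40, {
    co <- data.frame(offset = c(0, 10, 30, 50, 100), p = sample(1:5))
    rankByConsistency(list(co, co))$concordance
  })
  expect_lt(abs(mean(vals)), 0.2)
})

test_that("assessment summaries carry a gating exit status", {
  pN <- paramsFor("N")
  ok <- assess(pN$params, pN$model, refCfg("pressed"))
  pL <- paramsFor("L")
  bad <- assess(pL$params, pL$model, refCfg("pressed"))
  expect_equal(assessmentSummary(list(s1 = ok))$status, 0L)
  mix <- assessmentSummary(list(s1 = ok, s2 = bad))
  expect_equal(mix$status, 1L)
  expect_length(mix$text, 2L)
  expect_match(mix$text[2L], "under_fired")
  expect_error(assessmentSummary(list()), "no assessments")
})
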