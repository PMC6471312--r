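test_that("scene configs carry the published group anchors", {
  cfg <- sceneFromGroup("L", 1)
  expect_identical(modelArchetype(cfg), "valley")
  a <- modelAnchors(cfg)
  expect_equal(c(a$rho0, a$rho_min, a$x_m, a$rho_max, a$x_max),
               c(60, 35, 1.5, 82, 3.25))
  expect_identical(modelArchetype(sceneFromGroup("N_metal", 1)), "flat")
  expect_equal(modelAnchors(sceneFromGroup("N_metal", 1))$rho0, 25)
  expect_identical(modelArchetype(sceneFromGroup("H50", 1)), "linear_ramp")
  expect_error(sceneFromGroup("X9", 1), "unknown group")
})

test_that("ground-truth parameters equal the generating model's", {
  kL <- trueParameters(renderEnFace(
    sceneFromGroup("L", 1, widthPx = 32L, heightPx = 32L,
                   noiseModel = "none", grainDensity = 0))$truth)
  expect_equal(round(kL@k, 2), 2.34)
  tH <- trueParameters(renderEnFace(
    sceneFromGroup("H", 1, widthPx = 32L, heightPx = 32L,
                   noiseModel = "none", grainDensity = 0))$truth)
  expect_equal(tH@deltaRho, 48)
  tF <- trueParameters(renderEnFace(
    sceneFromGroup("N_metal", 1, widthPx = 32L, heightPx = 32L,
                   noiseModel = "none", grainDensity = 0))$truth)
  expect_equal(tF@k, 1)
  expect_equal(tF@deltaRho, 0)
  ## self-consistency with the parameters module
  truth <- renderEnFace(sceneFromGroup("N", 5, widthPx = 32L,
                                       heightPx = 32L))$truth
  expect_equal(as.data.frame(trueParameters(truth)),
               as.data.frame(sinterOCT:::.paramsFromModel(trueModel(truth))))
})

test_that("rendering is deterministic for identical configs", {
  cfg <- sceneFromGroup("H30", 9, widthPx = 64L, heightPx = 64L)
  a <- renderEnFace(cfg)
  b <- renderEnFace(cfg)
  expect_identical(pixels(a$image), pixels(b$image))
  expect_identical(grainCount(a$truth), grainCount(b$truth))
  dif <- renderEnFace(sceneFromGroup("H30", 10, widthPx = 64L,
                                     heightPx = 64L))
  expect_false(identical(pixels(a$image), pixels(dif$image)))
})

test_that("a noise-free flat scene renders a constant field", {
  out <- renderEnFace(sceneFromGroup("N_metal", 2, widthPx = 32L,
                                     heightPx = 24L, noiseModel = "none",
                                     grainDensity = 0))
  expect_true(all(pixels(out$image) == 25))
})

test_that("noise-free column means track the generating graph within 1 gray", {
  for (g in c("L", "N", "H", "H50")) {
    cfg <- sceneFromGroup(g, 3, widthPx = 128L, heightPx = 64L,
                          noiseModel = "none", grainDensity = 0)
    out <- renderEnFace(cfg)
    p <- extractProfile(out$image)
    expect_lte(max(abs(rho(p) - evaluateModel(trueModel(out$truth),
                                              xPos(p)))), 1)
  }
})

test_that("anchors outside the 8-bit range are rejected at render", {
  cfg <- sceneFromGroup("L", 1, widthPx = 32L, heightPx = 32L,
                        noiseModel = "none", grainDensity = 0)
  cfg@anchors$rho_max <- 300
  expect_error(renderEnFace(cfg), "0-255")
})

test_that("deeper valleys yield strictly larger recovered contrast", {
  prev <- -Inf
  for (rmin in c(50, 40, 30, 20)) {
    cfg <- sceneFromGroup("L", 1, widthPx = 128L, heightPx = 32L,
                          noiseModel = "none", grainDensity = 0)
    cfg@anchors$rho_min <- rmin
    out <- renderEnFace(cfg)
    sm <- smoothProfile(extractProfile(out$image), 3L)
    fit <- fitModel(sm, "valley")
    dr <- computeParameters(extractProfile(out$image), fit$model)@deltaRho
    expect_gt(dr, prev)
    prev <- dr
  }
})

test_that("planted non-overlapping grains are counted exactly downstream", {
  cfg <- sceneFromGroup("N_metal", 4, widthPx = 128L, heightPx = 128L,
                        noiseModel = "none", grainDensity = 10,
                        grainAmplitude = 200)
  out <- renderEnFace(cfg)
  expect_gt(grainCount(out$truth), 0L)
  expect_equal(countGrains(binarize(out$image)), grainCount(out$truth))
})

test_that("x-banded scenes are rotated back to an identical analysis", {
  ox <- renderEnFace(sceneFromGroup("L", 3, widthPx = 128L,
                                    heightPx = 128L, bandAxis = "x"))
  oy <- renderEnFace(sceneFromGroup("L", 3, widthPx = 128L,
                                    heightPx = 128L, bandAxis = "y"))
  expect_identical(pixels(orientBands(ox$image)), pixels(oy$image))
})
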