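test_that("binarization is strictly above the threshold", {
  all127 <- EnFaceImage(matrix(127, 8, 8))
  expect_true(all(pixels(binarize(all127)) == 0))
  all128 <- EnFaceImage(matrix(128, 8, 8))
  expect_true(all(pixels(binarize(all128)) == 1))
  chk <- matrix(c(0, 255), 8, 8)   # alternating columns-by-rows pattern
  b <- binarize(EnFaceImage(chk))
  expect_equal(pixels(b), (chk > 127) + 0)
  expect_error(binarize(all127, threshold = 300), "threshold")
})

test_that("grain counting uses 8-connectivity", {
  z <- matrix(0, 8, 8)
  expect_equal(countGrains(new("BinaryImage", pixels = z, threshold = 127)),
               0L)
  sq <- matrix(0, 12, 12)
  sq[2:3, 2:3] <- 1; sq[6:7, 6:7] <- 1; sq[10:11, 2:3] <- 1
  expect_equal(countGrains(new("BinaryImage", pixels = sq, threshold = 127)),
               3L)
  diagp <- matrix(0, 5, 5); diagp[2, 2] <- 1; diagp[3, 3] <- 1
  expect_equal(countGrains(new("BinaryImage", pixels = diagp,
                               threshold = 127)), 1L)
})

test_that("grain counting matches a flood-fill oracle on random 8x8 grids", {
  set.seed(42)
  for (i in seq_len(1000L)) {
    m <- matrix(rbinom(64, 1, runif(1, 0.2, 0.7)), 8, 8)
    expect_equal(countGrains(new("BinaryImage", pixels = m,
                                 threshold = 127)),
                 floodFillCount(m))
  }
})

test_that("profile extraction averages columns at pixel-center abscissae", {
  cst <- EnFaceImage(matrix(42, 10, 10))
  p <- extractProfile(cst)
  expect_equal(rho(p), rep(42, 10))
  expect_equal(xPos(p), (1:10 - 0.5) * 0.325)
  step <- EnFaceImage(cbind(matrix(0, 10, 5), matrix(255, 10, 5)))
  expect_equal(rho(extractProfile(step)), rep(c(0, 255), each = 5))
})

test_that("column-average conservation: profile mean equals image mean", {
  set.seed(7)
  img <- EnFaceImage(matrix(sample(0:255, 900, TRUE), 30, 30))
  expect_equal(mean(rho(extractProfile(img))), mean(pixels(img)),
               tolerance = 1e-9)
})

test_that("smoothing is a shrinking-window moving average", {
  alt <- new("ReflectivityProfile", x = 1:10, rho = rep(c(0, 255), 5),
             kind = "raw")
  sm <- smoothProfile(alt, 3L)
  expect_equal(rho(sm)[2:9], rep(c(85, 170), 4))   # interior window of 3
  expect_equal(rho(sm)[c(1, 10)], c(127.5, 127.5)) # shrunk edge windows
  expect_identical(rho(smoothProfile(alt, 1L)), rho(alt))
  cstp <- new("ReflectivityProfile", x = 1:9, rho = rep(33, 9),
              kind = "raw")
  expect_equal(rho(smoothProfile(cstp, 5L)), rep(33, 9))
  expect_error(smoothProfile(alt, 4L), "odd")
})

test_that("smoothing never leaves the range of the input", {
  set.seed(11)
  for (i in 1:20) {
    p <- new("ReflectivityProfile", x = 1:50,
             rho = runif(50, 0, 255), kind = "raw")
    for (w in c(3L, 7L, 15L)) {
      sm <- rho(smoothProfile(p, w))
      expect_gte(min(sm), min(rho(p)))
      expect_lte(max(sm), max(rho(p)))
    }
  }
})

test_that("air-to-material depth conversion divides by the index", {
  expect_equal(airToMaterialDepth(3.75, 1.5), 2.5)
  expect_equal(airToMaterialDepth(0, 1.5), 0)
  expect_equal(airToMaterialDepth(0.375, 1.0), 0.375)
  expect_error(airToMaterialDepth(1, 0.9), ">= 1")
})

test_that("band orientation is detected and corrected", {
  bands <- EnFaceImage(matrix(rep(c(40, 200), each = 10 * 5), 10, 10))
  expect_identical(pixels(orientBands(bands)), pixels(bands))
  rot <- EnFaceImage(t(pixels(bands))[10:1, ])
  back <- orientBands(rot)
  expect_equal(sort(colMeans(pixels(back))), sort(colMeans(pixels(bands))))
  cst <- EnFaceImage(matrix(9, 6, 6) + 0)
  expect_identical(pixels(orientBands(cst)), pixels(cst))  # tie: unchanged
})

test_that("image files round-trip and bad inputs are rejected", {
  img <- EnFaceImage(matrix(sample(0:255, 400, TRUE), 20, 20))
  fp <- tempfile(fileext = ".png")
  writeEnFace(img, fp)
  expect_equal(pixels(readEnFace(fp)), pixels(img))
  ft <- tempfile(fileext = ".tif")
  writeEnFace(img, ft)
  expect_equal(pixels(readEnFace(ft)), pixels(img))

  frgb <- tempfile(fileext = ".png")
  png::writePNG(array(runif(300), c(10, 10, 3)), frgb)
  expect_error(readEnFace(frgb), "single-channel 8-bit")
  f16 <- tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(100), 10, 10), f16, bits.per.sample = 16L)
  expect_error(readEnFace(f16), "8-bit")
  expect_error(readEnFace(tempfile(fileext = ".png")), "not found")
})
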