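## Synthetic en-face OCT phantoms with known ground truth.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Scene configuration for a study group
#'
#' Returns a [SceneConfig-class] whose archetype and anchors reproduce the
#' group's published averaged reflectivity graph (see [groupAnchors()]),
#' ready for [renderEnFace()]. Defaults emulate the study's acquisition:
#' 500 x 500 px covering 3.25 mm x 3.25 mm, bands parallel to the y axis,
#' multiplicative speckle, and a dense field of small bright grain
#' clusters. The grain defaults (30 clusters per mm^2, radius 1-2 px,
#' +40 gray levels) emulate fine granulation that line averaging largely
#' suppresses: the averaged graph stays within ~1-2 gray levels of the
#' band model while the raw profile picks up spikes of a few gray levels,
#' the same relation the published envelope and graph extremes exhibit.
#'
#' @param group a study group label (see [studyGroups()]).
#' @param seed integer seed; identical configs render identical phantoms.
#' @param widthPx,heightPx raster size in pixels.
#' @param lateralExtent lateral size in mm.
#' @param noiseModel `"none"`, `"gaussian"` or `"speckle"`.
#' @param noiseScale noise scale: gray levels for `"gaussian"`, relative
#'   standard deviation of the unit-mean multiplier for `"speckle"`;
#'   must be 0 for `"none"`.
#' @param grainDensity grain clusters per mm^2.
#' @param grainRadiusPx integer range of disc radii (px).
#' @param grainAmplitude added disc brightness (gray levels).
#' @param bandAxis `"y"` (reference orientation) or `"x"` (rotated scene).
#' @return a [SceneConfig-class].
#' @examples
#' cfg <- sceneFromGroup("L", seed = 1)
#' modelArchetype(cfg)
#' @export
sceneFromGroup <- function(group, seed,
                           widthPx = 500L, heightPx = 500L,
                           lateralExtent = 3.25,
                           noiseModel = c("speckle", "gaussian", "none"),
                           noiseScale = 0.1,
                           grainDensity = 30, grainRadiusPx = c(1L, 2L),
                           grainAmplitude = 40, bandAxis = "y") {
  if (!group %in% .GROUPS)
    stop("unknown group label '", group, "'; expected one of ",
         paste(.GROUPS, collapse = ", "))
  noiseModel <- match.arg(noiseModel)
  if (noiseModel == "none") noiseScale <- 0
  ga <- groupAnchors(group, purpose = "scene")
  anch <- ga$anchors
  anch$x_max <- lateralExtent
  new("SceneConfig",
      widthPx = as.integer(widthPx), heightPx = as.integer(heightPx),
      lateralExtent = lateralExtent, archetype = ga$archetype,
      anchors = anch, grainDensity = grainDensity,
      grainRadiusPx = as.integer(grainRadiusPx),
      grainAmplitude = grainAmplitude, bandAxis = bandAxis,
      noiseModel = noiseModel, noiseScale = noiseScale,
      seed = as.integer(seed))
}

## Plant non-overlapping bright discs; returns list(field, count).
.plantGrains <- function(nrow, ncol, density, radiusRange, amplitude,
                         areaMm2) {
  field <- matrix(0, nrow, ncol)
  n <- stats::rpois(1L, density * areaMm2)
  if (n == 0L) return(list(field = field, count = 0L))
  placed <- matrix(numeric(0), ncol = 3L)  # row, col, radius
  for (g in seq_len(n)) {
    for (try in seq_len(100L)) {
      r <- sample(seq(radiusRange[1L], radiusRange[2L]), 1L)
      ci <- stats::runif(1L, 1 + r, nrow - r)
      cj <- stats::runif(1L, 1 + r, ncol - r)
      ## demand a >= 2 px gap so discs stay disjoint under 8-connectivity
      ok <- !nrow(placed) ||
        all(sqrt((placed[, 1L] - ci)^2 + (placed[, 2L] - cj)^2) >=
              placed[, 3L] + r + 2)
      if (ok) {
        placed <- rbind(placed, c(ci, cj, r))
        ii <- max(1L, floor(ci - r)):min(nrow, ceiling(ci + r))
        jj <- max(1L, floor(cj - r)):min(ncol, ceiling(cj + r))
        d2 <- outer((ii - ci)^2, (jj - cj)^2, "+")
        field[ii, jj] <- field[ii, jj] + amplitude * (d2 <= r^2)
        break
      }
    }
  }
  list(field = field, count = nrow(placed))
}

#' Render a synthetic en-face OCT image
#'
#' Draws the phantom described by a [SceneConfig-class]: each column's mean
#' follows the archetype's averaged graph `rho(x)` evaluated at the column
#' center, sparse bright grain discs are added (non-overlapping placement),
#' noise is applied (`gaussian`: additive; `speckle`: multiplicative with a
#' unit-mean gamma multiplier of the configured relative spread), and the
#' result is quantized to 8 bits. Ground truth (generating model, its
#' parameter set, and the planted grain count) is stored pre-quantization.
#'
#' Identical configurations (including the seed) render bit-identical
#' images.
#'
#' @param config a [SceneConfig-class].
#' @return list with elements `image` ([EnFaceImage-class]) and `truth`
#'   ([GroundTruth-class]).
#' @examples
#' cfg <- sceneFromGroup("N_metal", seed = 1, widthPx = 64, heightPx = 64,
#'                       noiseModel = "none", grainDensity = 0)
#' out <- renderEnFace(cfg)
#' unique(as.vector(pixels(out$image)))  # constant field at rho0
#' @export
renderEnFace <- function(config) {
  validObject(config)
  model <- buildModel(config@archetype, config@anchors)
  xs <- (seq_len(config@widthPx) - 0.5) *
    (config@lateralExtent / config@widthPx)
  mu <- evaluateModel(model, xs)
  if (min(mu) < 0 || max(mu) > 255)
    stop("anchors put the reflectivity model outside the 0-255 gray range")
  .withSeed(config@seed, {
    base <- matrix(mu, nrow = config@heightPx, ncol = config@widthPx,
                   byrow = TRUE)
    areaMm2 <- config@lateralExtent^2 *
      (config@heightPx / config@widthPx)
    gr <- if (config@grainDensity > 0)
      .plantGrains(config@heightPx, config@widthPx, config@grainDensity,
                   config@grainRadiusPx, config@grainAmplitude, areaMm2)
    else list(field = 0, count = 0L)
    scene <- base + gr$field
    noisy <- switch(config@noiseModel,
      none = scene,
      gaussian = scene + matrix(
        stats::rnorm(length(scene), 0, config@noiseScale),
        nrow = nrow(base)),
      speckle = {
        sh <- 1 / config@noiseScale^2  # unit mean, sd = noiseScale
        scene * matrix(stats::rgamma(length(scene), shape = sh, rate = sh),
                       nrow = nrow(base))
      })
    px <- pmin(pmax(round(noisy), 0), 255)
    if (config@bandAxis == "x") {  # rotate 90 deg: bands become horizontal
      px <- t(px[nrow(px):1, , drop = FALSE])
      img <- new("EnFaceImage", pixels = px,
                 extentX = config@lateralExtent * config@heightPx /
                   config@widthPx,
                 extentY = config@lateralExtent)
    } else {
      img <- new("EnFaceImage", pixels = px,
                 extentX = config@lateralExtent,
                 extentY = config@lateralExtent * config@heightPx /
                   config@widthPx)
    }
    truth <- new("GroundTruth", model = model,
                 parameters = .paramsFromModel(model),
                 grainCount = as.integer(gr$count))
    list(image = img, truth = truth)
  })
}
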