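#' @import methods
NULL

## Archetype vocabulary for averaged reflectivity graphs rho(x).
.ARCHETYPES <- c("valley", "hump_valley", "oscillation", "ramp_plateau",
                 "linear_ramp", "flat")

## Study group labels: three pressed-ceramic groups and five metal-ceramic
## groups, named by their firing-temperature offset from the prescribed one.
.GROUPS <- c("L", "N", "H", "L100", "L30", "N_metal", "H30", "H50")

#' EnFaceImage: an 8-bit grayscale en-face OCT raster
#'
#' Holds the pixel matrix of a constant-depth (C-scan) OCT image together
#' with its lateral physical extent. Rows run along the y axis, columns
#' along the x axis, so column `j` samples lateral position
#' `x = (j - 0.5) * extentX / ncol` (pixel-center convention).
#'
#' @slot pixels numeric matrix, gray levels in `[0, 255]`.
#' @slot extentX,extentY lateral physical extents in mm (both `> 0`).
#' @exportClass EnFaceImage
setClass("EnFaceImage",
  representation(pixels = "matrix", extentX = "numeric", extentY = "numeric"),
  validity = function(object) {
    p <- object@pixels
    if (!is.numeric(p)) return("pixels must be a numeric matrix")
    if (anyNA(p)) return("pixels must not contain NA")
    if (min(p) < 0 || max(p) > 255) return("pixel values must lie in [0, 255]")
    if (length(object@extentX) != 1L || length(object@extentY) != 1L ||
        object@extentX <= 0 || object@extentY <= 0)
      return("extents must be single positive numbers (mm)")
    TRUE
  })

#' BinaryImage: thresholded en-face image
#'
#' @slot pixels matrix of 0/1 values.
#' @slot threshold gray level used to produce it (provenance).
#' @exportClass BinaryImage
setClass("BinaryImage",
  representation(pixels = "matrix", threshold = "numeric"),
  validity = function(object) {
    if (!all(object@pixels %in% c(0, 1))) return("pixels must be 0 or 1")
    TRUE
  })

#' ReflectivityProfile: reflectivity versus lateral position
#'
#' The y-averaged reflectivity of an en-face image as a function of the
#' x position (mm). `kind` distinguishes the raw column-mean profile from
#' its moving-average smoothed graph; both share abscissae.
#'
#' @slot x strictly increasing abscissae in mm.
#' @slot rho reflectivity (gray levels) at each abscissa, in `[0, 255]`.
#' @slot kind `"raw"` or `"smoothed"`.
#' @exportClass ReflectivityProfile
setClass("ReflectivityProfile",
  representation(x = "numeric", rho = "numeric", kind = "character"),
  validity = function(object) {
    if (length(object@x) != length(object@rho))
      return("x and rho must have equal length")
    if (length(object@x) && any(diff(object@x) <= 0))
      return("x must be strictly increasing")
    if (length(object@rho) && (min(object@rho) < 0 || max(object@rho) > 255))
      return("rho must lie in [0, 255]")
    if (!object@kind %in% c("raw", "smoothed"))
      return("kind must be 'raw' or 'smoothed'")
    TRUE
  })

#' PiecewiseModel: analytic model of an averaged reflectivity graph
#'
#' An ordered set of quadratic/linear/constant segments
#' `a x^2 + b x + c` on contiguous half-open intervals `[x_lo, x_hi)`
#' covering `[0, x_max]` (the last interval is closed at `x_max`).
#'
#' @slot segments data.frame with columns `x_lo`, `x_hi`, `a`, `b`, `c`.
#' @slot archetype one of `"valley"`, `"hump_valley"`, `"oscillation"`,
#'   `"ramp_plateau"`, `"linear_ramp"`, `"flat"`.
#' @slot anchors named list of the anchor values the model was built from.
#' @exportClass PiecewiseModel
setClass("PiecewiseModel",
  representation(segments = "data.frame", archetype = "character",
                 anchors = "list"),
  validity = function(object) {
    s <- object@segments
    need <- c("x_lo", "x_hi", "a", "b", "c")
    if (!all(need %in% names(s))) return("segments need x_lo,x_hi,a,b,c")
    if (nrow(s) < 1L) return("at least one segment required")
    if (any(s$x_lo >= s$x_hi)) return("segment intervals must be non-empty")
    if (nrow(s) > 1L) {
      if (max(abs(s$x_hi[-nrow(s)] - s$x_lo[-1L])) > 1e-9)
        return("segment intervals must be contiguous")
      ## continuity within 0.5 gray level at interior breakpoints
      ## (printed anchors are rounded to the gray level)
      for (i in seq_len(nrow(s) - 1L)) {
        xb <- s$x_hi[i]
        left <- s$a[i] * xb^2 + s$b[i] * xb + s$c[i]
        right <- s$a[i + 1L] * xb^2 + s$b[i + 1L] * xb + s$c[i + 1L]
        if (abs(left - right) > 0.5)
          return(sprintf("discontinuity %.3f at x = %.4f", left - right, xb))
      }
    }
    if (!object@archetype %in% .ARCHETYPES)
      return("unknown archetype")
    TRUE
  })

#' ParameterSet: the multi-parameter characterization of a sample
#'
#' Extremes of the averaged graph and of the raw-profile envelope, their
#' differences and ratios, and the maxima of the first and second
#' derivatives of the analytic model.
#'
#' @slot rhoMin,rhoMax extremes of the averaged graph (gray levels).
#' @slot rhoMinPeak,rhoMaxPeak extremes of the raw-profile envelope.
#' @slot deltaRho `rhoMax - rhoMin`; @slot deltaRhoPeak envelope difference.
#' @slot k `rhoMax / rhoMin`; @slot kPeak envelope ratio.
#' @slot gradMax maximum |d rho/d x| (gray levels per mm).
#' @slot curvMax maximum |d^2 rho/d x^2| (gray levels per mm^2).
#' @slot meanLevel mean of the averaged graph over the domain.
#' @exportClass ParameterSet
setClass("ParameterSet",
  representation(rhoMin = "numeric", rhoMax = "numeric",
                 rhoMinPeak = "numeric", rhoMaxPeak = "numeric",
                 deltaRho = "numeric", deltaRhoPeak = "numeric",
                 k = "numeric", kPeak = "numeric",
                 gradMax = "numeric", curvMax = "numeric",
                 meanLevel = "numeric"),
  validity = function(object) {
    if (object@deltaRho < -1e-9) return("deltaRho must be >= 0")
    if (object@deltaRhoPeak < -1e-9) return("deltaRhoPeak must be >= 0")
    if (object@rhoMin > 0 && object@k < 1 - 1e-9) return("k must be >= 1")
    if ((object@deltaRho == 0) != (abs(object@k - 1) < 1e-9))
      return("k == 1 must hold exactly when deltaRho == 0")
    ## the envelope encloses the averaged graph, up to rounding
    if (object@rhoMinPeak > object@rhoMin + 0.5)
      return("envelope minimum must lie below the graph minimum")
    if (object@rhoMaxPeak < object@rhoMax - 0.5)
      return("envelope maximum must lie above the graph maximum")
    TRUE
  })

#' SceneConfig: parameters of a synthetic en-face phantom
#'
#' @slot widthPx,heightPx raster size in pixels (both `>= 16`).
#' @slot lateralExtent lateral size in mm along the profile axis.
#' @slot archetype generating graph archetype.
#' @slot anchors anchor list consistent with the archetype
#'   (see [buildModel()]).
#' @slot grainDensity bright grain clusters per mm^2.
#' @slot grainRadiusPx integer range (length 2) of disc radii in px.
#' @slot grainAmplitude added brightness of a grain disc (gray levels).
#' @slot bandAxis `"y"` (bands parallel to y, the reference orientation)
#'   or `"x"` (rotated scene, exercises auto-orientation).
#' @slot noiseModel `"none"`, `"gaussian"` or `"speckle"`.
#' @slot noiseScale nonnegative; 0 exactly when `noiseModel == "none"`.
#' @slot seed integer RNG seed; identical configs render identical images.
#' @exportClass SceneConfig
setClass("SceneConfig",
  representation(widthPx = "integer", heightPx = "integer",
                 lateralExtent = "numeric", archetype = "character",
                 anchors = "list", grainDensity = "numeric",
                 grainRadiusPx = "integer", grainAmplitude = "numeric",
                 bandAxis = "character", noiseModel = "character",
                 noiseScale = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@widthPx < 16L || object@heightPx < 16L)
      return("widthPx and heightPx must be >= 16")
    if (object@lateralExtent <= 0) return("lateralExtent must be > 0")
    if (!object@archetype %in% .ARCHETYPES) return("unknown archetype")
    if (!object@bandAxis %in% c("x", "y")) return("bandAxis must be 'x' or 'y'")
    if (!object@noiseModel %in% c("none", "gaussian", "speckle"))
      return("unknown noiseModel")
    if ((object@noiseScale == 0) != (object@noiseModel == "none"))
      return("noiseScale must be 0 exactly when noiseModel is 'none'")
    if (object@noiseScale < 0) return("noiseScale must be >= 0")
    if (length(object@grainRadiusPx) != 2L || any(object@grainRadiusPx < 1L))
      return("grainRadiusPx must be two positive integers (min, max)")
    if (object@grainDensity < 0) return("grainDensity must be >= 0")
    TRUE
  })

#' GroundTruth: generating model and parameters of a rendered phantom
#'
#' @slot model the generating [PiecewiseModel-class].
#' @slot parameters the [ParameterSet-class] of the generating model
#'   (pre-quantization, noise-free).
#' @slot grainCount number of grain discs actually planted.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(model = "PiecewiseModel", parameters = "ParameterSet",
                 grainCount = "integer"))

#' AssessmentReport: the firing-temperature verdict for one sample
#'
#' @slot verdict `"normal"`, `"under_fired"`, `"over_fired"` or
#'   `"indeterminate"`.
#' @slot severity `"mild"`, `"severe"` or `"n/a"`.
#' @slot kDeviation `|k - 1|` of the sample.
#' @slot evidence character vector of triggered flags among
#'   `low_mean_level`, `high_mean_level`, `tilted_linear_graph`,
#'   `banded_alternation`, `flat_graph`.
#' @slot thresholds the active threshold configuration (list).
#' @exportClass AssessmentReport
setClass("AssessmentReport",
  representation(verdict = "character", severity = "character",
                 kDeviation = "numeric", evidence = "character",
                 thresholds = "list"),
  validity = function(object) {
    if (!object@verdict %in% c("normal", "under_fired", "over_fired",
                               "indeterminate"))
      return("unknown verdict")
    if (!object@severity %in% c("mild", "severe", "n/a"))
      return("unknown severity")
    nb <- object@thresholds$normal_band
    if (object@verdict == "normal" && !is.null(nb) &&
        !("tilted_linear_graph" %in% object@evidence) &&
        object@kDeviation > nb + 1e-12)
      return("normal verdict requires kDeviation <= normal_band")
    TRUE
  })
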