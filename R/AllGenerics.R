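#' @include AllClasses.R
NULL

#' Accessors for sinterOCT classes
#'
#' Small accessor family: slot access through functions, in the usual
#' Bioconductor style.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "EnFaceImage", function(x) x@pixels)
#' @rdname accessors
#' @export
setMethod("pixels", "BinaryImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("xPos", function(x) standardGeneric("xPos"))
#' @rdname accessors
#' @export
setMethod("xPos", "ReflectivityProfile", function(x) x@x)

#' @rdname accessors
#' @export
setGeneric("rho", function(x) standardGeneric("rho"))
#' @rdname accessors
#' @export
setMethod("rho", "ReflectivityProfile", function(x) x@rho)

#' @rdname accessors
#' @export
setGeneric("modelSegments", function(x) standardGeneric("modelSegments"))
#' @rdname accessors
#' @export
setMethod("modelSegments", "PiecewiseModel", function(x) x@segments)

#' @rdname accessors
#' @export
setGeneric("modelArchetype", function(x) standardGeneric("modelArchetype"))
#' @rdname accessors
#' @export
setMethod("modelArchetype", "PiecewiseModel", function(x) x@archetype)
#' @rdname accessors
#' @export
setMethod("modelArchetype", "SceneConfig", function(x) x@archetype)

#' @rdname accessors
#' @export
setGeneric("modelAnchors", function(x) standardGeneric("modelAnchors"))
#' @rdname accessors
#' @export
setMethod("modelAnchors", "PiecewiseModel", function(x) x@anchors)
#' @rdname accessors
#' @export
setMethod("modelAnchors", "SceneConfig", function(x) x@anchors)

#' @rdname accessors
#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))
#' @rdname accessors
#' @export
setMethod("verdict", "AssessmentReport", function(x) x@verdict)

#' @rdname accessors
#' @export
setGeneric("severity", function(x) standardGeneric("severity"))
#' @rdname accessors
#' @export
setMethod("severity", "AssessmentReport", function(x) x@severity)

#' @rdname accessors
#' @export
setGeneric("evidence", function(x) standardGeneric("evidence"))
#' @rdname accessors
#' @export
setMethod("evidence", "AssessmentReport", function(x) x@evidence)

#' @rdname accessors
#' @export
setGeneric("trueModel", function(x) standardGeneric("trueModel"))
#' @rdname accessors
#' @export
setMethod("trueModel", "GroundTruth", function(x) x@model)

#' @rdname accessors
#' @export
setGeneric("grainCount", function(x) standardGeneric("grainCount"))
#' @rdname accessors
#' @export
setMethod("grainCount", "GroundTruth", function(x) x@grainCount)

#' Parameter set of the generating model of a phantom
#'
#' Returns the [ParameterSet-class] of the model a phantom was rendered
#' from, for recovery tests against downstream estimates.
#'
#' @param x a [GroundTruth-class] as returned by [renderEnFace()].
#' @return a [ParameterSet-class].
#' @export
setGeneric("trueParameters", function(x) standardGeneric("trueParameters"))
#' @rdname trueParameters
#' @export
setMethod("trueParameters", "GroundTruth", function(x) x@parameters)

#' @describeIn ParameterSet-class coerce to a one-row data.frame (full
#'   precision; see [parameterTable()] for the 2-decimal table layout).
#' @param x a ParameterSet.
#' @param row.names,optional,... ignored, present for generic consistency.
#' @export
setMethod("as.data.frame", "ParameterSet",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(rho_min_peak = x@rhoMinPeak, rho_max_peak = x@rhoMaxPeak,
               delta_rho_peak = x@deltaRhoPeak, k_peak = x@kPeak,
               rho_min = x@rhoMin, rho_max = x@rhoMax,
               delta_rho = x@deltaRho, k = x@k,
               grad_max = x@gradMax, curv_max = x@curvMax,
               mean_level = x@meanLevel)
  })

setMethod("show", "EnFaceImage", function(object) {
  cat(sprintf("EnFaceImage: %d x %d px, %.3g x %.3g mm, gray range [%g, %g]\n",
              nrow(object@pixels), ncol(object@pixels),
              object@extentY, object@extentX,
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "ReflectivityProfile", function(object) {
  cat(sprintf("ReflectivityProfile (%s): %d points on [%.3g, %.3g] mm, rho in [%.4g, %.4g]\n",
              object@kind, length(object@x),
              min(object@x), max(object@x),
              min(object@rho), max(object@rho)))
})

setMethod("show", "PiecewiseModel", function(object) {
  cat(sprintf("PiecewiseModel <%s>, %d segment(s) on [0, %.3g] mm\n",
              object@archetype, nrow(object@segments),
              max(object@segments$x_hi)))
  s <- object@segments
  for (i in seq_len(nrow(s)))
    cat(sprintf("  [%.3g, %.3g): %.4g x^2 + %.4g x + %.4g\n",
                s$x_lo[i], s$x_hi[i], s$a[i], s$b[i], s$c[i]))
})

setMethod("show", "ParameterSet", function(object) {
  cat("ParameterSet\n")
  print(round(as.data.frame(object), 2), row.names = FALSE)
})

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf("SceneConfig <%s>: %d x %d px over %.3g mm, noise %s (%g), seed %d\n",
              object@archetype, object@heightPx, object@widthPx,
              object@lateralExtent, object@noiseModel, object@noiseScale,
              object@seed))
})

setMethod("show", "AssessmentReport", function(object) {
  cat(sprintf("AssessmentReport: %s (severity %s), |k - 1| = %.3f\n",
              object@verdict, object@severity, object@kDeviation))
  if (length(object@evidence))
    cat("  evidence:", paste(object@evidence, collapse = ", "), "\n")
})
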