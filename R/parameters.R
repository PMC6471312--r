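## The parameter family of a reflectivity graph and its analytic model.

#' Extremes of the averaged graph, computed analytically
#'
#' Global minimum and maximum of the piecewise model over its domain,
#' obtained from segment vertices (where they fall inside their interval)
#' and interval endpoints — no sampling involved.
#'
#' @param model a [PiecewiseModel-class].
#' @return named numeric `c(rho_min = , rho_max = )`.
#' @export
graphExtremes <- function(model) {
  s <- model@segments
  vals <- numeric(0)
  for (i in seq_len(nrow(s))) {
    xs <- c(s$x_lo[i], s$x_hi[i])
    if (s$a[i] != 0) {
      xv <- -s$b[i] / (2 * s$a[i])
      if (xv > s$x_lo[i] && xv < s$x_hi[i]) xs <- c(xs, xv)
    }
    vals <- c(vals, s$a[i] * xs^2 + s$b[i] * xs + s$c[i])
  }
  c(rho_min = min(vals), rho_max = max(vals))
}

#' Extremes of the raw-profile envelope
#'
#' The envelope extremes additionally carry the small high-spatial-
#' frequency variations of the reflectivity: they are the minimum and
#' maximum of the unsmoothed profile.
#'
#' @param raw a raw [ReflectivityProfile-class].
#' @return named numeric `c(rho_min_peak = , rho_max_peak = )`.
#' @export
envelopeExtremes <- function(raw) {
  c(rho_min_peak = min(raw@rho), rho_max_peak = max(raw@rho))
}

#' Scalar reflectivity parameters
#'
#' `deltaRho` and `deltaRhoPeak` are the differences `rho_max - rho_min`
#' of the averaged graph and of the raw envelope; `ratioK` and
#' `ratioKPeak` the corresponding ratios `rho_max / rho_min`. The ratio of
#' the averaged-graph extremes, `k`, is close to 1 for a normally fired
#' sample and drifts away as the sintering temperature drifts from the
#' prescribed one — it is the study's headline calibration indicator.
#'
#' @param rhoMax,rhoMin extremes (gray levels), `rhoMax >= rhoMin >= 0`;
#'   ratios additionally require `rhoMin > 0`.
#' @return a single number.
#' @export
deltaRho <- function(rhoMax, rhoMin) {
  if (any(rhoMin < 0) || any(rhoMax < rhoMin))
    stop("need rho_max >= rho_min >= 0")
  rhoMax - rhoMin
}

#' @rdname deltaRho
#' @export
deltaRhoPeak <- function(rhoMax, rhoMin) deltaRho(rhoMax, rhoMin)

#' @rdname deltaRho
#' @export
ratioK <- function(rhoMax, rhoMin) {
  if (any(rhoMin <= 0)) stop("k undefined: rho_min must be > 0")
  if (any(rhoMax < rhoMin)) stop("need rho_max >= rho_min")
  rhoMax / rhoMin
}

#' @rdname deltaRho
#' @export
ratioKPeak <- function(rhoMax, rhoMin) ratioK(rhoMax, rhoMin)

#' Maximum absolute gradient and curvature of a model
#'
#' The derivative of each segment is affine, so its absolute maximum over
#' the closed interval is attained at an endpoint; `maxGradient` is the
#' maximum of `|2 a x + b|` over all segment endpoints (gray levels/mm).
#' `maxCurvature` is the maximum of `|2 a|` over segments (gray
#' levels/mm^2).
#'
#' @param model a [PiecewiseModel-class].
#' @return a single nonnegative number.
#' @export
maxGradient <- function(model) {
  s <- model@segments
  max(abs(2 * s$a * s$x_lo + s$b), abs(2 * s$a * s$x_hi + s$b))
}

#' @rdname maxGradient
#' @export
maxCurvature <- function(model) {
  max(abs(2 * model@segments$a))
}

## ParameterSet of a bare model (envelope collapses onto the graph).
.paramsFromModel <- function(model) {
  ex <- graphExtremes(model)
  .makeParams(ex[["rho_min"]], ex[["rho_max"]],
              ex[["rho_min"]], ex[["rho_max"]], model)
}

.makeParams <- function(rhoMin, rhoMax, rhoMinPeak, rhoMaxPeak, model) {
  dr <- deltaRho(rhoMax, rhoMin)
  new("ParameterSet",
      rhoMin = rhoMin, rhoMax = rhoMax,
      rhoMinPeak = rhoMinPeak, rhoMaxPeak = rhoMaxPeak,
      deltaRho = dr, deltaRhoPeak = deltaRhoPeak(rhoMaxPeak, rhoMinPeak),
      k = if (rhoMin > 0) ratioK(rhoMax, rhoMin) else NA_real_,
      kPeak = if (rhoMinPeak > 0) ratioKPeak(rhoMaxPeak, rhoMinPeak)
              else NA_real_,
      gradMax = maxGradient(model), curvMax = maxCurvature(model),
      meanLevel = .modelMean(model))
}

#' Compute the full parameter set of a sample
#'
#' Combines the raw profile (envelope extremes) with the fitted or
#' constructed analytic model. By default the averaged-graph extremes are
#' the model's analytic extremes, so the differences, ratios and
#' derivative maxima all refer to the same analytic object; set
#' `useModelExtremes = FALSE` to take them from a smoothed profile
#' instead.
#'
#' The envelope is widened to enclose the graph extremes where a fitted
#' model marginally over- or undershoots the raw data (the envelope is
#' defined to contain the averaged graph).
#'
#' @param raw the raw [ReflectivityProfile-class] of the sample.
#' @param model the sample's [PiecewiseModel-class].
#' @param useModelExtremes logical; see above.
#' @param smoothed smoothed profile, required when
#'   `useModelExtremes = FALSE`.
#' @return a [ParameterSet-class].
#' @export
computeParameters <- function(raw, model, useModelExtremes = TRUE,
                              smoothed = NULL) {
  env <- envelopeExtremes(raw)
  if (useModelExtremes) {
    ex <- graphExtremes(model)
  } else {
    if (is.null(smoothed)) stop("smoothed profile required")
    ex <- c(rho_min = min(smoothed@rho), rho_max = max(smoothed@rho))
  }
  .makeParams(ex[["rho_min"]], ex[["rho_max"]],
              min(env[["rho_min_peak"]], ex[["rho_min"]] + 0.5),
              max(env[["rho_max_peak"]], ex[["rho_max"]] - 0.5),
      model)
}

#' Tabulate parameter sets for several samples
#'
#' One row per labelled sample with all parameter columns, rounded to two
#' decimals to mirror the published table layout (internal computation is
#' full precision).
#'
#' @param entries list of `list(label = , raw = , model = )` entries.
#' @return data.frame with columns `label`, `rho_min_peak`,
#'   `rho_max_peak`, `delta_rho_peak`, `k_peak`, `rho_min`, `rho_max`,
#'   `delta_rho`, `k`, `grad_max`, `curv_max`, `mean_level`.
#' @export
parameterTable <- function(entries) {
  if (!length(entries)) stop("need at least one entry")
  rows <- lapply(entries, function(e) {
    ps <- computeParameters(e$raw, e$model)
    cbind(data.frame(label = e$label),
          round(as.data.frame(ps), 2))
  })
  do.call(rbind, rows)
}

#' Regenerate the study's parameter tables from built-in fixtures
#'
#' For each study group the published envelope and averaged-graph extremes
#' (see [publishedGroupStats()]) give the differences and ratios, while
#' the derivative maxima come from the group's analytic table model
#' (`groupAnchors(group, "table")`). Cells are rounded to two decimals.
#'
#' @return data.frame with one row per group: `group`, `material`,
#'   `delta_rho_peak`, `k_peak`, `delta_rho`, `k`, `grad_max`, `curv_max`.
#' @export
reproduceTables <- function() {
  stats <- publishedGroupStats()
  rows <- lapply(seq_len(nrow(stats)), function(i) {
    g <- stats$group[i]
    ga <- groupAnchors(g, purpose = "table")
    model <- buildModel(ga$archetype, ga$anchors)
    data.frame(
      group = g, material = stats$material[i],
      rho_min_peak = stats$rho_min_peak[i],
      rho_max_peak = stats$rho_max_peak[i],
      delta_rho_peak = round(
        deltaRhoPeak(stats$rho_max_peak[i], stats$rho_min_peak[i]), 2),
      k_peak = round(
        ratioKPeak(stats$rho_max_peak[i], stats$rho_min_peak[i]), 2),
      rho_min = stats$rho_min[i], rho_max = stats$rho_max[i],
      delta_rho = round(deltaRho(stats$rho_max[i], stats$rho_min[i]), 2),
      k = round(ratioK(stats$rho_max[i], stats$rho_min[i]), 2),
      grad_max = round(maxGradient(model), 2),
      curv_max = round(maxCurvature(model), 2),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
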