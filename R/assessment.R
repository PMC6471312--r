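## Rule-based firing-temperature verdict and parameter consistency ranking.

#' Threshold configuration for the sintering verdict
#'
#' Every cut is an engineering default, explicitly surfaced (and echoed in
#' each report) rather than a claim of the underlying study:
#'
#' * `normal_band`: a sample is called normal when `|k - 1|` does not
#'   exceed this band (default 0.45 — wide enough to admit the normally
#'   fired groups of both materials, k = 1.25/1.42 pressed and 1.00
#'   metal, while rejecting the strongly deviated groups, k >= 1.59).
#' * `severe_band`: `|k - 1|` beyond this (default 1.0) marks a severe
#'   deviation.
#' * `low_level_cut`, `high_level_cut`: relative mean-level cuts against
#'   `reference_level` (the normal-group mean of the same material);
#'   defaults 0.88 and 1.10 — under-firing depresses backscatter by over
#'   12% in the study groups, over-firing raises the average level.
#' * `tilt_slope_min`: minimum positive end-to-end slope (gray
#'   levels/mm) of an essentially linear graph to count as tilted
#'   (default 1); a tilted graph is the signature of a strongly
#'   over-fired sample and forces an over-fired, severe verdict.
#' * `tilt_dev_frac`: maximum deviation of the model from the straight
#'   chord between its endpoints, as a fraction of the end-to-end rise,
#'   still compatible with "essentially linear" (default 0.35; banded or
#'   valley-shaped graphs deviate by multiples of their rise).
#' * `reference_level`: mean reflectivity of a normally fired sample of
#'   the same material (gray levels), needed by the relative cuts;
#'   `cut_mode = "absolute"` interprets the cuts as gray levels instead.
#'
#' @param normal_band,severe_band bands on `|k - 1|`.
#' @param low_level_cut,high_level_cut mean-level cuts (relative factors,
#'   or gray levels when `cut_mode = "absolute"`).
#' @param tilt_slope_min gray levels/mm.
#' @param tilt_dev_frac fraction of the rise.
#' @param reference_level gray levels, or `NA` when unknown.
#' @param cut_mode `"relative"` or `"absolute"`.
#' @return named list of thresholds.
#' @export
assessThresholds <- function(normal_band = 0.45, severe_band = 1.0,
                             low_level_cut = 0.88, high_level_cut = 1.10,
                             tilt_slope_min = 1.0, tilt_dev_frac = 0.35,
                             reference_level = NA_real_,
                             cut_mode = c("relative", "absolute")) {
  list(normal_band = normal_band, severe_band = severe_band,
       low_level_cut = low_level_cut, high_level_cut = high_level_cut,
       tilt_slope_min = tilt_slope_min, tilt_dev_frac = tilt_dev_frac,
       reference_level = reference_level,
       cut_mode = match.arg(cut_mode))
}

#' Assess oven calibration from a sample's parameters and model
#'
#' Encodes the study's multi-parametric findings as an explicit verdict:
#'
#' 1. A tilted graph — essentially linear (deviating from the straight
#'    chord between its endpoints by at most `tilt_dev_frac` of the
#'    rise) and rising by at least `tilt_slope_min` gray levels per mm
#'    end to end — is the
#'    signature of a much-higher-than-normal sintering temperature:
#'    over-fired, severe, regardless of `k`. The rule is shape-based
#'    rather than archetype-label-based so it also fires when a noisy
#'    ramp was fitted by a more flexible archetype.
#' 2. Otherwise the sample is normal iff `|k - 1| <= normal_band`.
#' 3. Otherwise the direction is decided by evidence, structural cues
#'    first: banded alternation (oscillation archetype) or a rising
#'    linear graph are over-firing signatures and dominate; failing
#'    those, a mean level below the low cut points to under-firing
#'    (incompletely sintered, weakly backscattering ceramic) and one
#'    above the high cut to over-firing. Absent evidence gives
#'    `indeterminate`.
#'
#' Severity is `severe` when `|k - 1| > severe_band` (or on tilt), else
#' `mild`; `n/a` for normal samples.
#'
#' @param params the sample's [ParameterSet-class].
#' @param model the sample's [PiecewiseModel-class] (same sample).
#' @param config threshold list from [assessThresholds()]; relative
#'   mean-level cuts require `reference_level`.
#' @return an [AssessmentReport-class].
#' @export
assess <- function(params, model, config = assessThresholds()) {
  k <- params@k
  kdev <- abs(k - 1)
  xmax <- modelDomain(model)
  rise <- evaluateModel(model, xmax) - evaluateModel(model, 0)
  flags <- character(0)
  if (params@deltaRho <= 0.5 || model@archetype == "flat")
    flags <- c(flags, "flat_graph")
  ## "essentially linear and rising": positive end-to-end slope and only
  ## a small deviation from the straight chord between the endpoints
  grid <- seq(0, xmax, length.out = 201L)
  chordDev <- max(abs(evaluateModel(model, grid) -
                        (evaluateModel(model, 0) + rise * grid / xmax)))
  tilted <- rise >= config$tilt_slope_min * xmax &&
    chordDev <= config$tilt_dev_frac * rise
  if (tilted) flags <- c(flags, "tilted_linear_graph")
  banded <- model@archetype == "oscillation" && params@deltaRho > 0.5
  if (banded) flags <- c(flags, "banded_alternation")

  meanFlag <- function(which) {
    if (config$cut_mode == "relative") {
      if (is.na(config$reference_level))
        stop("relative mean-level cuts requested but no reference_level ",
             "configured")
      cut <- config$reference_level *
        config[[paste0(which, "_level_cut")]]
    } else cut <- config[[paste0(which, "_level_cut")]]
    if (which == "low") params@meanLevel < cut else params@meanLevel > cut
  }

  if (tilted) {
    verdict <- "over_fired"; severity <- "severe"
  } else if (kdev <= config$normal_band) {
    verdict <- "normal"; severity <- "n/a"
  } else {
    lowFlag <- meanFlag("low")
    highFlag <- meanFlag("high")
    if (lowFlag) flags <- c(flags, "low_mean_level")
    if (highFlag) flags <- c(flags, "high_mean_level")
    overStruct <- banded ||
      (model@archetype == "linear_ramp" && rise > 0)
    verdict <- if (overStruct) "over_fired"
      else if (lowFlag) "under_fired"
      else if (highFlag) "over_fired"
      else "indeterminate"
    severity <- if (kdev > config$severe_band) "severe" else "mild"
  }
  new("AssessmentReport", verdict = verdict, severity = severity,
      kDeviation = kdev, evidence = flags, thresholds = config)
}

#' Rank parameters by monotonic consistency with temperature offset
#'
#' For each cohort (material) and each parameter, computes a Kendall-style
#' signed concordance between the parameter value and the absolute
#' temperature offset over all group pairs with distinct `|offset|`
#' (number of concordant minus discordant pairs, over the number of
#' compared pairs), then averages across cohorts. Parameters are returned
#' in decreasing order of mean concordance; ties break alphabetically.
#'
#' @param tables list of cohorts; each a data.frame with an `offset`
#'   column (temperature offset, C) plus one numeric column per
#'   parameter.
#' @param parameters which parameter columns to rank (default: all
#'   numeric columns except `offset`).
#' @return data.frame ordered by rank with columns `parameter` and
#'   `concordance`.
#' @export
rankByConsistency <- function(tables, parameters = NULL) {
  if (length(tables) < 2L)
    stop("need at least two cohorts with labeled temperature offsets")
  if (is.null(parameters)) {
    nums <- names(tables[[1L]])[vapply(tables[[1L]], is.numeric,
                                       logical(1L))]
    parameters <- setdiff(nums, "offset")
  }
  conc1 <- function(v, off) {
    pairs <- utils::combn(length(v), 2L)
    d_off <- abs(off[pairs[1L, ]]) - abs(off[pairs[2L, ]])
    keep <- d_off != 0
    if (!any(keep)) return(NA_real_)
    d_v <- v[pairs[1L, keep]] - v[pairs[2L, keep]]
    sum(sign(d_v) * sign(d_off[keep])) / sum(keep)
  }
  scores <- vapply(parameters, function(p) {
    mean(vapply(tables, function(tb) conc1(tb[[p]], tb$offset),
                numeric(1L)), na.rm = TRUE)
  }, numeric(1L))
  ord <- order(-scores, parameters)
  data.frame(parameter = parameters[ord], concordance = scores[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarize a set of assessments
#'
#' Produces a human-readable block per sample plus a JSON-ready list, and
#' an exit status: 0 when every verdict is normal, 1 otherwise (so shell
#' pipelines can gate on calibration).
#'
#' @param assessments named list of [AssessmentReport-class] objects.
#' @return list with `text` (character vector), `json` (list) and
#'   `status` (integer 0/1).
#' @export
assessmentSummary <- function(assessments) {
  if (!length(assessments)) stop("no assessments to summarize")
  labs <- names(assessments)
  if (is.null(labs)) labs <- paste0("sample", seq_along(assessments))
  text <- mapply(function(lab, a) {
    sprintf("%s: %s (severity %s), |k-1| = %.3f%s", lab, a@verdict,
            a@severity, a@kDeviation,
            if (length(a@evidence))
              paste0(" [", paste(a@evidence, collapse = ", "), "]")
            else "")
  }, labs, assessments)
  json <- lapply(assessments, function(a)
    list(verdict = a@verdict, severity = a@severity,
         k_deviation = a@kDeviation, evidence = as.list(a@evidence),
         thresholds = a@thresholds))
  names(json) <- labs
  status <- as.integer(any(vapply(assessments, function(a)
    a@verdict != "normal", logical(1L))))
  list(text = unname(text), json = json, status = status)
}
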