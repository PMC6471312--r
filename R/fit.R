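## Least-squares fitting of the piecewise archetypes to a smoothed graph.

.NPARAMS <- c(flat = 1L, linear_ramp = 2L, oscillation = 2L,
              ramp_plateau = 3L, valley = 4L, hump_valley = 6L)

.lsfit0 <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  co <- fit$coefficients
  co[is.na(co)] <- 0
  list(coef = co, sse = sum((y - X %*% co)^2))
}

## Unit three-lobe oscillation shape on [0, xmax]: level 0 at 0, T, 2T and
## xmax; lobes reach -1, +1, -1 at the mid-thirds.
.oscShape <- function(x, xmax) {
  T3 <- xmax / 3
  k <- pmin(floor(x / T3), 2)
  u <- (x - (k + 0.5) * T3) / (T3 / 2)
  sgn <- c(-1, 1, -1)[k + 1]
  sgn * (1 - u^2)
}

.fitGivenBreak <- function(x, y, archetype, br, xmax) {
  switch(archetype,
    flat = {
      f <- .lsfit0(matrix(1, length(x)), y)
      list(sse = f$sse,
           anchors = list(rho0 = f$coef[[1L]], x_max = xmax),
           segs = .seg(0, xmax, c(a = 0, b = 0, c = f$coef[[1L]])))
    },
    linear_ramp = {
      f <- .lsfit0(cbind(1, x), y)
      c0 <- f$coef[[1L]]; c1 <- f$coef[[2L]]
      list(sse = f$sse,
           anchors = list(rho0 = c0, rho_max = c0 + c1 * xmax,
                          x_max = xmax),
           segs = .seg(0, xmax, c(a = 0, b = c1, c = c0)))
    },
    oscillation = {
      s <- .oscShape(x, xmax)
      f <- .lsfit0(cbind(1, s), y)
      r0 <- f$coef[[1L]]; A <- f$coef[[2L]]
      m <- buildModel("oscillation",
                      list(rho0 = r0, A = A, x_max = xmax))
      list(sse = f$sse, anchors = m@anchors, segs = m@segments)
    },
    ramp_plateau = {
      b1 <- ifelse(x < br, (1 - x / br)^2, 0)
      f <- .lsfit0(cbind(1, b1), y)
      ri <- f$coef[[1L]]; r0 <- ri + f$coef[[2L]]
      fc <- parabolaPointVertex(c(0, r0), c(br, ri))
      list(sse = f$sse,
           anchors = list(rho0 = r0, x_i = br, rho_i = ri, x_max = xmax),
           segs = rbind(.seg(0, br, fc),
                        .seg(br, xmax, c(a = 0, b = 0, c = ri))))
    },
    valley = {
      left <- x < br
      b0 <- ifelse(left, (1 - x / br)^2, 0)
      bM <- ifelse(left, 0, ((x - br) / (xmax - br))^2)
      f <- .lsfit0(cbind(1 - b0 - bM, b0, bM), y)
      rmin <- f$coef[[1L]]; r0 <- f$coef[[2L]]; rM <- f$coef[[3L]]
      list(sse = f$sse,
           anchors = list(rho0 = r0, x_m = br, rho_min = rmin,
                          x_max = xmax, rho_max = rM),
           segs = rbind(
             .seg(0, br, parabolaPointVertex(c(0, r0), c(br, rmin))),
             .seg(br, xmax,
                  parabolaPointVertex(c(xmax, rM), c(br, rmin)))))
    },
    hump_valley = {
      xp <- pmax(x - br, 0)
      f <- .lsfit0(cbind(1, x, x^2, xp, xp^2), y)
      cf <- f$coef
      af <- cf[[3L]]; bf <- cf[[2L]]; c0 <- cf[[1L]]
      ag <- af + cf[[5L]]
      bg <- bf + cf[[4L]] - 2 * cf[[5L]] * br
      cg <- c0 - cf[[4L]] * br + cf[[5L]] * br^2
      fAt <- function(z) af * z^2 + bf * z + c0
      gAt <- function(z) ag * z^2 + bg * z + cg
      xM <- if (abs(af) > 1e-12) -bf / (2 * af) else NA_real_
      xm <- if (abs(ag) > 1e-12) -bg / (2 * ag) else NA_real_
      list(sse = f$sse,
           anchors = list(rho0 = c0,
                          x_M = xM,
                          rho_M = if (is.na(xM)) NA_real_ else fAt(xM),
                          x_i = br, rho_i = fAt(br),
                          x_m = xm,
                          rho_m = if (is.na(xm)) NA_real_ else gAt(xm),
                          x_max = xmax),
           segs = rbind(.seg(0, br, c(a = af, b = bf, c = c0)),
                        .seg(br, xmax, c(a = ag, b = bg, c = cg))))
    })
}

#' Fit a piecewise archetype to a smoothed reflectivity graph
#'
#' Least-squares fit of the archetype's vertex-constrained piecewise form.
#' For a fixed interior breakpoint every archetype is linear in its
#' remaining parameters, so the fit is a nested least squares: an
#' exhaustive, deterministic search of the breakpoint over the profile
#' abscissae (optionally strided) with a closed-form solve at each
#' candidate. The oscillation archetype has its breakpoints fixed at
#' thirds of the domain; flat and linear archetypes need no search.
#'
#' @param profile a smoothed [ReflectivityProfile-class] with at least 8
#'   points (use [smoothProfile()] first).
#' @param archetype archetype name (see [buildModel()]).
#' @param breakStride integer stride over candidate breakpoints (1 =
#'   every abscissa); larger values trade resolution for speed.
#' @param xmax model domain end; defaults to the last abscissa.
#' @param edgeTrim number of samples to drop at each end before fitting
#'   (default 0). The shrinking smoothing window biases the first and
#'   last half-window samples wherever the graph has slope; trimming them
#'   lets the analytic segments extrapolate to the domain ends unbiased.
#' @return list with `model` ([PiecewiseModel-class]), `anchors` (list),
#'   `sse` (sum of squared residuals) and `nparams`.
#' @export
fitModel <- function(profile, archetype, breakStride = 1L,
                     xmax = max(profile@x), edgeTrim = 0L) {
  archetype <- match.arg(archetype, .ARCHETYPES)
  x <- profile@x; y <- profile@rho
  if (edgeTrim > 0L) {
    keep <- seq(edgeTrim + 1L, length(x) - edgeTrim)
    x <- x[keep]; y <- y[keep]
  }
  n <- length(x)
  if (n < 8L)
    stop("need at least 8 profile points to fit '", archetype, "'")
  best <- NULL
  if (archetype %in% c("flat", "linear_ramp", "oscillation")) {
    best <- .fitGivenBreak(x, y, archetype, NA, xmax)
  } else {
    cand <- x[seq(4L, n - 3L, by = max(1L, as.integer(breakStride)))]
    cand <- cand[cand > 0 & cand < xmax]
    for (br in cand) {
      f <- .fitGivenBreak(x, y, archetype, br, xmax)
      if (is.null(best) || f$sse < best$sse) best <- f
    }
  }
  model <- new("PiecewiseModel", segments = best$segs,
               archetype = archetype, anchors = best$anchors)
  list(model = model, anchors = best$anchors, sse = best$sse,
       nparams = .NPARAMS[[archetype]])
}

#' Choose the archetype that best explains a smoothed graph
#'
#' Fits every archetype and compares the parameter-count-penalized error
#' `sse * (1 + p / n)`; ties (including multiple exact fits) break toward
#' the archetype with fewer parameters.
#'
#' @param profile a smoothed [ReflectivityProfile-class].
#' @param breakStride,edgeTrim passed to [fitModel()].
#' @param details if `TRUE`, also return all fits and penalties.
#' @return the archetype name, or (with `details = TRUE`) a list with
#'   `archetype`, `fits` and `penalized`.
#' @export
selectArchetype <- function(profile, breakStride = 1L, edgeTrim = 0L,
                            details = FALSE) {
  n <- length(profile@x) - 2L * edgeTrim
  fits <- lapply(.ARCHETYPES, function(a)
    fitModel(profile, a, breakStride = breakStride, edgeTrim = edgeTrim))
  names(fits) <- .ARCHETYPES
  pen <- vapply(fits, function(f) f$sse * (1 + f$nparams / n), numeric(1L))
  p <- .NPARAMS[.ARCHETYPES]
  tied <- pen <= min(pen) * (1 + 1e-9) + 1e-9
  pick <- .ARCHETYPES[tied][which.min(p[tied])]
  if (details) list(archetype = pick, fits = fits, penalized = pen)
  else pick
}
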