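#' Parabola through a point with a prescribed vertex
#'
#' Returns the coefficients `(a, b, c)` of the unique parabola
#' `a x^2 + b x + c` that passes through `point` and has its stationary
#' point (vertex) at `vertex`:
#' `a = (rho - rho_v) / (x - x_v)^2`, `b = -2 a x_v`,
#' `c = rho_v + a x_v^2`.
#' This vertex-constrained construction is the building block of all
#' piecewise reflectivity models: each parabolic portion of an averaged
#' graph is pinned by one anchor point and one extremum.
#'
#' If `point` and `vertex` coincide in value at the same abscissa the
#' degenerate flat parabola (`a = b = 0`) is returned; a point above or
#' below its own vertex abscissa has no solution and is rejected.
#'
#' @param point numeric `c(x, rho)`: a point on the parabola.
#' @param vertex numeric `c(x_v, rho_v)`: the stationary point.
#' @return named numeric vector `c(a = , b = , c = )`.
#' @examples
#' parabolaPointVertex(c(0, 60), c(1.5, 35))   # a = 11.11, b = -33.33, c = 60
#' @export
parabolaPointVertex <- function(point, vertex) {
  stopifnot(length(point) == 2L, length(vertex) == 2L)
  x <- point[[1L]]; r <- point[[2L]]
  xv <- vertex[[1L]]; rv <- vertex[[2L]]
  if (isTRUE(all.equal(x, xv, tolerance = 1e-12))) {
    if (isTRUE(all.equal(r, rv, tolerance = 1e-12)))
      return(c(a = 0, b = 0, c = rv))
    stop("no parabola: point and vertex share abscissa x = ", x,
         " but differ in value")
  }
  a <- (r - rv) / (x - xv)^2
  c(a = a, b = -2 * a * xv, c = rv + a * xv^2)
}

.seg <- function(x_lo, x_hi, coef) {
  data.frame(x_lo = x_lo, x_hi = x_hi,
             a = coef[["a"]], b = coef[["b"]], c = coef[["c"]])
}

.needAnchors <- function(anchors, syms, archetype) {
  missing <- syms[!vapply(syms, function(s)
    !is.null(anchors[[s]]) && is.finite(anchors[[s]]), logical(1L))]
  if (length(missing))
    stop("incomplete anchors for archetype '", archetype, "': missing ",
         paste(missing, collapse = ", "))
}

#' Build a piecewise analytic reflectivity model from anchors
#'
#' Constructs the archetype's segments geometrically from anchor points and
#' vertices (see [parabolaPointVertex()]), not from any printed polynomial:
#'
#' \describe{
#'   \item{valley}{parabola through `(0, rho0)` with vertex
#'     `(x_m, rho_min)`, then a parabola sharing that vertex through
#'     `(x_max, rho_max)`. Anchors: `rho0, x_m, rho_min, x_max, rho_max`.}
#'   \item{hump_valley}{parabola through `(0, rho0)` with vertex
#'     `(x_M, rho_M)` on `[0, x_i)`; then a parabola with its own vertex
#'     `(x_m, rho_m)` matching the first at `x_i` (continuity). When the
#'     first vertex sits at the origin (`x_M = 0`), the through-point is
#'     `(x_i, rho_i)` instead and `rho_i` is required.}
#'   \item{ramp_plateau}{parabola through `(0, rho0)` with vertex
#'     `(x_i, rho_i)`, then the constant plateau `rho_i`.}
#'   \item{oscillation}{three parabolic lobes on thirds of `[0, x_max]`
#'     with common level `rho0` at the breakpoints and amplitude `A`:
#'     down to `rho0 - A`, up to `rho0 + A`, down again. Anchors:
#'     `rho0, A, x_max`.}
#'   \item{linear_ramp}{the line from `(0, rho0)` to `(x_max, rho_max)`.}
#'   \item{flat}{the constant `rho0` on `[0, x_max]`.}
#' }
#'
#' @param archetype one of the archetype names above.
#' @param anchors named list of anchor values (mm and gray levels).
#' @return a [PiecewiseModel-class].
#' @examples
#' m <- buildModel("valley", list(rho0 = 60, x_m = 1.5, rho_min = 35,
#'                                x_max = 3.25, rho_max = 82))
#' evaluateModel(m, c(0, 1.5, 3.25))
#' @export
buildModel <- function(archetype, anchors) {
  archetype <- match.arg(archetype, .ARCHETYPES)
  a <- anchors
  segs <- switch(archetype,
    flat = {
      .needAnchors(a, c("rho0", "x_max"), archetype)
      .seg(0, a$x_max, c(a = 0, b = 0, c = a$rho0))
    },
    linear_ramp = {
      .needAnchors(a, c("rho0", "rho_max", "x_max"), archetype)
      .seg(0, a$x_max,
           c(a = 0, b = (a$rho_max - a$rho0) / a$x_max, c = a$rho0))
    },
    valley = {
      .needAnchors(a, c("rho0", "x_m", "rho_min", "x_max", "rho_max"),
                   archetype)
      stopifnot(a$x_m > 0, a$x_m < a$x_max)
      f <- parabolaPointVertex(c(0, a$rho0), c(a$x_m, a$rho_min))
      g <- parabolaPointVertex(c(a$x_max, a$rho_max), c(a$x_m, a$rho_min))
      rbind(.seg(0, a$x_m, f), .seg(a$x_m, a$x_max, g))
    },
    ramp_plateau = {
      .needAnchors(a, c("rho0", "x_i", "rho_i", "x_max"), archetype)
      stopifnot(a$x_i > 0, a$x_i < a$x_max)
      f <- parabolaPointVertex(c(0, a$rho0), c(a$x_i, a$rho_i))
      rbind(.seg(0, a$x_i, f),
            .seg(a$x_i, a$x_max, c(a = 0, b = 0, c = a$rho_i)))
    },
    hump_valley = {
      .needAnchors(a, c("rho0", "x_M", "rho_M", "x_i", "x_m", "rho_m",
                        "x_max"), archetype)
      stopifnot(a$x_i > 0, a$x_i < a$x_max)
      f <- if (a$x_M > 1e-9) {
        parabolaPointVertex(c(0, a$rho0), c(a$x_M, a$rho_M))
      } else {
        .needAnchors(a, "rho_i", archetype)
        parabolaPointVertex(c(a$x_i, a$rho_i), c(0, a$rho0))
      }
      fi <- f[["a"]] * a$x_i^2 + f[["b"]] * a$x_i + f[["c"]]
      g <- parabolaPointVertex(c(a$x_i, fi), c(a$x_m, a$rho_m))
      rbind(.seg(0, a$x_i, f), .seg(a$x_i, a$x_max, g))
    },
    oscillation = {
      .needAnchors(a, c("rho0", "A", "x_max"), archetype)
      T3 <- a$x_max / 3
      lobe <- function(k, sign) {
        v <- c((k + 0.5) * T3, a$rho0 + sign * a$A)
        parabolaPointVertex(c(k * T3, a$rho0), v)
      }
      rbind(.seg(0, T3, lobe(0, -1)),
            .seg(T3, 2 * T3, lobe(1, +1)),
            .seg(2 * T3, a$x_max, lobe(2, -1)))
    })
  new("PiecewiseModel", segments = segs, archetype = archetype,
      anchors = a)
}

.segmentIndex <- function(model, x) {
  s <- model@segments
  xmax <- s$x_hi[nrow(s)]
  if (any(x < -1e-9 | x > xmax + 1e-9))
    stop("x outside model domain [0, ", xmax, "]")
  x <- pmin(pmax(x, 0), xmax)
  pmin(findInterval(x, s$x_lo), nrow(s))
}

#' Evaluate a piecewise model and its derivatives
#'
#' `evaluateModel` returns the reflectivity of the segment containing each
#' `x`; `modelGradient` its first derivative `2 a x + b` (gray levels per
#' mm); `modelCurvature` its second derivative `2 a` (gray levels per
#' mm^2). Intervals are half-open `[x_lo, x_hi)`, the last closed at
#' `x_max`.
#'
#' @param model a [PiecewiseModel-class].
#' @param x positions in mm, inside `[0, x_max]`.
#' @return numeric vector of the same length as `x`.
#' @export
evaluateModel <- function(model, x) {
  i <- .segmentIndex(model, x)
  s <- model@segments
  s$a[i] * x^2 + s$b[i] * x + s$c[i]
}

#' @rdname evaluateModel
#' @export
modelGradient <- function(model, x) {
  i <- .segmentIndex(model, x)
  s <- model@segments
  2 * s$a[i] * x + s$b[i]
}

#' @rdname evaluateModel
#' @export
modelCurvature <- function(model, x) {
  i <- .segmentIndex(model, x)
  2 * model@segments$a[i]
}

#' @describeIn evaluateModel domain end `x_max` of a model (mm).
#' @export
modelDomain <- function(model) {
  model@segments$x_hi[nrow(model@segments)]
}

## Analytic mean of the model over [0, x_max] (exact segment integrals).
.modelMean <- function(model) {
  s <- model@segments
  ints <- s$a / 3 * (s$x_hi^3 - s$x_lo^3) +
    s$b / 2 * (s$x_hi^2 - s$x_lo^2) + s$c * (s$x_hi - s$x_lo)
  sum(ints) / modelDomain(model)
}
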