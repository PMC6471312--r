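#' Construct an EnFaceImage from a pixel matrix
#'
#' @param pixels numeric matrix of gray levels in `[0, 255]` (rows = y,
#'   columns = x).
#' @param extentX,extentY lateral extents in mm (default 3.25 mm square,
#'   the study's field of view).
#' @return an [EnFaceImage-class].
#' @export
EnFaceImage <- function(pixels, extentX = 3.25, extentY = 3.25) {
  new("EnFaceImage", pixels = pixels, extentX = extentX, extentY = extentY)
}

#' Orient an image so reflectivity bands run parallel to the y axis
#'
#' The quantification convention requires the dark/light bands of deviated
#' firings to be parallel to the y axis (so that the y-averaged profile
#' resolves them along x). If the banding runs along x instead — detected
#' as the variance of row means exceeding the variance of column means —
#' the image is rotated by 90 degrees. Flat images are returned unchanged
#' (ties break as "no rotation").
#'
#' @param image an [EnFaceImage-class].
#' @return an [EnFaceImage-class] in the reference orientation.
#' @export
orientBands <- function(image) {
  p <- image@pixels
  if (stats::var(rowMeans(p)) > stats::var(colMeans(p))) {
    ## rotate 90 degrees counterclockwise: former rows become columns
    p2 <- t(p)[ncol(p):1, , drop = FALSE]
    return(new("EnFaceImage", pixels = p2,
               extentX = image@extentY, extentY = image@extentX))
  }
  image
}

#' Binarize an en-face image at a gray threshold
#'
#' A pixel becomes 1 (white) iff its gray value is strictly above the
#' threshold, else 0 — the default threshold is 127, so an all-127 image
#' binarizes to all zeros.
#'
#' @param image an [EnFaceImage-class].
#' @param threshold gray level in `[0, 255]`.
#' @return a [BinaryImage-class].
#' @export
binarize <- function(image, threshold = 127) {
  if (length(threshold) != 1L || threshold < 0 || threshold > 255)
    stop("threshold must be a single gray level in [0, 255]")
  new("BinaryImage",
      pixels = (image@pixels > threshold) + 0,
      threshold = threshold)
}

#' Count white features (8-connected components) in a binary image
#'
#' The white features of the binarized en-face image quantify the
#' granulation. Two white pixels belong to the same feature when they
#' share an edge or a corner (8-connectivity). Components are counted by
#' building the pixel-adjacency graph and counting its connected
#' components.
#'
#' @param binary a [BinaryImage-class].
#' @return integer: number of white features.
#' @export
countGrains <- function(binary) {
  p <- binary@pixels
  idx <- which(p == 1)
  if (!length(idx)) return(0L)
  nr <- nrow(p)
  on <- matrix(FALSE, nrow(p), ncol(p)); on[idx] <- TRUE
  edges <- integer(0)
  ## shifts to the 4 forward neighbors (E, S, SE, SW); the symmetric ones
  ## are implied in an undirected graph
  for (sh in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))) {
    di <- sh[1L]; dj <- sh[2L]
    ri <- seq_len(nrow(p)); ci <- seq_len(ncol(p))
    ri0 <- ri[ri + di >= 1L & ri + di <= nrow(p)]
    ci0 <- ci[ci + dj >= 1L & ci + dj <= ncol(p)]
    a <- on[ri0, ci0, drop = FALSE] & on[ri0 + di, ci0 + dj, drop = FALSE]
    w <- which(a, arr.ind = TRUE)
    if (nrow(w)) {
      i1 <- ri0[w[, 1L]] + nr * (ci0[w[, 2L]] - 1L)
      i2 <- (ri0[w[, 1L]] + di) + nr * (ci0[w[, 2L]] + dj - 1L)
      edges <- c(edges, rbind(match(i1, idx), match(i2, idx)))
    }
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  as.integer(igraph::count_components(g))
}

#' Extract the raw reflectivity profile of an en-face image
#'
#' Averages all image lines (y positions) to give reflectivity as a
#' function of the x position: `rho[j]` is the mean of column `j`, at the
#' pixel-center abscissa `x[j] = (j - 0.5) * extentX / ncol` in mm.
#'
#' @param image an oriented [EnFaceImage-class] (see [orientBands()]).
#' @return a raw [ReflectivityProfile-class].
#' @export
extractProfile <- function(image) {
  p <- image@pixels
  new("ReflectivityProfile",
      x = (seq_len(ncol(p)) - 0.5) * image@extentX / ncol(p),
      rho = colMeans(p), kind = "raw")
}

#' Default smoothing window for a profile
#'
#' 5% of the profile length, rounded to the nearest odd integer (at least
#' 1) — wide enough to suppress the grain-scale envelope oscillations
#' while preserving the band-scale shape of the averaged graph.
#'
#' @param n number of profile points.
#' @return odd integer window length.
#' @export
defaultSmoothWindow <- function(n) {
  max(1L, 2L * round((0.05 * n - 1) / 2) + 1L)
}

#' Smooth a reflectivity profile into the averaged graph
#'
#' Centered moving average with edge truncation: near the boundaries the
#' window shrinks to the available samples, so the domain is preserved.
#' The result is the averaged graph rho(x) that the piecewise models are
#' fitted to.
#'
#' @param profile a raw [ReflectivityProfile-class].
#' @param window odd integer window length (default [defaultSmoothWindow()]).
#' @return a smoothed [ReflectivityProfile-class] on the same abscissae.
#' @export
smoothProfile <- function(profile, window = defaultSmoothWindow(length(profile@x))) {
  if (window < 1L || window %% 2L == 0L)
    stop("window must be a positive odd integer")
  n <- length(profile@rho)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, profile@rho))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  new("ReflectivityProfile", x = profile@x, rho = sm, kind = "smoothed")
}

#' Convert a depth measured in air to depth inside the material
#'
#' OCT ranges are measured as optical path in air; inside a medium of
#' refractive index `n` the geometric depth is `z_air / n` (e.g. an axial
#' range of 3.75 mm in air is 2.5 mm inside ceramic with n = 1.5).
#'
#' @param zAir depth or range measured in air (mm, `>= 0`).
#' @param n refractive index (`>= 1`).
#' @return geometric depth in mm.
#' @export
airToMaterialDepth <- function(zAir, n) {
  if (any(n < 1)) stop("refractive index must be >= 1")
  if (any(zAir < 0)) stop("depth must be >= 0")
  zAir / n
}
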