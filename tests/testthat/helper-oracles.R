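# Independent oracles and generators used across the test files.

# Brute-force 8-connected component count by stack-based flood fill.
floodFillCount <- function(m) {
  visited <- matrix(FALSE, nrow(m), ncol(m))
  count <- 0L
  for (i0 in seq_len(nrow(m))) for (j0 in seq_len(ncol(m))) {
    if (m[i0, j0] != 1 || visited[i0, j0]) next
    count <- count + 1L
    stack <- list(c(i0, j0)); visited[i0, j0] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        i <- p[1L] + di; j <- p[2L] + dj
        if (i >= 1 && i <= nrow(m) && j >= 1 && j <= ncol(m) &&
            m[i, j] == 1 && !visited[i, j]) {
          visited[i, j] <- TRUE
          stack[[length(stack) + 1L]] <- c(i, j)
        }
      }
    }
  }
  count
}

# Numeric maximum |d rho/dx|: dense per-segment grids with central
# differences inside and second-order one-sided differences at the
# segment ends (exact for quadratics, hence a tight oracle).
numericGradMax <- function(model) {
  s <- modelSegments(model)
  gmax <- 0
  for (i in seq_len(nrow(s))) {
    xs <- seq(s$x_lo[i], s$x_hi[i], length.out = 201L)
    ys <- s$a[i] * xs^2 + s$b[i] * xs + s$c[i]
    dx <- xs[2L] - xs[1L]
    d <- c((-3 * ys[1L] + 4 * ys[2L] - ys[3L]) / (2 * dx),
           (ys[-(1:2)] - ys[-(length(ys) - 1:0)]) / (2 * dx),
           (3 * ys[length(ys)] - 4 * ys[length(ys) - 1L] +
              ys[length(ys) - 2L]) / (2 * dx))
    gmax <- max(gmax, abs(d))
  }
  gmax
}

profileFromModel <- function(model, x, kind = "smoothed") {
  new("ReflectivityProfile", x = x, rho = evaluateModel(model, x),
      kind = kind)
}

# Random well-posed anchor sets per archetype; breakpoints restricted to
# the sampling grid so the exhaustive breakpoint search can recover them
# exactly. Rejection-samples until the built model stays inside the
# 8-bit gray range.
randomAnchorSet <- function(archetype, xgrid) {
  repeat {
    a <- .randomAnchorSet1(archetype, xgrid)
    ex <- graphExtremes(buildModel(archetype, a))
    if (ex[["rho_min"]] >= 0 && ex[["rho_max"]] <= 255) return(a)
  }
}

.randomAnchorSet1 <- function(archetype, xgrid) {
  xmax <- max(xgrid)
  gridPick <- function(lofrac, hifrac) {
    cand <- xgrid[xgrid >= lofrac * xmax & xgrid <= hifrac * xmax]
    sample(cand, 1L)
  }
  switch(archetype,
    flat = list(rho0 = runif(1, 20, 200), x_max = xmax),
    linear_ramp = {
      r0 <- runif(1, 20, 120)
      list(rho0 = r0, rho_max = r0 + runif(1, 5, 100), x_max = xmax)
    },
    oscillation = list(rho0 = runif(1, 60, 150), A = runif(1, 5, 40),
                       x_max = xmax),
    valley = {
      rmin <- runif(1, 10, 80)
      list(rho0 = rmin + runif(1, 5, 80), x_m = gridPick(0.2, 0.8),
           rho_min = rmin, x_max = xmax,
           rho_max = rmin + runif(1, 5, 120))
    },
    ramp_plateau = {
      ri <- runif(1, 20, 100)
      list(rho0 = ri + runif(1, 5, 80), x_i = gridPick(0.2, 0.8),
           rho_i = ri, x_max = xmax)
    },
    hump_valley = {
      xi <- gridPick(0.3, 0.7)
      r0 <- runif(1, 40, 120)
      list(rho0 = r0, x_M = runif(1, 0.15 * xi, 0.85 * xi),
           rho_M = r0 + runif(1, 10, 60), x_i = xi,
           x_m = runif(1, xi + 0.15 * (xmax - xi),
                       xmax - 0.15 * (xmax - xi)),
           rho_m = r0 - runif(1, 10, 60), x_max = xmax)
    })
}
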