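# Shared numeric helpers (internal).

# Trapezoidal integral over a (possibly descending) axis; returns the area
# with the orientation of increasing ppm.
.trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  a <- sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  if (x[1] > x[length(x)]) -a else a
}

#' Lorentzian line shape parameterised by total area
#'
#' `area/pi * gamma / ((x - center)^2 + gamma^2)`, with `gamma` the half width
#' at half maximum; the full integral over the real line equals `area`.
#'
#' @param x evaluation points (ppm)
#' @param center peak position (ppm)
#' @param gamma half width at half maximum (ppm)
#' @param area total analytic area (intensity x ppm)
#' @return intensities at `x`
#' @export
lorentzianPpm <- function(x, center, gamma, area) {
  (area / pi) * gamma / ((x - center)^2 + gamma^2)
}

# Fraction of a Lorentzian's total area falling inside [lo, hi].
.lorentzWindowFraction <- function(center, gamma, lo, hi) {
  (atan((hi - center) / gamma) - atan((lo - center) / gamma)) / pi
}

# Normalize a window to (low, high) and return the axis indices inside it,
# plus the exact window-edge samples (linear interpolation) so trapezoidal
# integrals cover precisely the requested width regardless of the grid.
.windowIndices <- function(spectrum, window) {
  w <- sort(as.numeric(window))
  pp <- spectrum@ppm
  if (w[1] < min(pp) || w[2] > max(pp))
    stop(sprintf("integration window [%.4f, %.4f] outside spectral range [%.4f, %.4f]",
                 w[1], w[2], min(pp), max(pp)), call. = FALSE)
  idx <- which(pp >= w[1] & pp <= w[2])
  if (length(idx) < 2)
    stop("integration window contains fewer than 2 points", call. = FALSE)
  y <- spectrum@intensities
  x_in <- pp[idx]
  y_in <- y[idx]
  edge <- if (is.complex(y)) {
    function(at) complex(real = stats::approx(rev(pp), rev(Re(y)), at)$y,
                         imaginary = stats::approx(rev(pp), rev(Im(y)), at)$y)
  } else {
    function(at) stats::approx(rev(pp), rev(y), at)$y
  }
  x_edge <- c(w[2], x_in, w[1])
  y_edge <- c(edge(w[2]), y_in, edge(w[1]))
  keep <- !duplicated(x_edge)
  list(window = w, idx = idx, x = x_edge[keep], y = y_edge[keep])
}

# Smooth flat-topped band used for the fatty-acid matrix interference:
# cosine ramp [x0,x1], flat 1 on [x1,x2], cosine ramp down [x2,x3].
.flatTopBand <- function(x, x0 = 2.80, x1 = 2.90, x2 = 3.20, x3 = 3.30) {
  y <- numeric(length(x))
  up <- x > x0 & x < x1
  y[up] <- 0.5 * (1 - cos(pi * (x[up] - x0) / (x1 - x0)))
  y[x >= x1 & x <= x2] <- 1
  dn <- x > x2 & x < x3
  y[dn] <- 0.5 * (1 + cos(pi * (x[dn] - x2) / (x3 - x2)))
  y
}

# Local seed guard: set the RNG seed if non-NULL, restoring the caller's
# stream on exit so simulation calls compose predictably.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}
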