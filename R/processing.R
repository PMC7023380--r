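#' Exponential apodization of an FID
#'
#' Multiplies the FID by `exp(-pi * lb_hz * t)`, which broadens every spectral
#' line by `lb_hz` Hz. The first point (t = 0) is unchanged.
#'
#' @param fid a [FID-class] object
#' @param lb_hz line broadening in Hz (>= 0); defaults to the LB stored in the
#'   acquisition parameters
#' @return a [FID-class] object of the same length
#' @export
apodizeExponential <- function(fid, lb_hz = fid@params@lb_hz) {
  if (!is.finite(lb_hz) || lb_hz < 0)
    stop("lb_hz must be >= 0", call. = FALSE)
  tt <- (seq_along(fid@values) - 1) * fid@dwell_s
  new("FID", values = fid@values * exp(-pi * lb_hz * tt),
      dwell_s = fid@dwell_s, params = fid@params)
}

#' Fourier transform an FID into a (complex) spectrum
#'
#' Zero-fills the FID to `zero_fill_to` points, halves the first time-domain
#' point (the standard DC-offset correction for a discretely sampled decay),
#' applies the discrete Fourier transform, scales by the dwell time so that
#' spectral integrals over Hz approximate the continuous transform, and
#' arranges the result on a descending ppm axis about `center_ppm`.
#'
#' The returned spectrum is complex; run [phaseCorrect()] to obtain real
#' absorption-mode intensities.
#'
#' @param fid a [FID-class] object
#' @param zero_fill_to spectrum size (>= number of FID points); defaults to SI
#' @param center_ppm chemical shift of the window centre
#' @return a complex [NMRSpectrum-class] of length `zero_fill_to`
#' @export
transformToSpectrum <- function(fid, zero_fill_to = fid@params@si,
                                center_ppm = 6.175) {
  n <- length(fid@values)
  if (!is.finite(zero_fill_to) || zero_fill_to < n)
    stop("zero_fill_to must be at least the number of FID points", call. = FALSE)
  v <- fid@values
  v[1] <- v[1] / 2
  s <- stats::fft(c(v, rep(0 + 0i, zero_fill_to - n))) * fid@dwell_s
  sw <- fid@params@sw_hz
  freq <- (seq_len(zero_fill_to) - 1) / zero_fill_to * sw
  freq[freq >= sw / 2] <- freq[freq >= sw / 2] - sw
  ppm <- center_ppm + freq / fid@params@sfo_mhz
  ord <- order(ppm, decreasing = TRUE)
  params <- fid@params
  params@si <- zero_fill_to
  new("NMRSpectrum", intensities = s[ord], ppm = ppm[ord], params = params,
      label = "", meta = list(center_ppm = center_ppm))
}

.applyPhase <- function(values, phi0, phi1) {
  frac <- (seq_along(values) - 1) / (length(values) - 1) - 0.5
  values * exp(1i * (phi0 + phi1 * frac))
}

#' Automatic phase correction
#'
#' Chooses zero- and first-order phases by minimising the integrated squared
#' negative intensity of the real part (an absorption-mode spectrum has no
#' large negative lobes), via a coarse grid followed by Nelder-Mead
#' refinement. Real input is returned unchanged (already phased).
#'
#' @param spectrum an [NMRSpectrum-class]; complex for an actual correction
#' @return an [NMRSpectrum-class] with real intensities; the applied phases
#'   (degrees) are stored in `@meta$phase0_deg` / `@meta$phase1_deg`
#' @export
phaseCorrect <- function(spectrum) {
  v <- spectrum@intensities
  if (!is.complex(v)) {
    spectrum@meta$phase0_deg <- 0
    spectrum@meta$phase1_deg <- 0
    return(spectrum)
  }
  scale <- sum(Mod(v)^2)
  obj <- function(phi) {
    r <- Re(.applyPhase(v, phi[1], phi[2]))
    sum(pmin(r, 0)^2) / scale
  }
  grid <- expand.grid(phi0 = seq(-pi, pi, length.out = 25),
                      phi1 = seq(-pi, pi, length.out = 13))
  vals <- apply(grid, 1, obj)
  start <- as.numeric(grid[which.min(vals), ])
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 500))
  spectrum@intensities <- Re(.applyPhase(v, fit$par[1], fit$par[2]))
  spectrum@meta$phase0_deg <- fit$par[1] * 180 / pi
  spectrum@meta$phase1_deg <- fit$par[2] * 180 / pi
  spectrum
}

#' Automatic baseline correction
#'
#' Asymmetric least squares: a stiff second-difference-penalised smooth curve
#' is fitted with weights that iteratively favour points below the current
#' estimate, so the curve tracks the signal-free baseline and ignores peaks.
#' The estimate is subtracted from the spectrum.
#'
#' @param spectrum an [NMRSpectrum-class] with real intensities
#' @param lambda smoothness penalty (larger = stiffer baseline)
#' @param p asymmetry: weight of points above the baseline estimate
#' @param maxit reweighting iterations
#' @return the baseline-corrected [NMRSpectrum-class]
#' @export
baselineCorrect <- function(spectrum, lambda = 1e8, p = 0.001, maxit = 10) {
  y <- spectrum@intensities
  if (is.complex(y))
    stop("baseline correction expects a phased, real spectrum", call. = FALSE)
  n <- length(y)
  if (n < 10)
    stop("spectrum shorter than the minimum baseline window (10 points)",
         call. = FALSE)
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  P <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (i in seq_len(maxit)) {
    W <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(W + P, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (all(w_new == w)) break
    w <- w_new
  }
  spectrum@intensities <- y - z
  spectrum@meta$baseline <- list(lambda = lambda, p = p, iterations = i)
  spectrum
}

#' Full processing chain from FID to corrected spectrum
#'
#' Exponential apodization, zero-filled Fourier transform, automatic phase
#' correction, and automatic baseline correction -- the standard 1D
#' processing sequence.
#'
#' @inheritParams apodizeExponential
#' @inheritParams transformToSpectrum
#' @param baseline apply baseline correction? (simulated spectra are already
#'   flat; the step mainly matters for measured data)
#' @param ... passed on to [baselineCorrect()]
#' @return a processed real [NMRSpectrum-class]
#' @export
processSpectrum <- function(fid, lb_hz = fid@params@lb_hz,
                            zero_fill_to = fid@params@si, center_ppm = 6.175,
                            baseline = TRUE, ...) {
  sp <- transformToSpectrum(apodizeExponential(fid, lb_hz), zero_fill_to,
                            center_ppm)
  sp <- phaseCorrect(sp)
  if (baseline) sp <- baselineCorrect(sp, ...)
  sp
}
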