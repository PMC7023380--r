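#' Construct acquisition parameters
#'
#' Builds an [AcquisitionParameters-class] object, deriving the spectrometer
#' frequency from the Hz/ppm pair and the acquisition time from TD and SW
#' when these are not given.
#'
#' @param td time-domain points
#' @param sw_hz spectral width in Hz
#' @param sw_ppm spectral width in ppm
#' @param sfo_mhz spectrometer proton frequency in MHz; default `sw_hz/sw_ppm`
#' @param ns,ds scans and dummy scans
#' @param d1_s relaxation delay, s
#' @param aq_s acquisition time, s; default `td/(2*sw_hz)`
#' @param si real spectrum size
#' @param rg receiver gain
#' @param temp_k temperature, K
#' @param lb_hz exponential line broadening, Hz
#' @param device device label
#' @return an [AcquisitionParameters-class] object
#' @examples
#' p <- acquisitionParameters(td = 131072, sw_hz = 8223.68, sw_ppm = 20.5503)
#' acquisitionTime(p)
#' @export
acquisitionParameters <- function(td = 131072, sw_hz = 8223.68,
                                  sw_ppm = 20.5503, sfo_mhz = sw_hz / sw_ppm,
                                  ns = 64, ds = 2, d1_s = 30,
                                  aq_s = td / (2 * sw_hz), si = 262144,
                                  rg = 45.2, temp_k = 300.0, lb_hz = 0.30,
                                  device = "UltraShield") {
  if (!is.finite(sw_hz) || sw_hz <= 0)
    stop("sw_hz must be a positive number", call. = FALSE)
  if (!is.finite(td) || td <= 0)
    stop("td must be a positive number", call. = FALSE)
  new("AcquisitionParameters",
      td = td, sw_hz = sw_hz, sw_ppm = sw_ppm, sfo_mhz = sfo_mhz, ns = ns,
      ds = ds, d1_s = d1_s, aq_s = aq_s, si = si, rg = rg, temp_k = temp_k,
      lb_hz = lb_hz, device = device)
}

#' Device presets for the two 400 MHz spectrometers
#'
#' Acquisition dialects for the two instruments the method runs on: the
#' UltraShield (SW 20.5503 ppm / 8223.68 Hz) and the Ascend
#' (20.5617 ppm / 8223.69 Hz). Both use TD 131072, SI 262144, NS 64, DS 2,
#' D1 30 s, RG 45.2, 300.0 K, LB 0.30 Hz. `td` and `si` may be overridden,
#' e.g. for reduced simulation grids.
#'
#' @param device `"UltraShield"` or `"Ascend"`
#' @param td,si optional overrides of time-domain points / spectrum size
#' @return an [AcquisitionParameters-class] object
#' @export
devicePreset <- function(device = c("UltraShield", "Ascend"),
                         td = 131072, si = 262144) {
  device <- match.arg(device)
  if (device == "UltraShield")
    acquisitionParameters(td = td, sw_hz = 8223.68, sw_ppm = 20.5503,
                          si = si, device = device)
  else
    acquisitionParameters(td = td, sw_hz = 8223.69, sw_ppm = 20.5617,
                          si = si, device = device)
}

#' @rdname acquisitionTime
#' @export
setMethod("acquisitionTime", "AcquisitionParameters", function(x) {
  if (x@sw_hz <= 0) stop("spectral width must be positive", call. = FALSE)
  x@td / (2 * x@sw_hz)
})

#' @rdname acquisitionTime
#' @export
setMethod("acquisitionTime", "FID", function(x) acquisitionTime(x@params))

#' @rdname acquisitionTime
#' @export
setMethod("acquisitionTime", "NMRSpectrum", function(x) acquisitionTime(x@params))

#' Construct a descending ppm axis
#'
#' Returns `si` equally spaced chemical-shift values covering the spectral
#' width, descending (NMR convention). The spacing is `sw_ppm/si`; points sit
#' at bin midpoints, so the first-minus-last span equals
#' `sw_ppm * (si - 1)/si`.
#'
#' @param params an [AcquisitionParameters-class] object
#' @param center_ppm chemical shift at the window centre (transmitter offset);
#'   default 6.175 ppm places TMS (0 ppm) and the aldehyde region (9.7 ppm)
#'   inside the window
#' @return numeric vector of length `params@si`, strictly decreasing
#' @export
buildPpmAxis <- function(params, center_ppm = 6.175) {
  si <- params@si
  if (!is.finite(si) || si < 2) stop("si must be >= 2", call. = FALSE)
  if (params@sfo_mhz <= 0 || params@sw_ppm <= 0)
    stop("spectral width and carrier frequency must be positive", call. = FALSE)
  dppm <- params@sw_ppm / si
  center_ppm + params@sw_ppm / 2 - (seq_len(si) - 0.5) * dppm
}

setMethod("show", "AcquisitionParameters", function(object) {
  cat(sprintf("AcquisitionParameters [%s]\n", object@device))
  cat(sprintf("  TD %d  SW %.4f ppm (%.2f Hz)  SFO %.3f MHz  SI %d\n",
              as.integer(object@td), object@sw_ppm, object@sw_hz,
              object@sfo_mhz, as.integer(object@si)))
  cat(sprintf("  NS %d  DS %d  D1 %.1f s  AQ %.2f s  RG %.1f  %.1f K  LB %.2f Hz\n",
              as.integer(object@ns), as.integer(object@ds), object@d1_s,
              object@aq_s, object@rg, object@temp_k, object@lb_hz))
})

setMethod("show", "NMRSpectrum", function(object) {
  rng <- range(object@ppm)
  cat(sprintf("NMRSpectrum '%s': %d points, %.3f .. %.3f ppm (%s)\n",
              if (length(object@label)) object@label else "",
              length(object@ppm), rng[2], rng[1],
              if (is.complex(object@intensities)) "complex" else "real"))
})

setMethod("show", "FID", function(object) {
  cat(sprintf("FID: %d complex points, dwell %.3g s, AQ %.2f s [%s]\n",
              length(object@values), object@dwell_s,
              acquisitionTime(object), object@params@device))
})

#' @rdname NMRSpectrum-class
#' @export
setMethod("ppmAxis", "NMRSpectrum", function(x) x@ppm)

#' @rdname NMRSpectrum-class
#' @export
setMethod("intensities", "NMRSpectrum", function(x) x@intensities)

#' @rdname NMRSpectrum-class
#' @export
setMethod("acqParams", "NMRSpectrum", function(x) x@params)

#' @rdname NMRSpectrum-class
#' @export
setMethod("acqParams", "FID", function(x) x@params)

#' @rdname NMRSpectrum-class
#' @export
setMethod("sampleLabel", "NMRSpectrum", function(x) x@label)

#' Create an eretic calibration
#'
#' @param factor mol/L per unit proton-normalised area (must be > 0)
#' @param reference description of the quantification reference
#' @param device device preset label
#' @return an [EreticCalibration-class] object
#' @export
ereticCalibration <- function(factor, reference = "external quant reference",
                              device = "UltraShield") {
  new("EreticCalibration", factor = factor, reference = reference,
      device = device)
}
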