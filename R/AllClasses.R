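#' @import methods
#' @importFrom stats lm coef qt sd optim rnorm anova median approx
#' @importFrom utils head tail read.table write.table
NULL

setClassUnion("numeric_or_complex", c("numeric", "complex"))

#' Acquisition parameters of a 1D proton NMR experiment
#'
#' Bookkeeping for the pulse-program parameters that determine the time- and
#' frequency-domain grids: time-domain size (TD), spectral width (SW, in Hz
#' and ppm), spectrometer proton frequency, scan counts, relaxation delay,
#' acquisition time (AQ), real spectrum size (SI), receiver gain, temperature
#' and exponential line broadening (LB).
#'
#' Validity enforces the acquisition arithmetic: AQ = TD / (2 SW_Hz) within
#' 0.01 s, and SW_Hz = SW_ppm x carrier MHz within 0.1 Hz.
#'
#' @slot td time-domain points (TD)
#' @slot sw_hz spectral width in Hz
#' @slot sw_ppm spectral width in ppm
#' @slot sfo_mhz spectrometer proton frequency in MHz (implied by SW Hz/ppm)
#' @slot ns number of scans
#' @slot ds number of dummy scans
#' @slot d1_s relaxation delay in seconds
#' @slot aq_s acquisition time in seconds
#' @slot si real spectrum size after zero filling
#' @slot rg receiver gain
#' @slot temp_k sample temperature in kelvin
#' @slot lb_hz exponential line broadening in Hz
#' @slot device device label (free text)
#' @exportClass AcquisitionParameters
setClass("AcquisitionParameters",
  representation(
    td = "numeric", sw_hz = "numeric", sw_ppm = "numeric", sfo_mhz = "numeric",
    ns = "numeric", ds = "numeric", d1_s = "numeric", aq_s = "numeric",
    si = "numeric", rg = "numeric", temp_k = "numeric", lb_hz = "numeric",
    device = "character"
  )
)

setValidity("AcquisitionParameters", function(object) {
  msg <- character()
  pos <- c(td = object@td, sw_hz = object@sw_hz, sw_ppm = object@sw_ppm,
           sfo_mhz = object@sfo_mhz, ns = object@ns, si = object@si,
           temp_k = object@temp_k)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad))
    msg <- c(msg, paste0("nonpositive parameter(s): ", paste(bad, collapse = ", ")))
  if (object@lb_hz < 0) msg <- c(msg, "lb_hz must be >= 0")
  if (!length(msg)) {
    if (abs(object@aq_s - object@td / (2 * object@sw_hz)) > 0.01)
      msg <- c(msg, "aq_s inconsistent with td/(2*sw_hz) (tolerance 0.01 s)")
    if (abs(object@sw_hz - object@sw_ppm * object@sfo_mhz) > 0.1)
      msg <- c(msg, "sw_hz inconsistent with sw_ppm * sfo_mhz (tolerance 0.1 Hz)")
  }
  if (length(msg)) msg else TRUE
})

#' Free induction decay
#'
#' Complex time-domain signal, Bruker-like convention: TD/2 complex points,
#' dwell time 1/SW_Hz.
#'
#' @slot values complex FID points
#' @slot dwell_s dwell time in seconds per complex point
#' @slot params an [AcquisitionParameters-class] object
#' @exportClass FID
setClass("FID",
  representation(values = "complex", dwell_s = "numeric",
                 params = "AcquisitionParameters")
)

setValidity("FID", function(object) {
  msg <- character()
  if (length(object@values) != object@params@td / 2)
    msg <- c(msg, "length(values) must equal td/2 complex points")
  if (abs(object@dwell_s - 1 / object@params@sw_hz) > 1e-12)
    msg <- c(msg, "dwell_s must equal 1/sw_hz")
  if (length(msg)) msg else TRUE
})

#' One-dimensional NMR spectrum
#'
#' Frequency-domain intensities on a strictly descending ppm axis (standard
#' NMR display, high field right). Intensities are real after phasing; the
#' complex pre-phasing stage produced by [transformToSpectrum()] is carried in
#' the same class.
#'
#' @slot intensities real (or, pre-phasing, complex) intensity per point
#' @slot ppm chemical-shift axis, strictly monotonic decreasing
#' @slot params an [AcquisitionParameters-class] object
#' @slot label free-text sample identifier
#' @slot meta list of processing metadata (applied phases, baseline settings, ...)
#' @exportClass NMRSpectrum
setClass("NMRSpectrum",
  representation(intensities = "numeric_or_complex", ppm = "numeric",
                 params = "AcquisitionParameters", label = "character",
                 meta = "list")
)

setValidity("NMRSpectrum", function(object) {
  msg <- character()
  if (length(object@intensities) != length(object@ppm))
    msg <- c(msg, "intensities and ppm axis must have equal length")
  if (length(object@ppm) >= 2 && any(diff(object@ppm) >= 0))
    msg <- c(msg, "ppm axis must be strictly monotonic decreasing")
  if (length(msg)) msg else TRUE
})

#' Eretic (PULCON) calibration
#'
#' The single calibration degree of freedom of the quantification: the
#' proportionality constant converting a proton-normalised peak area
#' (intensity x ppm units) into molar concentration on a given spectrometer.
#'
#' @slot factor mol/L per unit of proton-normalised area
#' @slot reference free-text description of the quant reference used
#' @slot device device preset label the factor belongs to
#' @exportClass EreticCalibration
setClass("EreticCalibration",
  representation(factor = "numeric", reference = "character",
                 device = "character")
)

setValidity("EreticCalibration", function(object) {
  if (!is.finite(object@factor) || object@factor <= 0)
    "factor must be a positive number"
  else TRUE
})
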