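#' @rdname NMRSpectrum-class
#' @param x an object
#' @export
setGeneric("ppmAxis", function(x) standardGeneric("ppmAxis"))

#' @rdname NMRSpectrum-class
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname NMRSpectrum-class
#' @export
setGeneric("acqParams", function(x) standardGeneric("acqParams"))

#' @rdname NMRSpectrum-class
#' @export
setGeneric("sampleLabel", function(x) standardGeneric("sampleLabel"))

#' Acquisition time implied by the time-domain size and spectral width
#'
#' AQ = TD / (2 SW_Hz) seconds for the complex (TD/2-point) convention.
#'
#' @param x an [AcquisitionParameters-class], [FID-class] or
#'   [NMRSpectrum-class] object
#' @return acquisition time in seconds
#' @examples
#' acquisitionTime(devicePreset("UltraShield"))  # 7.97 s
#' @export
setGeneric("acquisitionTime", function(x) standardGeneric("acquisitionTime"))
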