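# Shared fixtures: reduced-size acquisition grids keep the suite fast while
# preserving the instrument's spectral width and carrier frequency.

deskParams <- function(si = 32768, td = 16384, device = "UltraShield") {
  devicePreset(device, td = td, si = si)
}

noiselessSettings <- function(...) {
  args <- utils::modifyList(list(noise_sd = 0, interference_amplitude = 0),
                            list(...))
  do.call(simulationSettings, args)
}

# A bare spectrum from explicit intensities on a desk-scale axis.
spectrumFromIntensities <- function(y, params = deskParams(si = length(y)),
                                    center_ppm = 6.175) {
  new("NMRSpectrum", intensities = y, ppm = buildPpmAxis(params, center_ppm),
      params = params, label = "fixture", meta = list())
}

# Closed-form area of a Lorentzian restricted to [lo, hi] (the trapezoid
# oracle's analytic counterpart).
lorentzPartialArea <- function(center, gamma, area, lo, hi) {
  area / pi * (atan((hi - center) / gamma) - atan((lo - center) / gamma))
}
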