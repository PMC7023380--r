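#' Simulation settings
#'
#' Conditions of the synthetic spectrometer. `response_factor` is the device
#' constant linking a proton-normalised molar concentration to peak area
#' (area units x ppm per mol/L per proton) -- the quantity the eretic factor
#' inverts. `caffeine_dissolved_fraction` models caffeine's restricted
#' solubility in CDCl3 (only this fraction of the nominal concentration
#' appears in solution; quantification undoes it with the empirical
#' recalculation factor 6, i.e. the default fraction is 1/6).
#'
#' @param noise_sd standard deviation of additive Gaussian spectral noise
#'   (intensity units)
#' @param interference_amplitude intensity of the broad fatty-acid matrix
#'   background spanning roughly 2.9-3.2 ppm
#' @param peak_fwhm_hz natural Lorentzian full width at half maximum, Hz;
#'   the line-broadening LB of the acquisition parameters is added on top
#' @param seed RNG seed (NULL: use the current stream)
#' @param device_preset `"UltraShield"` or `"Ascend"`
#' @param caffeine_dissolved_fraction fraction of nominal caffeine in solution
#' @param rel_area_noise relative (multiplicative) measurement noise on each
#'   analyte's peak area; scalar or named per-analyte vector
#' @param response_factor device constant (area x ppm per mol/L per proton)
#' @param tms_area area of the TMS reference singlet at 0 ppm
#' @return a list of settings (class `SimulationSettings`)
#' @export
simulationSettings <- function(noise_sd = 1.0, interference_amplitude = 0,
                               peak_fwhm_hz = 1.0, seed = NULL,
                               device_preset = c("UltraShield", "Ascend"),
                               caffeine_dissolved_fraction = 1 / 6,
                               rel_area_noise = 0, response_factor = 1e4,
                               tms_area = 20) {
  device_preset <- match.arg(device_preset)
  stopifnot(noise_sd >= 0, peak_fwhm_hz > 0,
            caffeine_dissolved_fraction > 0, caffeine_dissolved_fraction <= 1,
            interference_amplitude >= 0, response_factor > 0)
  structure(list(noise_sd = noise_sd,
                 interference_amplitude = interference_amplitude,
                 peak_fwhm_hz = peak_fwhm_hz, seed = seed,
                 device_preset = device_preset,
                 caffeine_dissolved_fraction = caffeine_dissolved_fraction,
                 rel_area_noise = rel_area_noise,
                 response_factor = response_factor, tms_area = tms_area),
            class = "SimulationSettings")
}

#' Eretic calibration matched to the simulator
#'
#' The simulator's response factor inverted -- the calibration a PULCON
#' reference measurement would deliver on the synthetic instrument.
#'
#' @param settings a [simulationSettings()] list
#' @return an [EreticCalibration-class]
#' @export
matchedEreticCalibration <- function(settings = simulationSettings()) {
  ereticCalibration(1 / settings$response_factor,
                    reference = "simulator response factor (inverted)",
                    device = settings$device_preset)
}

.relNoiseFor <- function(rel, analyte) {
  if (length(rel) == 1 && is.null(names(rel))) return(as.numeric(rel))
  if (!is.null(names(rel)) && analyte %in% names(rel)) return(as.numeric(rel[analyte]))
  0
}

#' Simulate a coffee-extract spectrum with known ground truth
#'
#' Each analyte contributes a Lorentzian at its `center_ppm` with analytic
#' area `response_factor * n_protons * c_mol`, where `c_mol` is the dissolved
#' molar concentration (`mg/L / (1000 * molar mass)`; caffeine is first
#' multiplied by the dissolved fraction). A TMS reference singlet sits at
#' 0 ppm. The fatty-acid matrix interference is a smooth flat-topped band
#' (flat across 2.90-3.20 ppm, cosine shoulders to 2.80/3.30), so it loads
#' the OMC window (3.125-3.185) and the reference window (3.04-3.10)
#' equally -- the property the interference correction relies on. Gaussian
#' noise of sd `noise_sd` is added pointwise.
#'
#' @param concentrations named numeric vector, nominal mg/L per analyte
#'   (missing analytes are 0)
#' @param analytes analyte table, see [coffeeAnalytes()]
#' @param settings a [simulationSettings()] list
#' @param params acquisition parameters; default the settings' device preset
#' @param center_ppm axis centre
#' @param area_scale named per-analyte multiplier on the signal area
#'   (extraction/matrix bias; default 1)
#' @param seed RNG seed override (default `settings$seed`)
#' @return a list with `spectrum` ([NMRSpectrum-class]) and `truth`
#'   (data.frame: analyte, nominal and dissolved mg/L, nominal and realized
#'   area)
#' @export
simulateSpectrum <- function(concentrations, analytes = coffeeAnalytes(),
                             settings = simulationSettings(),
                             params = devicePreset(settings$device_preset),
                             center_ppm = 6.175, area_scale = NULL,
                             seed = settings$seed) {
  conc <- stats::setNames(rep(0, nrow(analytes)), analytes$name)
  if (length(concentrations)) {
    if (is.null(names(concentrations)))
      stop("concentrations must be a named vector (mg/L per analyte)",
           call. = FALSE)
    unknown <- setdiff(names(concentrations), analytes$name)
    if (length(unknown))
      stop("unknown analyte(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    if (any(concentrations < 0))
      stop("concentrations must be >= 0", call. = FALSE)
    conc[names(concentrations)] <- concentrations
  }
  ppm <- buildPpmAxis(params, center_ppm)
  lo <- min(ppm); hi <- max(ppm)
  if (any(analytes$window_low < lo) || any(analytes$window_high > hi))
    stop("analyte window outside the simulated spectral range", call. = FALSE)
  gamma <- ((settings$peak_fwhm_hz + params@lb_hz) / 2) / params@sfo_mhz

  .withSeed(seed, {
    y <- numeric(length(ppm))
    truth <- analytes[, c("name", "center_ppm", "n_protons", "molar_mass_g_mol")]
    truth$conc_nominal_mg_L <- as.numeric(conc[truth$name])
    truth$conc_dissolved_mg_L <- truth$conc_nominal_mg_L *
      ifelse(truth$name == "caffeine", settings$caffeine_dissolved_fraction, 1)
    scale <- stats::setNames(rep(1, nrow(truth)), truth$name)
    if (!is.null(area_scale))
      scale[names(area_scale)] <- as.numeric(area_scale)
    truth$area_nominal <- settings$response_factor * truth$n_protons *
      truth$conc_dissolved_mg_L / (1000 * truth$molar_mass_g_mol) *
      as.numeric(scale[truth$name])
    truth$area_realized <- vapply(seq_len(nrow(truth)), function(i) {
      rel <- .relNoiseFor(settings$rel_area_noise, truth$name[i])
      if (rel > 0)
        truth$area_nominal[i] * max(0, 1 + stats::rnorm(1, 0, rel))
      else truth$area_nominal[i]
    }, numeric(1))
    for (i in seq_len(nrow(truth)))
      if (truth$area_realized[i] > 0)
        y <- y + lorentzianPpm(ppm, truth$center_ppm[i], gamma,
                               truth$area_realized[i])
    if (settings$tms_area > 0)
      y <- y + lorentzianPpm(ppm, 0, gamma, settings$tms_area)
    if (settings$interference_amplitude > 0)
      y <- y + settings$interference_amplitude * .flatTopBand(ppm)
    if (settings$noise_sd > 0)
      y <- y + stats::rnorm(length(y), 0, settings$noise_sd)
    sp <- new("NMRSpectrum", intensities = y, ppm = ppm, params = params,
              label = "simulated", meta = list(simulated = TRUE))
    list(spectrum = sp, truth = truth)
  })
}

#' Simulate a time-domain FID for a set of Lorentzian resonances
#'
#' Produces the complex FID whose processed spectrum (see
#' [processSpectrum()]) contains, for each row of `peaks`, a Lorentzian of
#' analytic area `area` (intensity x ppm) at `ppm` with natural full width
#' `fwhm_hz` (before line broadening). Used to exercise the processing chain
#' against known areas.
#'
#' @param peaks data.frame with columns `ppm`, `area`, `fwhm_hz`
#' @param params acquisition parameters (TD/2 complex points are generated)
#' @param center_ppm transmitter offset
#' @param phase0_deg,phase1_deg phase errors to inject (degrees)
#' @return a [FID-class]
#' @export
simulateFid <- function(peaks, params = devicePreset("UltraShield"),
                        center_ppm = 6.175, phase0_deg = 0, phase1_deg = 0) {
  n <- params@td / 2
  dwell <- 1 / params@sw_hz
  tt <- (0:(n - 1)) * dwell
  v <- complex(real = numeric(n), imaginary = numeric(n))
  for (i in seq_len(nrow(peaks))) {
    f0 <- (peaks$ppm[i] - center_ppm) * params@sfo_mhz
    # the absorption part of a one-sided FT carries half the time-domain
    # amplitude, hence the factor 2 to hit the target spectral area
    a <- 2 * peaks$area[i] * params@sfo_mhz
    v <- v + a * exp(2i * pi * f0 * tt - pi * peaks$fwhm_hz[i] * tt)
  }
  if (phase0_deg != 0 || phase1_deg != 0) {
    # a zero-order error is a constant rotation; first-order is emulated in
    # the frequency domain by the processing tests, here only phi0 applies
    v <- v * exp(1i * phase0_deg * pi / 180)
  }
  new("FID", values = v, dwell_s = dwell, params = params)
}

#' The ten-level dilution plan of the calibration series
#'
#' Reproduces the dilution matrix used to prepare the 1-1000 mg/L working
#' solutions in a constant total volume of 1500 uL: five analyte stocks plus
#' CDCl3 make-up, two blanks per series. Levels up to 100 mg/L are diluted
#' from the 1000 mg/L stocks, levels from 250 mg/L from the 5000 mg/L
#' stocks.
#'
#' @return data.frame with columns `target_mg_L`, `dilution_text`,
#'   `stock_mg_L`, `volume_per_stock_uL`, `volume_all_analytes_uL`,
#'   `volume_solvent_uL`, `blank`
#' @export
buildDilutionPlan <- function() {
  targets <- c(1, 5, 10, 25, 50, 100, 250, 500, 750, 1000)
  dil <- c("1:1000", "1:200", "1:100", "1:40", "1:20", "1:10",
           "1:20", "1:10", "1:6.66", "1:5")
  stock <- c(rep(1000, 6), rep(5000, 4))
  per_stock <- targets * 1500 / stock
  plan <- data.frame(
    target_mg_L = c(0, 0, targets),
    dilution_text = c("blank", "blank", dil),
    stock_mg_L = c(NA, NA, stock),
    volume_per_stock_uL = c(0, 0, per_stock),
    volume_all_analytes_uL = c(0, 0, 5 * per_stock),
    volume_solvent_uL = c(1500, 1500, 1500 - 5 * per_stock),
    blank = c(TRUE, TRUE, rep(FALSE, 10))
  )
  stopifnot(all(abs(plan$volume_all_analytes_uL + plan$volume_solvent_uL -
                      1500) < 1e-9))
  plan
}

#' The three-factor factorial validation design
#'
#' Six calibration series (arrays) crossing coffee type (100% arabica
#' decaffeinated, 100% robusta, green coffee) with shaking time (20 or
#' 10 min), each measured on both spectrometers; every series is the
#' ten-level dilution plan plus two blanks. Yields 72 test solutions, 144
#' measurements, 120 excluding blanks.
#'
#' @return a list of class `ValidationDesign` with elements `cells`
#'   (data.frame: array, device, coffee_type, shaking_min) and `plan`
#'   ([buildDilutionPlan()])
#' @export
buildValidationDesign <- function() {
  arrays <- data.frame(
    array = 1:6,
    coffee_type = rep(c("arabica_decaf", "robusta", "green"), 2),
    shaking_min = rep(c(20, 10), each = 3)
  )
  cells <- merge(arrays, data.frame(device = c("UltraShield", "Ascend")))
  cells <- cells[order(cells$array, cells$device),
                 c("array", "device", "coffee_type", "shaking_min")]
  rownames(cells) <- NULL
  structure(list(cells = cells, plan = buildDilutionPlan()),
            class = "ValidationDesign")
}

#' Counts implied by the validation design
#'
#' @param design a [buildValidationDesign()] object
#' @return named vector: `test_solutions` (prepared once per array),
#'   `measurements` (each solution on both devices),
#'   `measurements_excluding_blanks`
#' @export
designCounts <- function(design = buildValidationDesign()) {
  n_arrays <- length(unique(design$cells$array))
  n_devices <- length(unique(design$cells$device))
  per_series <- nrow(design$plan)
  n_blanks <- sum(design$plan$blank)
  solutions <- n_arrays * per_series
  measurements <- solutions * n_devices
  c(test_solutions = solutions, measurements = measurements,
    measurements_excluding_blanks = measurements -
      n_arrays * n_blanks * n_devices)
}

#' Matrix-effect presets per coffee type
#'
#' Emulation settings for the three validation matrices: per-analyte
#' extraction biases (measured over spiked) and relative measurement noise,
#' plus interference amplitude and spectral noise. Roasted matrices are
#' nearly unbiased with moderate noise; green (raw) coffee carries strong
#' analyte-specific biases and a much larger dispersion, which is what makes
#' its results indicative only. Kahweol in robusta is assigned a low
#' recovery and poor precision (its native content in that matrix is too low
#' for a precise determination). The spectrometer and, by default, the
#' shaking time have no systematic effect.
#'
#' @param coffee_type `"arabica_decaf"`, `"robusta"` or `"green"`
#' @param shaking_min 20 or 10
#' @param shaking10_bias multiplicative bias applied to all analytes at
#'   10 min shaking (default 1: no effect)
#' @return list with `bias` and `rel_noise` (named per analyte),
#'   `interference_amplitude`, `noise_sd`
#' @export
matrixPreset <- function(coffee_type = c("arabica_decaf", "robusta", "green"),
                         shaking_min = 20, shaking10_bias = 1) {
  coffee_type <- match.arg(coffee_type)
  an <- c("caffeine", "omc", "kahweol", "furfuryl_alcohol", "hmf")
  preset <- switch(coffee_type,
    arabica_decaf = list(
      bias = stats::setNames(c(1.01, 0.97, 0.95, 0.97, 1.02), an),
      rel_noise = stats::setNames(c(0.081, 0.065, 0.222, 0.061, 0.083), an),
      interference_amplitude = 5, noise_sd = 1),
    robusta = list(
      bias = stats::setNames(c(1.02, 1.01, 0.74, 0.99, 1.01), an),
      rel_noise = stats::setNames(c(0.074, 0.078, 0.327, 0.058, 0.069), an),
      interference_amplitude = 30, noise_sd = 1),
    green = list(
      bias = stats::setNames(c(1.37, 0.54, 1.88, 0.93, 1.07), an),
      rel_noise = stats::setNames(c(1.04, 1.88, 5.70, 0.25, 0.27), an),
      interference_amplitude = 30, noise_sd = 2)
  )
  if (shaking_min == 10) preset$bias <- preset$bias * shaking10_bias
  preset
}

#' Simulate the full factorial validation design
#'
#' Generates one spectrum per design measurement (12 series x 12 solutions =
#' 144 by default), applying the matrix presets of each cell, and returns the
#' spectra together with the ground-truth table the validation statistics
#' consume. Deterministic for a given seed.
#'
#' @param design a [buildValidationDesign()] object
#' @param analytes analyte table
#' @param settings base [simulationSettings()]; per-cell presets override
#'   interference, spectral noise, biases and relative noise
#' @param params acquisition parameters for the simulated spectra
#' @param seed RNG seed for the whole design
#' @param presets function `(coffee_type, shaking_min) -> preset`; default
#'   [matrixPreset()]
#' @param keep_spectra keep the spectrum objects (set `FALSE` to retain only
#'   the ground truth, e.g. when quantifying on the fly is not needed)
#' @return list of class `SimulatedDesign`: `spectra` (list, names =
#'   measurement ids), `truth` (data.frame: one row per measurement x
#'   analyte, with design factors, `target_mg_L`, `spiked_mg_kg`,
#'   `bias_applied`, `blank`)
#' @export
simulateDesign <- function(design = buildValidationDesign(),
                           analytes = coffeeAnalytes(),
                           settings = simulationSettings(),
                           params = devicePreset(settings$device_preset),
                           seed = settings$seed, presets = matrixPreset,
                           keep_spectra = TRUE) {
  known <- c("arabica_decaf", "robusta", "green")
  if (!all(design$cells$coffee_type %in% known))
    stop("unknown coffee type in design: ",
         paste(setdiff(design$cells$coffee_type, known), collapse = ", "),
         call. = FALSE)
  .withSeed(seed, {
    spectra <- list()
    rows <- list()
    for (ci in seq_len(nrow(design$cells))) {
      cell <- design$cells[ci, ]
      pre <- presets(cell$coffee_type, cell$shaking_min)
      s <- settings
      s$interference_amplitude <- pre$interference_amplitude
      s$noise_sd <- pre$noise_sd
      s$rel_area_noise <- pre$rel_noise
      s$device_preset <- cell$device
      s$seed <- NULL
      for (li in seq_len(nrow(design$plan))) {
        lev <- design$plan[li, ]
        id <- sprintf("a%d_%s_l%02d", cell$array, cell$device, li)
        conc <- stats::setNames(rep(lev$target_mg_L, nrow(analytes)),
                                analytes$name)
        sim <- simulateSpectrum(conc, analytes, s, params = params,
                                area_scale = pre$bias, seed = NULL)
        if (keep_spectra) spectra[[id]] <- sim$spectrum
        tr <- sim$truth
        rows[[id]] <- data.frame(
          id = id, array = cell$array, device = cell$device,
          coffee_type = cell$coffee_type, shaking_min = cell$shaking_min,
          level = li, target_mg_L = lev$target_mg_L, blank = lev$blank,
          analyte = tr$name, spiked_mg_kg = lev$target_mg_L * 7.5,
          bias_applied = as.numeric(pre$bias[tr$name]),
          area_realized = tr$area_realized,
          stringsAsFactors = FALSE
        )
      }
    }
    structure(list(spectra = spectra, truth = do.call(rbind, c(rows, list(
      make.row.names = FALSE)))), class = "SimulatedDesign")
  })
}
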