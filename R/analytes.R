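#' Analyte definitions for the coffee screening method
#'
#' Per-analyte constants: the ppm integration window of the characteristic
#' signal, the simulated resonance position inside it, the number of protons
#' contributing to the signal, the molar mass, the recalculation factor
#' applied to the measured solution concentration (6 for caffeine, reflecting
#' its restricted solubility in CDCl3 as established against an HPLC
#' reference; 1 otherwise), and the guidance value with the coffee
#' declaration it applies to.
#'
#' Windows: OMC 3.125-3.185, caffeine 3.38-3.44, kahweol 5.85-5.925, furfuryl
#' alcohol 7.39-7.411, HMF 9.67-9.69 ppm. Guidance values: OMC < 50 mg/kg in
#' declared 100% arabica, caffeine < 1000 mg/kg in decaffeinated coffee
#' (German coffee regulation), kahweol < 300 mg/kg in declared 100% robusta.
#'
#' @return a data.frame with one row per analyte and columns `name`,
#'   `window_low`, `window_high`, `center_ppm`, `n_protons`,
#'   `molar_mass_g_mol`, `recalculation_factor`, `guidance_value_mg_kg`,
#'   `guidance_scope`
#' @export
coffeeAnalytes <- function() {
  df <- data.frame(
    name = c("omc", "caffeine", "kahweol", "furfuryl_alcohol", "hmf"),
    window_low  = c(3.125, 3.38, 5.85, 7.39, 9.67),
    window_high = c(3.185, 3.44, 5.925, 7.411, 9.69),
    center_ppm  = c(3.155, 3.41, 5.8875, 7.4005, 9.68),
    n_protons   = c(3, 3, 1, 1, 1),
    molar_mass_g_mol = c(330.46, 194.19, 314.42, 98.10, 126.11),
    recalculation_factor = c(1, 6, 1, 1, 1),
    guidance_value_mg_kg = c(50, 1000, 300, NA, NA),
    guidance_scope = c("arabica_100", "decaffeinated", "robusta_100", NA, NA),
    stringsAsFactors = FALSE
  )
  stopifnot(all(df$window_low < df$window_high),
            all(df$center_ppm > df$window_low & df$center_ppm < df$window_high),
            all(df$n_protons >= 1))
  df
}

#' The interference reference window next to the OMC signal
#'
#' The 3.04-3.10 ppm range, equal in width (0.06 ppm) to the OMC window and
#' affected by the same broad fatty-acid matrix background, whose integral is
#' subtracted from the OMC window integral to avoid over-quantification.
#'
#' @return numeric `c(low, high)` in ppm
#' @export
omcNoiseWindow <- function() c(3.04, 3.10)
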