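#' Physical constants used throughout the package
#'
#' Faraday constant (C mol-1), molar gas constant (J mol-1 K-1), reference
#' temperature (K) and water density (kg m-3). All quantities in the package
#' are SI: concentrations in mol m-3 (numerically equal to mM), potentials in
#' V, pressures in Pa, lengths in m, volumes in m3, molar fluxes in
#' mol m-2 s-1.
#'
#' @format A named list with elements `F` (96485.332), `R` (8.314462),
#'   `Tref` (298.15) and `rho_w` (1000).
#' @export
sr_const <- list(
  F     = 96485.332,
  R     = 8.314462,
  Tref  = 298.15,
  rho_w = 1000
)

# RT/F at temperature T (V)
rtf <- function(T = sr_const$Tref) sr_const$R * T / sr_const$F

#' Convert pH to free proton concentration
#'
#' @param pH pH value.
#' @return Free H+ concentration in mol m-3 (`10^(-pH) * 1000`).
#' @export
ph_to_conc <- function(pH) 10^(-pH) * 1000

#' Convert free proton concentration to pH
#'
#' @param c Free H+ concentration in mol m-3.
#' @return pH value.
#' @export
conc_to_ph <- function(c) -log10(c / 1000)

#' Unit conversions for reported fluxes and contents
#'
#' The model computes fluxes in mol s-1 per kg fresh weight; experimental
#' sodium fluxes to the shoot are conventionally reported in
#' nmol min-1 g-1 FW. Contents are computed in mol per kg FW and reported
#' in umol g-1 FW (numerically equal to mmol kg-1).
#'
#' @param x Numeric vector of values to convert.
#' @return Converted numeric vector.
#' @examples
#' mol_s_kg_to_nmol_min_g(1e-6)  # 60
#' nmol_min_g_to_mol_s_kg(mol_s_kg_to_nmol_min_g(3.2e-7))  # round trip
#' @export
mol_s_kg_to_nmol_min_g <- function(x) x * 1e9 * 60 / 1e3

#' @rdname mol_s_kg_to_nmol_min_g
#' @export
nmol_min_g_to_mol_s_kg <- function(x) x / (1e9 * 60 / 1e3)

#' @rdname mol_s_kg_to_nmol_min_g
#' @export
mol_kg_to_umol_g <- function(x) x * 1e3

#' @rdname mol_s_kg_to_nmol_min_g
#' @export
umol_g_to_mol_kg <- function(x) x / 1e3
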