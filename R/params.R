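#' Default kinetic and water-transport parameters
#'
#' Returns the package's default parameter set. Channel permeabilities,
#' carrier-cycle rates and antiporter strengths are the package's fitted
#' defaults: they were calibrated with [two_stage_fit()] against the target
#' structure used for model optimization (root Na+/K+ content and epidermal
#' trans-membrane potential for the outer root; xylem ion concentrations and
#' the Na+ flux to the shoot for the stele), yielding resting epidermal
#' potentials near -120 mV, cytosolic pH near 7.2 and vacuolar pH near 5.5.
#' The plasma-membrane Na+/H+ antiporter strengths default to
#' 2e-7 m4 mol-1 s-1 in the outer tissues and 3e-7 m4 mol-1 s-1 in the
#' stele.
#'
#' Carrier-cycle rate vectors are in the order
#' `k12, k21, k23, k32, k34, k43, k41, k14`; `k12` (binding on the cis side)
#' and `k43` (binding on the trans side) are concentration-scaled and are
#' multiplied by the substrate product at evaluation time.
#'
#' @return A named list of parameters (SI units).
#' @export
default_params <- function() {
  list(
    T = sr_const$Tref,
    # --- plasma-membrane channels ---
    P_nscc = 3.5e-10,     # m/s, base Na=K permeability of VI NSCC
    K_Ca   = 0.3,         # mol/m3, half-block of NSCC by external Ca2+
    P_kir  = 1.5e-8,      # m/s, inward-rectifying K+ channel
    kir_Vhalf = -0.10, kir_slope = 0.012,
    P_kor  = 1e-8,        # m/s, outward-rectifying K+ channel
    kor_offset = 0.02, kor_slope = 0.015, K_cyt_ref = 100,
    P_hkt  = 5e-9,        # m/s, Na+-selective uniporter, mature stele
    P_anion_outer = 1e-10, # m/s, background anion channel, outer tissues
    P_anion_stele = 1e-8,  # m/s, anion channel on mature xylem parenchyma
    P_H_pm = 1e-5,        # m/s, background H+ permeability of plasma membranes
    P_H_ton = 3e-5,       # m/s, background H+ permeability of tonoplasts
    k_chx = 3e-7,         # m4/mol/s, plasma-membrane K+/H+ exchanger (CHX)
    # --- plasma-membrane pump and symporters (four-state carrier cycles) ---
    pump_rates = c(1e7, 100, 1000, 0.1, 1000, 1e4, 100, 20),
    pump_zt = 1, N_pump = 2e-8,
    khsym_rates = c(1e5, 100, 100, 100, 200, 1e3, 50, 50),
    khsym_zt = 2, N_khsym = 2e-9,
    clhsym_rates = c(1e6, 100, 100, 100, 200, 1e2, 50, 50),
    clhsym_zt = 1, N_clhsym = 5e-10,
    # --- plasma-membrane Na+/H+ antiporters (SOS1) ---
    k_ap_outer = 2e-7,    # m4/mol/s, epidermis/cortex/endodermis
    k_ap_stele = 1e-6,    # m4/mol/s, xylem parenchyma (+ apex xylem)
    sos1_residual_frac = 0.1,  # residual activity of the sos1 genotype
    # --- tonoplast ---
    vpump_rates = c(1e7, 100, 500, 0.1, 500, 1e4, 100, 20),
    vpump_zt = 1, N_vpump = 3e-9,
    P_ton_K = 1e-8, P_ton_Na = 5e-10, P_ton_Cl = 5e-10,
    k_nhx = 1e-7,         # tonoplast Na+/H+ antiporter, mature zone
    k_khton = 1e-8,       # tonoplast K+/H+ antiporter
    # --- water ---
    Lp_pm = 1.5e-13, sigma_pm = 0.95,
    Lp_ton = 1e-12, sigma_ton = 1.0,
    Lp_pd = 1e-10, sigma_pd = 0.1,
    k_h_wall = 1e-18,     # m2/Pa/s, apoplastic (wall) hydraulic permeability
    k_h_xylem = 1e-12,    # m2/Pa/s, open xylem conduit
    k_h_surface = 1e-16,  # m2/Pa/s, epidermis wall to medium
    # --- fixed charges, buffers, elasticity ---
    wall_charge = 0.5,    # mol/m3 fixed anionic charge in living-cell walls
    xylem_wall_charge = 0,
    B_cyt = 20, Kb_cyt = ph_to_conc(7.2),   # buffer pK at cytosolic pH
    B_vac = 20, Kb_vac = ph_to_conc(5.5),
    eps_cell = 5e6,       # Pa, volumetric elastic modulus of cells
    eps_wall = 1e8,       # Pa, effective compliance of apoplastic space
    P_turgor0 = 4e5,      # Pa, turgor at reference volume
    # --- diffusivities (free solution, m2/s) and tortuosities ---
    D_Na = 1.33e-9, D_K = 1.96e-9, D_Cl = 2.03e-9, D_H = 9.3e-9,
    tort_apo = 0.3, tort_pd = 0.1,
    # --- initial interior composition (mol/m3, pH) ---
    Na_cyt0 = 5, K_cyt0 = 100, Cl_cyt0 = 20, pH_cyt0 = 7.2,
    Na_vac0 = 10, K_vac0 = 80, Cl_vac0 = 30, pH_vac0 = 5.5
  )
}

#' Default transporter distribution over tissues and zones
#'
#' Which transporter family acts on which plasma membrane, mirroring the
#' literature-derived distribution the model assumes: H+ pumps, NSCC and
#' background anion channels on every living cell; K+ inward rectifiers and
#' K+/H+ and Cl-/2H+ symporters on the uptake tissues (epidermis, cortex);
#' K+ outward rectifiers on the epidermis and, in the mature zone, the
#' xylem parenchyma (xylem K+ loading); the Na+-selective uniporter
#' (HKT1;1-like) on mature xylem parenchyma; tonoplast Na+/H+ antiporters
#' in the mature zone only.
#'
#' @param antiporter_map Optional named logical specification of
#'   plasma-membrane Na+/H+ antiporter placement, as produced by
#'   [scenario_antiporter_map()]; default: all tissues, both zones
#'   (the wild-type optimization assumption).
#' @return A list of distribution rules consumed by [build_model()].
#' @export
default_distribution <- function(antiporter_map = NULL) {
  if (is.null(antiporter_map)) antiporter_map <- scenario_antiporter_map("all")
  list(
    pump   = list(tissues = sr_tissues, zones = c("apex", "mature")),
    nscc   = list(tissues = sr_tissues, zones = c("apex", "mature")),
    anion  = list(tissues = sr_tissues, zones = c("apex", "mature")),
    kir    = list(tissues = c("epidermis", "cortex"), zones = c("apex", "mature")),
    kor    = list(tissues = c("epidermis"), zones = c("apex", "mature"),
                  extra = list(tissues = "xylem_parenchyma", zones = "mature")),
    khsym  = list(tissues = c("epidermis", "cortex"), zones = c("apex", "mature")),
    clhsym = list(tissues = c("epidermis", "cortex"), zones = c("apex", "mature")),
    hkt    = list(tissues = "xylem_parenchyma", zones = "mature"),
    nhx    = list(zones = "mature"),
    antiporter_map = antiporter_map
  )
}

#' External-medium presets
#'
#' The four ionic media used for the experimental comparisons (one per data
#' source), plus the media of the scenario analyses. Concentrations in
#' mol m-3 (= mM); `Na` and `K` are the NaCl and KCl concentrations, so
#' `Cl = Na + K`.
#'
#' @param name Preset name, one of `"flux_content"` (50 NaCl, 11.9 KCl,
#'   0.5 Ca, pH 5.5), `"xylem"` (50, 2, 2, pH 4.4), `"content_100"`
#'   (100, 7.5, 0.8, pH 5.7), `"potentials"` (50, 0.5, 0.1, pH 5.5),
#'   `"cytosolic_100"` (100, 7.5, 0.5, pH 5.7), `"shoot_flux"`
#'   (50, 1.9, 0.5, pH 5.5), `"nacl_range"` (10, 1, 0.15, pH 5.0),
#'   `"efflux"` (10, 1, 0.25, pH 6.0).
#' @param NaCl Optional NaCl concentration override (mol m-3).
#' @return A `medium` list with elements `Na`, `K`, `Cl`, `Ca`, `pH`.
#' @export
medium_preset <- function(name = c("flux_content", "xylem", "content_100",
                                   "potentials", "cytosolic_100", "shoot_flux",
                                   "nacl_range", "efflux"),
                          NaCl = NULL) {
  name <- match.arg(name)
  m <- switch(name,
    flux_content  = list(Na = 50, K = 11.9, Ca = 0.5, pH = 5.5),
    xylem         = list(Na = 50, K = 2, Ca = 2, pH = 4.4),
    content_100   = list(Na = 100, K = 7.5, Ca = 0.8, pH = 5.7),
    potentials    = list(Na = 50, K = 0.5, Ca = 0.1, pH = 5.5),
    cytosolic_100 = list(Na = 100, K = 7.5, Ca = 0.5, pH = 5.7),
    shoot_flux    = list(Na = 50, K = 1.9, Ca = 0.5, pH = 5.5),
    nacl_range    = list(Na = 10, K = 1, Ca = 0.15, pH = 5.0),
    efflux        = list(Na = 10, K = 1, Ca = 0.25, pH = 6.0)
  )
  if (!is.null(NaCl)) m$Na <- NaCl
  m$Cl <- m$Na + m$K
  validate_medium(m)
}

#' Construct and validate an external medium
#'
#' @param Na,K NaCl and KCl concentrations (mol m-3).
#' @param Ca External Ca2+ (mol m-3); modifies NSCC permeability only.
#' @param pH Medium pH, must lie in (2, 9).
#' @param Cl Total Cl- (mol m-3); defaults to `Na + K`.
#' @return A validated `medium` list.
#' @export
make_medium <- function(Na, K, Ca, pH, Cl = Na + K) {
  validate_medium(list(Na = Na, K = K, Cl = Cl, Ca = Ca, pH = pH))
}

validate_medium <- function(m) {
  need <- c("Na", "K", "Cl", "Ca", "pH")
  if (!all(need %in% names(m)))
    stop("medium: must have fields ", paste(need, collapse = ", "))
  if (m$pH <= 2 || m$pH >= 9) stop("medium: pH must lie in (2, 9)")
  if (any(unlist(m[c("Na", "K", "Cl", "Ca")]) < 0))
    stop("medium: concentrations must be >= 0")
  m$H <- ph_to_conc(m$pH)
  m
}

#' Pre-salt variant of a medium
#'
#' Removes NaCl (leaving a trace 0.2 mol m-3 Na) and rebalances Cl.
#'
#' @param medium A medium list.
#' @param Na_trace Residual Na+ (mol m-3).
#' @return A validated pre-salt medium.
#' @export
presalt_medium <- function(medium, Na_trace = 0.2) {
  make_medium(Na = Na_trace, K = medium$K, Ca = medium$Ca, pH = medium$pH)
}
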