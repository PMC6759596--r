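#' Goldman-Hodgkin-Katz flux through an ion channel
#'
#' Constant-field flux for a single ion species across a membrane. The sign
#' convention throughout the package is that positive flux leaves the inner
#' compartment (efflux). `V` is the trans-membrane potential, inside minus
#' outside. At `V = 0` the analytic limit `P * (c_in - c_out)` is used; near
#' zero a first-order expansion keeps the flux continuous.
#'
#' @param P Permeability (m s-1), non-negative.
#' @param z Ion valence (integer).
#' @param V Trans-membrane potential (V), inside minus outside.
#' @param c_in,c_out Concentrations on the inner/outer face (mol m-3).
#' @param T Temperature (K).
#' @param open_p Optional open probability multiplier in `[0, 1]`.
#' @return Molar flux (mol m-2 s-1), positive = efflux. Vectorized over all
#'   arguments.
#' @examples
#' # zero flux at the Nernst potential
#' V_eq <- (8.314462 * 298.15 / 96485.332) * log(100 / 10)
#' ghk_flux(1e-9, 1, V_eq, 10, 100)
#' @export
ghk_flux <- function(P, z, V, c_in, c_out, T = sr_const$Tref, open_p = 1) {
  stopifnot(all(P >= 0), all(c_in >= -1e-12), all(c_out >= -1e-12), all(T > 0))
  u <- z * V / rtf(T)
  small <- abs(u) < 1e-6
  em <- exp(-pmin(pmax(u, -500), 500))
  J <- ifelse(small,
    c_in - c_out + u * (c_in + c_out) / 2,
    u * (c_in - c_out * em) / (1 - em)
  )
  P * open_p * J
}

#' Boltzmann open probability of a two-state voltage-gated channel
#'
#' `p = 1 / (1 + exp(s * (V - V_half) / slope))` where `s = +1` for
#' inward-rectifying gating (channel opens on hyperpolarization) and
#' `s = -1` for outward-rectifying gating (opens on depolarization).
#' `polarity = "none"` returns 1.
#'
#' @param V Trans-membrane potential (V).
#' @param V_half Half-activation potential (V).
#' @param slope Slope factor (V), must be non-zero.
#' @param polarity One of `"inward"`, `"outward"`, `"none"`.
#' @return Open probability in `[0, 1]`; monotone in `V`.
#' @export
boltzmann_open_probability <- function(V, V_half, slope,
                                       polarity = c("inward", "outward", "none")) {
  polarity <- match.arg(polarity)
  if (polarity == "none") return(rep(1, length(V)))
  if (any(slope == 0)) stop("boltzmann_open_probability: slope must be non-zero")
  s <- if (polarity == "inward") 1 else -1
  1 / (1 + exp(pmin(pmax(s * (V - V_half) / slope, -500), 500)))
}

#' Gating midpoint of outward-rectifying K+ channels
#'
#' Outward rectifiers (KOR/SKOR/GORK class) track the K+ equilibrium
#' potential: the half-activation potential shifts with the apoplastic K+
#' concentration as `V_half = E_K + offset`, with
#' `E_K = (RT/F) log(K_apoplast / K_cytosol_ref)`. This keeps the channel
#' from becoming a K+ influx pathway when apoplastic K+ collapses.
#'
#' @param K_apoplast Apoplastic K+ concentration (mol m-3), positive.
#' @param offset Constant offset added to `E_K` (V).
#' @param K_cytosol_ref Reference cytosolic K+ concentration (mol m-3).
#' @param T Temperature (K).
#' @return Shifted `V_half` (V), strictly increasing in `K_apoplast`.
#' @export
kor_gating_midpoint <- function(K_apoplast, offset = 0.02,
                                K_cytosol_ref = 100, T = sr_const$Tref) {
  if (any(K_apoplast <= 0)) stop("kor_gating_midpoint: K_apoplast must be > 0")
  rtf(T) * log(K_apoplast / K_cytosol_ref) + offset
}

#' Calcium block of nonselective cation channels
#'
#' External Ca2+ blocks voltage-insensitive nonselective cation channels
#' (NSCC) with single-site hyperbolic kinetics:
#' `P_eff = P_base * K_Ca / (K_Ca + Ca_ext)`.
#'
#' @param P_base Unblocked permeability (m s-1).
#' @param Ca_ext External Ca2+ concentration (mol m-3).
#' @param K_Ca Half-block constant (mol m-3).
#' @return Effective permeability, strictly decreasing in `Ca_ext`.
#' @export
nscc_permeability <- function(P_base, Ca_ext, K_Ca = 0.3) {
  stopifnot(all(P_base >= 0), all(Ca_ext >= 0), all(K_Ca >= 0))
  P_base * K_Ca / (K_Ca + Ca_ext)
}

#' Mass-action Na+/H+ antiporter flux
#'
#' 1:1 electroneutral exchange (SOS1 on plasma membranes, NHX-class on
#' tonoplasts): `J_Na = k_ap * (Na_in * H_out - Na_out * H_in)`, positive =
#' Na+ efflux from the inner compartment; the coupled H+ flux is `-J_Na`,
#' so the net charge flux is exactly zero.
#'
#' @param k_ap Mass-action coefficient (m4 mol-1 s-1).
#' @param Na_in,Na_out,H_in,H_out Concentrations (mol m-3); `H` is free H+.
#' @return List with `J_Na`, `J_H` (= `-J_Na`) and `J_charge` (= 0),
#'   each mol m-2 s-1.
#' @export
antiporter_flux <- function(k_ap, Na_in, Na_out, H_in, H_out) {
  stopifnot(all(k_ap >= 0))
  J <- k_ap * (Na_in * H_out - Na_out * H_in)
  list(J_Na = J, J_H = -J, J_charge = J * 0)
}

#' Steady-state flux of a four-state carrier cycle
#'
#' Pumps and symporters are modeled as four-state carrier cycles
#' (bind on the cis side, translocate, release on the trans side, return).
#' The steady-state cycle flux is the King-Altman expression
#' `J = N * (k12 k23 k34 k41 - k21 k32 k43 k14) / Sigma`, where `Sigma` is
#' the sum of the 16 directional diagrams of the cycle. Substrate binding is
#' folded in by multiplying `k12` by the cis-side substrate product and
#' `k43` by the trans-side product before calling (or via `S_cis`/`S_trans`).
#' Charge translocation on the 2-3 step is voltage-dependent with symmetric
#' Eyring factors `exp(-z_t F (phi_trans - phi_cis) / (2RT))`.
#'
#' @param N Carrier surface density (mol m-2).
#' @param k Numeric vector or 8-column matrix of base rate constants in the
#'   order `k12, k21, k23, k32, k34, k43, k41, k14` (s-1, binding steps
#'   concentration-scaled).
#' @param z_t Charge translocated by the 2-3 step (cis to trans).
#' @param dphi `phi_trans - phi_cis` (V).
#' @param S_cis,S_trans Substrate concentration products multiplying `k12`
#'   and `k43`.
#' @param T Temperature (K).
#' @return Cycle flux (mol m-2 s-1), positive = cis-to-trans transport.
#'   Zero under detailed balance and proportional to `N`.
#' @export
carrier_cycle_flux <- function(N, k, z_t = 0, dphi = 0, S_cis = 1, S_trans = 1,
                               T = sr_const$Tref) {
  if (is.null(dim(k))) k <- matrix(k, ncol = 8, byrow = TRUE)
  stopifnot(ncol(k) == 8, all(k >= 0), all(N >= 0))
  fv <- exp(pmin(pmax(-z_t * sr_const$F * dphi / (2 * sr_const$R * T), -200), 200))
  a <- k[, 1] * S_cis          # k12
  b <- k[, 2]                  # k21
  cc <- k[, 3] * fv            # k23
  d <- k[, 4] / fv             # k32
  e <- k[, 5]                  # k34
  f <- k[, 6] * S_trans        # k43
  g <- k[, 7]                  # k41
  h <- k[, 8]                  # k14
  D1 <- cc * e * g + b * e * g + b * d * g + b * d * f
  D2 <- e * g * a + d * g * a + d * f * a + d * f * h
  D3 <- g * a * cc + f * a * cc + f * h * cc + f * h * b
  D4 <- a * cc * e + h * cc * e + h * b * e + h * b * d
  den <- D1 + D2 + D3 + D4
  num <- a * cc * e * g - b * d * f * h
  J <- ifelse(den > 0, N * num / den, 0)
  as.numeric(J)
}

#' Water flux across a plasma membrane
#'
#' Nonequilibrium-thermodynamics volume flux driven by hydraulic and
#' osmotic pressure differences:
#' `Jv = Lp * ((P_in - P_out) - sigma * (pi_in - pi_out))`, positive = out
#' of the inner compartment.
#'
#' @param Lp Hydraulic conductivity (m s-1 Pa-1).
#' @param sigma Reflection coefficient in `[0, 1]`.
#' @param P_in,P_out Hydraulic pressures (Pa).
#' @param pi_in,pi_out Osmotic pressures (Pa).
#' @return Volume flux (m s-1), positive = outward.
#' @export
water_flux_plasma_membrane <- function(Lp, sigma, P_in, P_out, pi_in, pi_out) {
  stopifnot(all(Lp >= 0), all(sigma >= 0), all(sigma <= 1))
  Lp * ((P_in - P_out) - sigma * (pi_in - pi_out))
}

#' Water flux across a tonoplast
#'
#' Tonoplasts do not sustain a hydraulic pressure difference; the volume
#' flux is osmotic only: `Jv = Lp * (-sigma * (pi_in - pi_out))`, positive =
#' from cytosol into vacuole when the vacuole is the outer face and
#' `pi_out > pi_in`.
#'
#' @inheritParams water_flux_plasma_membrane
#' @return Volume flux (m s-1).
#' @export
water_flux_tonoplast <- function(Lp, sigma, pi_in, pi_out) {
  stopifnot(all(Lp >= 0), all(sigma >= 0), all(sigma <= 1))
  -Lp * sigma * (pi_in - pi_out)
}

#' Van 't Hoff osmotic pressure
#'
#' `pi = R T sum(c)` over all osmotically active species (the four mobile
#' ions plus impermeant anions and buffer where present).
#'
#' @param c_total Total osmolyte concentration (mol m-3).
#' @param T Temperature (K).
#' @return Osmotic pressure (Pa).
#' @export
osmotic_pressure <- function(c_total, T = sr_const$Tref) {
  sr_const$R * T * c_total
}
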