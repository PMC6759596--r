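#' Extended Nernst-Planck flux along an apoplastic or symplastic edge
#'
#' Two-point finite-volume discretization of electrodiffusion with
#' convection between compartments `a` and `b`:
#' `J = -D * ((c_b - c_a)/L + z (F/RT) cbar (phi_b - phi_a)/L) + c_up * v`,
#' where `cbar` is the arithmetic interface mean and `c_up` the upwind
#' concentration with respect to the water velocity `v` (positive a to b).
#' First-order upwinding keeps the scheme monotone in the
#' advection-dominated xylem limit.
#'
#' @param D Effective diffusivity along the edge (m2 s-1).
#' @param z Ion valence.
#' @param c_a,c_b Concentrations at the two nodes (mol m-3).
#' @param phi_a,phi_b Electric potentials (V).
#' @param L Path length (m), positive.
#' @param v Water velocity through the edge (m s-1), positive a to b.
#' @param T Temperature (K).
#' @return Molar flux density (mol m-2 s-1), positive a to b. Vectorized.
#' @export
nernst_planck_edge_flux <- function(D, z, c_a, c_b, phi_a, phi_b, L, v = 0,
                                    T = sr_const$Tref) {
  if (any(L <= 0)) stop("nernst_planck_edge_flux: path length L must be > 0")
  cbar <- (c_a + c_b) / 2
  diff_drift <- -D * ((c_b - c_a) / L +
    z * (sr_const$F / (sr_const$R * T)) * cbar * (phi_b - phi_a) / L)
  # smoothed first-order upwinding: full upwind for |v| >> 1e-13 m/s,
  # differentiable at v = 0 (keeps the stiff solver's Newton iteration
  # from chattering on sign changes of near-zero wall flows)
  w <- tanh(v / 1e-13)
  c_up <- cbar + w * (c_a - c_b) / 2
  diff_drift + c_up * v
}

#' Hydraulic water flux along an apoplastic edge
#'
#' Apoplastic water movement is driven by hydraulic pressure gradients only:
#' `q = -k_h * (P_b - P_a) / L` (m s-1, positive a to b).
#'
#' @param k_h Apoplastic hydraulic permeability (m2 Pa-1 s-1).
#' @param P_a,P_b Hydraulic pressures (Pa).
#' @param L Path length (m), positive.
#' @return Volume flux density (m s-1), positive a to b.
#' @export
apoplast_water_edge_flux <- function(k_h, P_a, P_b, L) {
  if (any(L <= 0)) stop("apoplast_water_edge_flux: path length L must be > 0")
  -k_h * (P_b - P_a) / L
}

#' Water flux through plasmodesmata
#'
#' Symplastic water flow responds to both hydraulic and osmotic pressure
#' differences: `q = L_pd * ((P_a - P_b) - sigma_pd * (pi_a - pi_b))`
#' (m s-1, positive a to b).
#'
#' @param L_pd Plasmodesmal hydraulic conductivity (m s-1 Pa-1).
#' @param sigma_pd Reflection coefficient of the plasmodesmal path.
#' @param P_a,P_b Hydraulic pressures (Pa).
#' @param pi_a,pi_b Osmotic pressures (Pa).
#' @return Volume flux density (m s-1), positive a to b.
#' @export
symplast_water_edge_flux <- function(L_pd, sigma_pd, P_a, P_b, pi_a, pi_b) {
  L_pd * ((P_a - P_b) - sigma_pd * (pi_a - pi_b))
}

#' Equilibrium partition of total protons over a single buffer
#'
#' Cytosols and vacuoles carry a single equilibrium buffer `B- + H+ <-> BH`
#' with total capacity `B_total` and dissociation constant `K_b`. Given the
#' total proton pool `H_total = H_free + H_bound` with
#' `H_bound = B_total H_free / (K_b + H_free)`, the free concentration is
#' the positive root of
#' `H_free^2 + (K_b + B_total - H_total) H_free - K_b H_total = 0`.
#'
#' @param H_total Total proton concentration (mol m-3).
#' @param B_total Buffer capacity (mol m-3).
#' @param K_b Buffer dissociation constant (mol m-3).
#' @return List with `H_free` and `H_bound` (mol m-3); `H_free` is strictly
#'   increasing in `H_total`. Vectorized.
#' @export
proton_buffer_partition <- function(H_total, B_total, K_b) {
  stopifnot(all(H_total >= 0), all(B_total >= 0), all(K_b >= 0))
  b <- K_b + B_total - H_total
  # numerically stable positive quadratic root
  disc <- sqrt(b^2 + 4 * K_b * H_total)
  H_free <- ifelse(b >= 0, 2 * K_b * H_total / (b + disc), (disc - b) / 2)
  H_free <- pmin(H_free, H_total)
  list(H_free = H_free, H_bound = H_total - H_free)
}

#' Per-compartment electroneutrality residual
#'
#' `r = c_Na + c_K + c_H_free - c_Cl - c_buffer_anion - c_fixed_anion`
#' in mol-equivalents m-3. The free buffer anion concentration is
#' `B_total - H_bound`; fixed anionic charge is present in apoplasts
#' (cell-wall charges) and as the impermeant organic anion pool in living
#' compartments. Potentials are the algebraic unknowns that hold this
#' residual at zero along a solution.
#'
#' @param c_Na,c_K,c_Cl Mobile ion concentrations (mol m-3).
#' @param c_H_free Free proton concentration (mol m-3).
#' @param B_total Buffer capacity (mol m-3); 0 in apoplasts.
#' @param H_bound Buffer-bound protons (mol m-3).
#' @param fixed_anion Fixed anionic charge density (mol m-3, positive
#'   number of negative equivalents).
#' @return Residual (mol-equiv m-3); 0 for an electroneutral compartment.
#' @export
electroneutrality_residual <- function(c_Na, c_K, c_Cl, c_H_free,
                                       B_total = 0, H_bound = 0,
                                       fixed_anion = 0) {
  c_Na + c_K + c_H_free - c_Cl - (B_total - H_bound) - fixed_anion
}
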