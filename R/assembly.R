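# Model assembly: state layout, residual assembly, consistent initialization.
#
# State layout (layer-major, deterministic): 6 slots per compartment,
#   [c_Na, c_K, c_Cl, c_H, V, phi]
# where c_H is the total proton pool for living compartments (free +
# buffer-bound) and the free concentration in apoplasts; V (m3) is the
# dynamic compartment volume (cells follow the elastic turgor law,
# apoplasts a much stiffer wall-compliance law, so walls are close to
# rigid); phi (V) is algebraic. The algebraic rows are per-compartment net
# charge-flux balance (the differentiated electroneutrality constraint;
# initial states are built exactly electroneutral).

SPZ <- c(Na = 1, K = 1, Cl = -1, H = 1)   # valences, species order Na,K,Cl,H

slot_of <- function(comp_idx, s) (comp_idx - 1L) * 6L + s

acc <- function(n, idx, val) {
  out <- numeric(n)
  if (length(idx)) {
    tmp <- rowsum(val, idx)
    out[as.integer(rownames(tmp))] <- tmp
  }
  out
}

#' Assemble a runnable root-transport model
#'
#' Combines a geometry, a connectivity graph, a transporter distribution and
#' a kinetic parameter set into a model object holding the state layout,
#' per-edge parameter arrays, the mass vector of the differential-algebraic
#' system, solver tolerances and the Jacobian bandwidth.
#'
#' @param config A configuration list with elements `geometry` (arguments
#'   for [build_root_grid()]), `barriers` (arguments for [apply_barriers()]),
#'   `params` (see [default_params()]), `distribution`
#'   (see [default_distribution()]), optional `genotype`
#'   (`"wild_type"`/`"sos1"`), optional `closed` (drop boundary edges),
#'   optional `P_top` (xylem top pressure, default -0.3 MPa) and `solver`
#'   (`rtol`, `atol` scale).
#' @return An object of class `sr_model`.
#' @export
build_model <- function(config) {
  p <- config$params
  geom <- do.call(build_root_grid, config$geometry)
  conn <- do.call(apply_barriers, c(list(geometry = geom), config$barriers))
  edges <- conn[!conn$blocked, , drop = FALSE]
  closed <- isTRUE(config$closed)
  if (closed)
    edges <- edges[!edges$pathway %in%
                     c("boundary_external", "boundary_xylem_top"), ,
                   drop = FALSE]
  comp <- geom$comp
  n <- nrow(comp)
  kind <- match(comp$kind, c("apoplast", "cytosol", "vacuole")) - 1L
  living <- comp$living

  # fixed anion amounts (mol): wall charges in apoplasts; the impermeant
  # organic anion pool of living compartments is set at initialization
  A_amt <- numeric(n)
  wall <- ifelse(comp$tissue == "xylem" & comp$zone == "mature",
                 p$xylem_wall_charge, p$wall_charge)
  A_amt[kind == 0L] <- wall[kind == 0L] * comp$V0[kind == 0L]
  B_conc0 <- ifelse(kind == 1L, p$B_cyt, ifelse(kind == 2L, p$B_vac, 0))
  B_amt <- B_conc0 * comp$V0
  K_b <- ifelse(kind == 2L, p$Kb_vac, p$Kb_cyt)

  # cell grouping for turgor (cytosol and vacuole share one wall)
  cyt_idx <- which(comp$kind == "cytosol")
  vac_idx <- which(comp$kind == "vacuole")
  key <- paste(comp$layer, comp$ring)
  vac_of <- rep(NA_integer_, n)
  vac_of[cyt_idx] <- vac_idx[match(key[cyt_idx], key[vac_idx])]
  cyt_of <- rep(NA_integer_, n)
  cyt_of[vac_idx] <- cyt_idx[match(key[vac_idx], key[cyt_idx])]
  V0_cell <- numeric(n)
  V0_cell[cyt_idx] <- comp$V0[cyt_idx] + comp$V0[vac_of[cyt_idx]]
  V0_cell[vac_idx] <- V0_cell[cyt_of[vac_idx]]

  # ---- edge groups ----
  pw <- edges$pathway
  mk_np <- function(sel, kh, tort) {
    e <- edges[sel, , drop = FALSE]
    list(a = e$a, b = e$b, area = e$area_m2, L = e$length_m,
         kh = rep_len(kh, nrow(e)),
         D = c(p$D_Na, p$D_K, p$D_Cl, p$D_H) * tort)
  }
  sel_ap <- pw %in% c("apoplast_radial", "apoplast_axial")
  ap <- mk_np(sel_ap, p$k_h_wall, p$tort_apo)
  # open xylem conduit: identify axial edges between mature xylem apoplasts
  is_xyl <- comp$tissue == "xylem" & comp$kind == "apoplast"
  if (any(sel_ap)) {
    e <- edges[sel_ap, ]
    xyl_edge <- e$pathway == "apoplast_axial" & is_xyl[e$a] & is_xyl[e$b]
    ap$kh[xyl_edge] <- p$k_h_xylem
  }
  pd <- {
    e <- edges[pw == "plasmodesma", , drop = FALSE]
    list(a = e$a, b = e$b, area = e$area_m2, L = e$length_m,
         Lp = p$Lp_pd, sigma = p$sigma_pd,
         D = c(p$D_Na, p$D_K, p$D_Cl, p$D_H) * p$tort_pd)
  }
  ext <- {
    e <- edges[pw == "boundary_external", , drop = FALSE]
    list(a = e$a, area = e$area_m2, L = e$length_m, kh = p$k_h_surface,
         D = c(p$D_Na, p$D_K, p$D_Cl, p$D_H) * p$tort_apo)
  }
  top <- {
    e <- edges[pw == "boundary_xylem_top", , drop = FALSE]
    list(a = e$a, area = e$area_m2, L = e$length_m, kh = p$k_h_xylem)
  }

  # ---- plasma-membrane edges with per-edge transporter parameters ----
  epm <- edges[pw == "plasma_membrane", , drop = FALSE]
  tis <- comp$tissue[epm$a]; zon <- comp$zone[epm$a]
  dist <- config$distribution
  has <- function(rule) {
    ok <- tis %in% rule$tissues & zon %in% rule$zones
    if (!is.null(rule$extra))
      ok <- ok | (tis %in% rule$extra$tissues & zon %in% rule$extra$zones)
    ok
  }
  amap <- dist$antiporter_map
  ap_on <- amap[cbind(zon, tis)]
  k_ap <- ifelse(ap_on,
                 ifelse(tis %in% c("xylem_parenchyma", "xylem"),
                        p$k_ap_stele, p$k_ap_outer), 0)
  if (identical(config$genotype, "sos1")) k_ap <- k_ap * p$sos1_residual_frac
  pm <- list(
    cyt = epm$a, apo = epm$b, area = epm$area_m2,
    P_nscc = ifelse(has(dist$nscc), p$P_nscc, 0),
    P_kir = ifelse(has(dist$kir), p$P_kir, 0),
    P_kor = ifelse(has(dist$kor), p$P_kor, 0),
    P_hkt = ifelse(has(dist$hkt), p$P_hkt, 0),
    P_anion = ifelse(has(dist$anion),
                     ifelse(tis == "xylem_parenchyma" & zon == "mature",
                            p$P_anion_stele, p$P_anion_outer), 0),
    N_pump = ifelse(has(dist$pump), p$N_pump, 0),
    N_khsym = ifelse(has(dist$khsym), p$N_khsym, 0),
    N_clhsym = ifelse(has(dist$clhsym), p$N_clhsym, 0),
    k_ap = as.numeric(k_ap),
    Lp = p$Lp_pm, sigma = p$sigma_pm,
    tissue = tis, zone = zon
  )
  eto <- edges[pw == "tonoplast", , drop = FALSE]
  zto <- comp$zone[eto$a]
  ton <- list(
    cyt = eto$a, vac = eto$b, area = eto$area_m2,
    P_Na = p$P_ton_Na, P_K = p$P_ton_K, P_Cl = p$P_ton_Cl,
    N_vpump = p$N_vpump,
    k_nhx = ifelse(zto %in% dist$nhx$zones, p$k_nhx, 0),
    k_khton = p$k_khton,
    Lp = p$Lp_ton, sigma = p$sigma_ton
  )

  # mass vector and tolerances
  mass <- rep(1, 6 * n)
  mass[slot_of(seq_len(n), 6L)] <- 0            # potential rows (algebraic)
  atol <- rep(1e-6, 6 * n)
  atol[slot_of(seq_len(n), 4L)] <- 1e-9
  atol[slot_of(seq_len(n), 5L)] <- comp$V0 * 1e-6
  atol[slot_of(seq_len(n), 6L)] <- 1e-8
  # state nondimensionalization for the integrator (conditioning of the
  # Radau iteration matrix): concentrations O(10), volumes O(V0),
  # potentials O(0.1)
  sscale <- rep(10, 6 * n)
  sscale[slot_of(seq_len(n), 4L)] <- 0.01
  sscale[slot_of(seq_len(n), 5L)] <- comp$V0
  sscale[slot_of(seq_len(n), 6L)] <- 0.1

  # Jacobian bandwidth: couplings are local (within a layer and to the
  # adjacent layer); measured from the realized edge list
  # +2: an edge flux can depend on the partner cell's turgor, hence on the
  # volume of the vacuole adjacent to the partner cytosol
  span <- max(abs(edges$a - edges$b)[edges$b > 0], 1)
  bw <- (span + 2L) * 6L

  # a closed system has no external ground: pin the first apoplast
  # potential (absolute potentials are arbitrary there, differences matter)
  ground <- if (closed) which(kind == 0L)[1] else NA_integer_
  model <- structure(list(
    config = config, geometry = geom, connectivity = conn, comp = comp,
    n_comp = n, kind = kind, living = living, ground = ground,
    V0 = comp$V0, A_amt = A_amt, B_amt = B_amt, K_b = K_b,
    vac_of = vac_of, cyt_of = cyt_of, V0_cell = V0_cell,
    ap = ap, pd = pd, ext = ext, top = top, pm = pm, ton = ton,
    params = p, closed = closed,
    P_top = if (is.null(config$P_top)) -0.3e6 else config$P_top,
    mass = mass, atol = atol, bw = bw, sscale = sscale
  ), class = "sr_model")
  model
}

#' @export
print.sr_model <- function(x, ...) {
  cat("saltroot model:", x$n_comp, "compartments,", 6 * x$n_comp,
      "states, bandwidth", x$bw, "\n")
  invisible(x)
}

# free proton concentration for every compartment
free_H <- function(model, cH, V) {
  Hf <- pmax(cH, 0)   # guard transient negative excursions of the integrator
  liv <- model$living
  if (any(liv)) {
    pb <- proton_buffer_partition(Hf[liv], model$B_amt[liv] / V[liv],
                                  model$K_b[liv])
    Hf[liv] <- pb$H_free
  }
  Hf
}

# hydraulic pressure of every compartment from its volume state
pressures <- function(model, V) {
  p <- model$params
  apo <- model$kind == 0L
  P <- numeric(model$n_comp)
  P[apo] <- p$eps_wall * (V[apo] - model$V0[apo]) / model$V0[apo]
  ci <- which(model$kind == 1L)
  if (length(ci)) {
    Vcell <- V[ci] + V[model$vac_of[ci]]
    Pc <- p$P_turgor0 + p$eps_cell * (Vcell - model$V0_cell[ci]) /
      model$V0_cell[ci]
    P[ci] <- Pc
    P[model$vac_of[ci]] <- Pc
  }
  P
}

#' Evaluate the DAE residual (reference implementation)
#'
#' Assembles the full right-hand side of the root transport system at a
#' given state: species conservation rows `d c/dt`, volume rows `d V/dt`
#' for living compartments, and the algebraic rows (net charge-flux balance
#' defining the potentials; net water-volume balance defining apoplastic
#' pressures). With `detail = TRUE` the per-edge fluxes are returned for
#' observable extraction.
#'
#' @param t Time (s); the system is autonomous given fixed boundary
#'   conditions, `t` is accepted for solver compatibility.
#' @param y State vector.
#' @param model An `sr_model`.
#' @param bc Boundary conditions: a medium (see [make_medium()]) with
#'   optional `P_ext` (default 0).
#' @param detail Return per-edge flux tables alongside the residual.
#' @return Numeric vector `dy` (or a list with `dy` and flux detail).
#' @export
assemble_residual <- function(t, y, model, bc, detail = FALSE) {
  n <- model$n_comp
  p <- model$params
  Y <- matrix(y, nrow = 6L)
  cNa <- Y[1, ]; cK <- Y[2, ]; cCl <- Y[3, ]; cH <- Y[4, ]
  V <- Y[5, ]; phi <- Y[6, ]
  if (any(!is.finite(y))) stop("assemble_residual: non-finite state")
  Hf <- free_H(model, cH, V)
  P <- pressures(model, V)
  RT <- sr_const$R * p$T
  osm <- cNa + cK + cCl + Hf + (model$A_amt + model$B_amt) / V
  piv <- RT * osm

  gNa <- numeric(n); gK <- numeric(n); gCl <- numeric(n); gH <- numeric(n)
  gW <- numeric(n)   # net water volume gain (m3/s)
  conc <- list(cNa, cK, cCl, Hf)

  dep <- function(idx_a, idx_b, J) {
    # J mol/s (or m3/s), positive a->b; idx_b = 0 means boundary
    ga <- -acc(n, idx_a, J)
    keep <- idx_b > 0
    if (any(keep)) ga <- ga + acc(n, idx_b[keep], J[keep])
    ga
  }

  det <- if (detail) list() else NULL

  # ---- apoplastic edges: hydraulic water + Nernst-Planck ----
  np_block <- function(g, q_dens) {
    qv <- q_dens * g$area
    Js <- vector("list", 4)
    for (s in 1:4) {
      J <- nernst_planck_edge_flux(g$D[s], SPZ[s], conc[[s]][g$a],
                                   conc[[s]][g$b], phi[g$a], phi[g$b],
                                   g$L, q_dens, p$T) * g$area
      Js[[s]] <- J
    }
    list(q = qv, Js = Js)
  }
  if (length(model$ap$a)) {
    g <- model$ap
    qd <- apoplast_water_edge_flux(g$kh, P[g$a], P[g$b], g$L)
    fl <- np_block(g, qd)
    gW <- gW + dep(g$a, g$b, fl$q)
    gNa <- gNa + dep(g$a, g$b, fl$Js[[1]])
    gK  <- gK  + dep(g$a, g$b, fl$Js[[2]])
    gCl <- gCl + dep(g$a, g$b, fl$Js[[3]])
    gH  <- gH  + dep(g$a, g$b, fl$Js[[4]])
    if (detail) det$ap <- fl
  }
  # ---- plasmodesmata: symplastic water + Nernst-Planck ----
  if (length(model$pd$a)) {
    g <- model$pd
    qd <- symplast_water_edge_flux(g$Lp, g$sigma, P[g$a], P[g$b],
                                   piv[g$a], piv[g$b])
    fl <- np_block(g, qd)
    gW <- gW + dep(g$a, g$b, fl$q)
    gNa <- gNa + dep(g$a, g$b, fl$Js[[1]])
    gK  <- gK  + dep(g$a, g$b, fl$Js[[2]])
    gCl <- gCl + dep(g$a, g$b, fl$Js[[3]])
    gH  <- gH  + dep(g$a, g$b, fl$Js[[4]])
    if (detail) det$pd <- fl
  }
  # ---- external boundary (medium side b) ----
  if (length(model$ext$a)) {
    g <- model$ext
    cb <- c(bc$Na, bc$K, bc$Cl, bc$H)
    P_ext <- if (is.null(bc$P_ext)) 0 else bc$P_ext
    qd <- apoplast_water_edge_flux(g$kh, P[g$a], P_ext, g$L)
    qv <- qd * g$area
    gW <- gW + dep(g$a, rep(0L, length(g$a)), qv)
    Js <- vector("list", 4)
    for (s in 1:4) {
      J <- nernst_planck_edge_flux(g$D[s], SPZ[s], conc[[s]][g$a], cb[s],
                                   phi[g$a], 0, g$L, qd, p$T) * g$area
      Js[[s]] <- J
      gs <- dep(g$a, rep(0L, length(g$a)), J)
      if (s == 1) gNa <- gNa + gs else if (s == 2) gK <- gK + gs
      else if (s == 3) gCl <- gCl + gs else gH <- gH + gs
    }
    if (detail) det$ext <- list(a = g$a, q = qv, Js = Js)
  }
  # ---- xylem top boundary: advective outflow to the shoot ----
  if (length(model$top$a)) {
    g <- model$top
    qd <- -g$kh * (model$P_top - P[g$a]) / g$L   # positive = out
    qv <- qd * g$area
    gW <- gW + dep(g$a, 0L, qv)
    Js <- vector("list", 4)
    for (s in 1:4) {
      J <- conc[[s]][g$a] * qv    # upwind: xylem concentration leaves
      Js[[s]] <- J
      gs <- dep(g$a, 0L, J)
      if (s == 1) gNa <- gNa + gs else if (s == 2) gK <- gK + gs
      else if (s == 3) gCl <- gCl + gs else gH <- gH + gs
    }
    if (detail) det$top <- list(a = g$a, q = qv, Js = Js)
  }
  # ---- plasma membranes ----
  if (length(model$pm$cyt)) {
    g <- model$pm
    ci <- g$cyt; ai <- g$apo
    Vm <- phi[ci] - phi[ai]
    Ca_ext <- bc$Ca
    P_nscc_eff <- nscc_permeability(g$P_nscc, Ca_ext, p$K_Ca)
    JNa <- ghk_flux(P_nscc_eff, 1, Vm, cNa[ci], cNa[ai], p$T) +
           ghk_flux(g$P_hkt, 1, Vm, cNa[ci], cNa[ai], p$T)
    p_kir <- boltzmann_open_probability(Vm, p$kir_Vhalf, p$kir_slope, "inward")
    vh_kor <- kor_gating_midpoint(pmax(cK[ai], 1e-6), p$kor_offset,
                                  p$K_cyt_ref, p$T)
    p_kor <- boltzmann_open_probability(Vm, vh_kor, p$kor_slope, "outward")
    JK <- ghk_flux(P_nscc_eff, 1, Vm, cK[ci], cK[ai], p$T) +
          ghk_flux(g$P_kir * p_kir, 1, Vm, cK[ci], cK[ai], p$T) +
          ghk_flux(g$P_kor * p_kor, 1, Vm, cK[ci], cK[ai], p$T)
    JCl <- ghk_flux(g$P_anion, -1, Vm, cCl[ci], cCl[ai], p$T)
    # H+ pump (efflux), K+/H+ and Cl-/2H+ symporters (influx)
    Jpump <- carrier_cycle_flux(g$N_pump, p$pump_rates, p$pump_zt,
                                phi[ai] - phi[ci], Hf[ci], Hf[ai], p$T)
    Jkh <- carrier_cycle_flux(g$N_khsym, p$khsym_rates, p$khsym_zt,
                              phi[ci] - phi[ai], cK[ai] * Hf[ai],
                              cK[ci] * Hf[ci], p$T)
    Jclh <- carrier_cycle_flux(g$N_clhsym, p$clhsym_rates, p$clhsym_zt,
                               phi[ci] - phi[ai], cCl[ai] * Hf[ai]^2,
                               cCl[ci] * Hf[ci]^2, p$T)
    Jap <- antiporter_flux(g$k_ap, cNa[ci], cNa[ai], Hf[ci], Hf[ai])$J_Na
    Jchx <- antiporter_flux(p$k_chx, cK[ci], cK[ai], Hf[ci], Hf[ai])$J_Na
    Jhleak <- ghk_flux(p$P_H_pm, 1, Vm, Hf[ci], Hf[ai], p$T)
    JNa <- JNa + Jap
    JK <- JK - Jkh + Jchx
    JCl <- JCl - Jclh
    JH <- Jpump + Jhleak - Jap - Jchx - Jkh - 2 * Jclh
    qd <- water_flux_plasma_membrane(g$Lp, g$sigma, P[ci], P[ai],
                                     piv[ci], piv[ai])
    gNa <- gNa + dep(ci, ai, JNa * g$area)
    gK  <- gK  + dep(ci, ai, JK * g$area)
    gCl <- gCl + dep(ci, ai, JCl * g$area)
    gH  <- gH  + dep(ci, ai, JH * g$area)
    gW  <- gW  + dep(ci, ai, qd * g$area)
    if (detail)
      det$pm <- list(cyt = ci, apo = ai, area = g$area, J_Na = JNa, J_K = JK,
                     J_Cl = JCl, J_H = JH, J_ap_Na = Jap, q = qd * g$area,
                     Vm = Vm, tissue = g$tissue, zone = g$zone)
  }
  # ---- tonoplasts (positive flux = cytosol to vacuole) ----
  if (length(model$ton$cyt)) {
    g <- model$ton
    ci <- g$cyt; vi <- g$vac
    Vt <- phi[ci] - phi[vi]
    JNa <- ghk_flux(g$P_Na, 1, Vt, cNa[ci], cNa[vi], p$T)
    JK  <- ghk_flux(g$P_K, 1, Vt, cK[ci], cK[vi], p$T)
    JCl <- ghk_flux(g$P_Cl, -1, Vt, cCl[ci], cCl[vi], p$T)
    Jvp <- carrier_cycle_flux(g$N_vpump, p$vpump_rates, p$vpump_zt,
                              phi[vi] - phi[ci], Hf[ci], Hf[vi], p$T)
    Jnhx <- antiporter_flux(g$k_nhx, cNa[ci], cNa[vi], Hf[ci], Hf[vi])$J_Na
    Jkh  <- antiporter_flux(g$k_khton, cK[ci], cK[vi], Hf[ci], Hf[vi])$J_Na
    Jhleak <- ghk_flux(p$P_H_ton, 1, Vt, Hf[ci], Hf[vi], p$T)
    JNa <- JNa + Jnhx
    JK <- JK + Jkh
    JH <- Jvp + Jhleak - Jnhx - Jkh
    qd <- water_flux_tonoplast(g$Lp, g$sigma, piv[ci], piv[vi])
    gNa <- gNa + dep(ci, vi, JNa * g$area)
    gK  <- gK  + dep(ci, vi, JK * g$area)
    gCl <- gCl + dep(ci, vi, JCl * g$area)
    gH  <- gH  + dep(ci, vi, JH * g$area)
    gW  <- gW  + dep(ci, vi, qd * g$area)
    if (detail)
      det$ton <- list(cyt = ci, vac = vi, J_Na = JNa, J_K = JK, J_Cl = JCl,
                      J_H = JH, q = qd * g$area)
  }

  Vdot <- gW
  dY <- matrix(0, nrow = 6L, ncol = n)
  dY[1, ] <- (gNa - cNa * Vdot) / V
  dY[2, ] <- (gK - cK * Vdot) / V
  dY[3, ] <- (gCl - cCl * Vdot) / V
  dY[4, ] <- (gH - cH * Vdot) / V
  dY[5, ] <- Vdot
  dY[6, ] <- (gNa + gK - gCl + gH) / model$V0          # algebraic: charge balance
  if (!is.na(model$ground)) dY[6, model$ground] <- -phi[model$ground]
  dy <- as.numeric(dY)
  if (any(!is.finite(dy))) {
    bad <- which(!is.finite(dY), arr.ind = TRUE)
    stop("assemble_residual: non-finite flux in compartment ",
         bad[1, 2], " (", model$comp$tissue[bad[1, 2]], " ",
         model$comp$kind[bad[1, 2]], ", layer ",
         model$comp$layer[bad[1, 2]], "), slot ", bad[1, 1])
  }
  if (detail) list(dy = dy, det = det, P = P, pi = piv, H_free = Hf, V = V)
  else dy
}

#' Build an electroneutral initial state
#'
#' Sets documented uniform initial concentrations (apoplasts at the medium
#' composition with cell-wall counter-cations; cytosols and vacuoles at the
#' configured resting composition), chooses the impermeant organic anion
#' pool of every living compartment so that each compartment is exactly
#' electroneutral, then solves the algebraic subsystem (potentials and
#' apoplastic pressures) by damped Newton iteration.
#'
#' @param model An `sr_model`.
#' @param bc Boundary medium.
#' @param guess Optional initial values `list(phi_apo, phi_cyt, phi_vac)`.
#' @return State vector with consistent algebraic variables; the chosen
#'   anion amounts are stored in `attr(, "A_amt")` and written into
#'   `model` by [initialize_model()].
#' @export
initial_state <- function(model, bc, guess = NULL) {
  p <- model$params
  n <- model$n_comp
  comp <- model$comp
  kind <- model$kind
  if (is.null(guess)) guess <- list(phi_apo = -0.005, phi_cyt = -0.12,
                                    phi_vac = -0.10)
  cNa <- cK <- cCl <- cH <- numeric(n)
  A_amt <- model$A_amt
  apo <- kind == 0L
  X <- A_amt[apo] / model$V0[apo]
  shareNa <- bc$Na / max(bc$Na + bc$K, 1e-12)
  cNa[apo] <- bc$Na + X * shareNa
  cK[apo] <- bc$K + X * (1 - shareNa)
  cH[apo] <- bc$H
  cCl[apo] <- cNa[apo] + cK[apo] + cH[apo] - X   # exact electroneutrality

  for (k in 1:2) {
    sel <- kind == k
    if (k == 1L) {
      na0 <- p$Na_cyt0; k0 <- p$K_cyt0; cl0 <- p$Cl_cyt0
      Hfree <- ph_to_conc(p$pH_cyt0); B <- p$B_cyt; Kb <- p$Kb_cyt
    } else {
      na0 <- p$Na_vac0; k0 <- p$K_vac0; cl0 <- p$Cl_vac0
      Hfree <- ph_to_conc(p$pH_vac0); B <- p$B_vac; Kb <- p$Kb_vac
    }
    Hb <- B * Hfree / (Kb + Hfree)
    cNa[sel] <- na0; cK[sel] <- k0; cCl[sel] <- cl0
    cH[sel] <- Hfree + Hb
    A_conc <- na0 + k0 + Hfree - cl0 - (B - Hb)
    if (A_conc < 0)
      stop("initial_state: initial composition implies a negative ",
           "impermeant anion pool; adjust Na/K/Cl initial values")
    A_amt[sel] <- A_conc * model$V0[sel]
  }
  Y <- matrix(0, 6L, n)
  Y[1, ] <- cNa; Y[2, ] <- cK; Y[3, ] <- cCl; Y[4, ] <- cH
  Y[5, ] <- model$V0
  Y[6, ] <- ifelse(kind == 0L, guess$phi_apo,
                   ifelse(kind == 1L, guess$phi_cyt, guess$phi_vac))
  y <- as.numeric(Y)
  attr(y, "A_amt") <- A_amt
  y
}

#' Prepare a model and a consistent state for integration
#'
#' Installs the electroneutral anion pools from [initial_state()] into the
#' model and solves the algebraic subsystem so that the returned state
#' satisfies all algebraic rows to `tol`.
#'
#' @param model An `sr_model`.
#' @param bc Boundary medium.
#' @param y Optional starting state (defaults to [initial_state()]).
#' @param tol Convergence tolerance on the scaled algebraic residual.
#' @return List with the updated `model` and consistent state `y`.
#' @export
initialize_model <- function(model, bc, y = NULL, tol = 1e-10) {
  if (is.null(y)) {
    y <- initial_state(model, bc)
    model$A_amt <- attr(y, "A_amt")
    attr(y, "A_amt") <- NULL
  }
  # alternate: solve the algebraic subsystem (which adjusts apoplast
  # volumes), then re-balance the fixed-anion amounts at the new volumes so
  # every compartment is exactly electroneutral; converges in 2-3 rounds
  for (it in 1:4) {
    y <- solve_algebraic(model, bc, y, tol = tol)
    Y <- matrix(y, nrow = 6L)
    V <- Y[5, ]
    Hf <- free_H(model, Y[4, ], V)
    Hb <- pmax(Y[4, ], 0) - Hf
    A_new <- (Y[1, ] + Y[2, ] + Hf - Y[3, ] -
                (model$B_amt / V - Hb)) * V
    drift <- max(abs(A_new - model$A_amt) / pmax(model$A_amt, 1e-30))
    model$A_amt <- A_new
    if (drift < 1e-12) break
  }
  list(model = model, y = y)
}

# Solve the algebraic subsystem (potentials + apoplast pressures) for a
# fixed differential state: a short pseudo-transient relaxation (small
# artificial capacitance on the algebraic rows, which has the physical sign
# of a membrane capacitance / wall compressibility) brings the unknowns
# into the Newton basin; a damped, row-scaled Newton iteration polishes.
solve_algebraic <- function(model, bc, y, tol = 1e-10, max_iter = 40,
                            use_cpp = TRUE) {
  n <- model$n_comp
  # unknowns: all potentials, plus apoplast volumes (so the stiff
  # wall-compliance water balance starts equilibrated)
  apo <- which(model$kind == 0L)
  ai <- sort(c(slot_of(seq_len(n), 6L), slot_of(apo, 5L)))
  scale <- ifelse(ai %% 6L == 0L, 0.05, model$V0[(ai - 1L) %/% 6L + 1L])
  f <- rhs_fun(model, bc, use_cpp = use_cpp)

  # --- phase 1: pseudo-transient relaxation of the algebraic slots only ---
  if (use_cpp) {
    mask <- integer(length(y))
    mask[ai] <- 1L
    s <- model$sscale
    # keep the pack alive in this frame for the whole integration
    pack_ptr <- sr_make_pack(cpp_pack(model))
    sr_use_pack(pack_ptr, bc_vec(validate_medium(bc)), s, mask)
    out <- try(deSolve::radau(
      y = y / s, times = c(0, 10), func = "sr_derivs", dllname = "saltroot",
      initfunc = NULL, parms = NULL,
      rtol = 1e-6, atol = model$atol / s,
      jactype = "bandint", bandup = model$bw, banddown = model$bw,
      maxsteps = 20000), silent = TRUE)
    if (!inherits(out, "try-error") && nrow(out) > 1)
      y[ai] <- (out[nrow(out), -1] * s)[ai]
  } else {
    freeze <- setdiff(seq_along(y), ai)
    func <- function(t, yy, parms) {
      dy <- f(t, yy)
      dy[freeze] <- 0
      list(dy)
    }
    out <- try(deSolve::radau(
      y = y, times = c(0, 10), func = func, parms = NULL,
      rtol = 1e-6, atol = model$atol,
      jactype = "bandint", bandup = model$bw, banddown = model$bw,
      maxsteps = 20000), silent = TRUE)
    if (!inherits(out, "try-error") && nrow(out) > 1)
      y[ai] <- out[nrow(out), -1][ai]
  }

  # --- phase 2: damped Newton polish (strict improvement only) ---
  # row weights put charge rows (mol m-3 s-1) and water rows (m3 s-1,
  # rescaled by 1/V0 to 1 s-1) on comparable footing
  wrow <- ifelse(ai %% 6L == 0L, 1, 1 / model$V0[(ai - 1L) %/% 6L + 1L])
  res <- function(z) {
    y2 <- y; y2[ai] <- z
    f(0, y2)[ai] * wrow
  }
  z <- y[ai]
  r <- res(z)
  rs_norm <- function(r) max(abs(r))
  r0 <- rs_norm(r)
  tol_eff <- max(tol, 1e-9 * r0)
  for (it in seq_len(max_iter)) {
    if (rs_norm(r) < tol_eff) break
    J <- matrix(0, length(ai), length(ai))
    for (j in seq_along(ai)) {
      h <- 1e-6 * scale[j]
      zp <- z; zp[j] <- zp[j] + h
      J[, j] <- (res(zp) - r) / h
    }
    # drop structurally inert unknowns (e.g. the potential of a compartment
    # with no charge-carrying pathway): zero row and column
    rowmax <- apply(abs(J), 1, max)
    live <- rowmax > 1e-30   # only structurally zero rows are inert
    dz <- numeric(length(z))
    if (any(live)) {
      Jl <- J[live, live, drop = FALSE]
      rl <- r[live]
      rw <- 1 / pmax(apply(abs(Jl), 1, max), 1e-30)
      dz[live] <- tryCatch(solve(Jl * rw, -rl * rw), error = function(e) {
        A <- Jl * rw
        lam <- 1e-10 * max(abs(A))^2
        as.numeric(solve(crossprod(A) + diag(lam, ncol(A)),
                         crossprod(A, -rl * rw)))
      })
    }
    # trust region on the physical variables
    cap <- max(abs(dz) / (10 * scale), 1)
    dz <- dz / cap
    lam <- 1
    improved <- FALSE
    while (lam >= 1e-5) {
      z2 <- z + lam * dz
      r2 <- tryCatch(res(z2), error = function(e) NULL)
      if (!is.null(r2) && rs_norm(r2) < rs_norm(r)) {
        z <- z2; r <- r2; improved <- TRUE; break
      }
      lam <- lam / 2
    }
    if (!improved) break   # no descent: keep the relaxed solution
  }
  if (rs_norm(r) >= max(1e-6 * r0, 1e-4))
    warning("solve_algebraic: scaled residual ", format(rs_norm(r), digits = 3),
            " (initial ", format(r0, digits = 3), ")")
  y[ai] <- z
  y
}
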