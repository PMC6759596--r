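# Time integration and observable extraction.

# flatten a model into plain vectors with 0-based indices for the compiled RHS
cpp_pack <- function(model) {
  p <- model$params
  prm <- c(T = p$T, eps_cell = p$eps_cell, eps_wall = p$eps_wall,
           P_turgor0 = p$P_turgor0,
           K_Ca = p$K_Ca, kir_Vhalf = p$kir_Vhalf, kir_slope = p$kir_slope,
           kor_offset = p$kor_offset, kor_slope = p$kor_slope,
           K_cyt_ref = p$K_cyt_ref, P_H_pm = p$P_H_pm, P_H_ton = p$P_H_ton,
           k_chx = p$k_chx,
           pump_zt = p$pump_zt,
           khsym_zt = p$khsym_zt, clhsym_zt = p$clhsym_zt,
           vpump_zt = p$vpump_zt)
  z <- function(v) as.integer(v - 1L)
  list(
    n = model$n_comp,
    ground = if (is.na(model$ground)) -1L else as.integer(model$ground - 1L),
    living = as.integer(model$living),
    kind = as.integer(model$kind),
    V0 = model$V0, A_amt = model$A_amt, B_amt = model$B_amt, K_b = model$K_b,
    vac_of = as.integer(ifelse(is.na(model$vac_of), -1L, model$vac_of - 1L)),
    V0_cell = model$V0_cell,
    prm = prm,
    pump_rates = p$pump_rates, khsym_rates = p$khsym_rates,
    clhsym_rates = p$clhsym_rates, vpump_rates = p$vpump_rates,
    P_top = model$P_top,
    ap = list(a = z(model$ap$a), b = z(model$ap$b), area = model$ap$area,
              L = model$ap$L, kh = model$ap$kh, D = model$ap$D),
    pd = list(a = z(model$pd$a), b = z(model$pd$b), area = model$pd$area,
              L = model$pd$L, Lp = model$pd$Lp, sigma = model$pd$sigma,
              D = model$pd$D),
    ext = list(a = z(model$ext$a), area = model$ext$area, L = model$ext$L,
               kh = model$ext$kh, D = model$ext$D),
    top = list(a = z(model$top$a), area = model$top$area, L = model$top$L,
               kh = model$top$kh),
    pm = list(cyt = z(model$pm$cyt), apo = z(model$pm$apo),
              area = model$pm$area, P_nscc = model$pm$P_nscc,
              P_kir = model$pm$P_kir, P_kor = model$pm$P_kor,
              P_hkt = model$pm$P_hkt, P_anion = model$pm$P_anion,
              N_pump = model$pm$N_pump, N_khsym = model$pm$N_khsym,
              N_clhsym = model$pm$N_clhsym, k_ap = model$pm$k_ap,
              Lp = model$pm$Lp, sigma = model$pm$sigma),
    ton = list(cyt = z(model$ton$cyt), vac = z(model$ton$vac),
               area = model$ton$area, P_Na = model$ton$P_Na,
               P_K = model$ton$P_K, P_Cl = model$ton$P_Cl,
               N_vpump = model$ton$N_vpump, k_nhx = model$ton$k_nhx,
               k_khton = model$ton$k_khton, Lp = model$ton$Lp,
               sigma = model$ton$sigma)
  )
}

bc_vec <- function(bc) {
  c(bc$Na, bc$K, bc$Cl, bc$H, bc$Ca, if (is.null(bc$P_ext)) 0 else bc$P_ext)
}

# right-hand-side closure for a fixed boundary medium
rhs_fun <- function(model, bc, use_cpp = TRUE) {
  bc <- validate_medium(bc)
  if (use_cpp) {
    ptr <- sr_make_pack(cpp_pack(model))
    b6 <- bc_vec(bc)
    function(t, y) sr_rhs_pack(t, y, ptr, b6)
  } else {
    function(t, y) assemble_residual(t, y, model, bc)
  }
}

integrate_segment <- function(model, bc, y0, times, rtol = 1e-6,
                              atol = NULL, use_cpp = TRUE, maxsteps = 50000,
                              hini = 0.1, partial_ok = FALSE) {
  f <- rhs_fun(model, bc, use_cpp = use_cpp)
  if (is.null(atol)) atol <- model$atol
  s <- model$sscale
  if (use_cpp) {
    ptr <- sr_make_pack(cpp_pack(model))
    sr_use_pack(ptr, bc_vec(validate_medium(bc)), s)
    out <- deSolve::radau(
      y = y0 / s, times = times, func = "sr_derivs", dllname = "saltroot",
      initfunc = NULL, parms = NULL,
      rtol = rtol, atol = atol / s,
      mass = matrix(model$mass, nrow = 1), massup = 0, massdown = 0,
      jactype = "bandint", bandup = model$bw, banddown = model$bw,
      maxsteps = maxsteps, hini = hini
    )
  } else {
    func <- function(t, ys, parms) list(f(t, ys * s) / s)
    out <- deSolve::radau(
      y = y0 / s, times = times, func = func, parms = NULL,
      rtol = rtol, atol = atol / s,
      mass = matrix(model$mass, nrow = 1), massup = 0, massdown = 0,
      jactype = "bandint", bandup = model$bw, banddown = model$bw,
      maxsteps = maxsteps, hini = hini
    )
  }
  out[, -1] <- sweep(out[, -1, drop = FALSE], 2, s, "*")
  got <- out[, 1]
  if (!partial_ok && max(got) < max(times) * (1 - 1e-12) - 1e-9)
    stop("integrator stopped at t = ", format(max(got), digits = 6),
         " s of requested ", format(max(times), digits = 6),
         " s; last accepted state retained in the error condition",
         call. = FALSE)
  out
}

# scaled rate of change of the differential slots (1/s)
state_rate <- function(model, bc, y, use_cpp = TRUE) {
  dy <- rhs_fun(model, bc, use_cpp = use_cpp)(0, y)
  n <- model$n_comp
  sel <- which(model$mass > 0)
  floors <- rep(1e-3, 6 * n)
  vslots <- slot_of(seq_len(n), 5L)
  floors[vslots] <- model$V0
  max(abs(dy[sel]) / pmax(abs(y[sel]), floors[sel]))
}

#' Relax the model to its pre-salt steady state
#'
#' Integrates from the documented uniform initial state (see
#' [initial_state()]) under the pre-salt medium until the scaled rate of
#' change of every differential variable falls below `rate_tol` (1/s),
#' using geometrically growing integration windows.
#'
#' @param model An `sr_model`.
#' @param bc Pre-salt boundary medium.
#' @param y0 Optional starting state (a consistent state from
#'   [initialize_model()]); when `NULL` the model is initialized first. In
#'   that case the updated model is attached to the result as
#'   `attr(, "model")` (the anion pools are part of the model).
#' @param rate_tol Convergence threshold on the scaled state rate (1/s).
#' @param t_max Maximum simulated relaxation time (s).
#' @param rtol,use_cpp Solver controls.
#' @return The relaxed state vector, with the achieved rate in
#'   `attr(, "rate")` and the updated model in `attr(, "model")`.
#' @export
solve_presalt_steady_state <- function(model, bc, y0 = NULL,
                                       rate_tol = 1e-9, t_max = 2e9,
                                       rtol = 1e-6, use_cpp = TRUE) {
  bc <- validate_medium(bc)
  if (is.null(y0)) {
    ini <- initialize_model(model, bc)
    model <- ini$model
    y0 <- ini$y
  }
  y <- y0
  rate <- state_rate(model, bc, y, use_cpp = use_cpp)
  if (rate >= rate_tol) {
    # grow the horizon geometrically and stop at the first converged state;
    # a chunk that stalls short of its end is acceptable if a reached state
    # already satisfies the criterion
    tt <- 10^seq(2, log10(t_max), length.out = 14)
    t_prev <- 0
    for (t_next in tt) {
      out <- suppressWarnings(
        integrate_segment(model, bc, y, c(t_prev, t_next), rtol = rtol,
                          use_cpp = use_cpp, maxsteps = 2e5,
                          partial_ok = TRUE))
      ylast <- as.numeric(out[nrow(out), -1])
      if (any(!is.finite(ylast))) break
      y <- ylast
      t_prev <- out[nrow(out), 1]
      rate <- state_rate(model, bc, y, use_cpp = use_cpp)
      if (rate < rate_tol || t_prev < t_next * (1 - 1e-9)) break
    }
  }
  if (rate >= rate_tol)
    stop("solve_presalt_steady_state: no steady state within ",
         format(t_max, digits = 3), " s; final scaled rate ",
         format(rate, digits = 3), " 1/s")
  attr(y, "rate") <- rate
  attr(y, "model") <- model
  y
}

#' Define a salt-step protocol
#'
#' @param pre_medium,salt_medium Boundary media before and after the salt
#'   step (see [make_medium()], [medium_preset()]).
#' @param salt_onset Time of the medium switch (s) measured from the start
#'   of the protocol.
#' @param duration Total protocol duration (s), > 0.
#' @param times Output time grid (s); defaults to a grid that is dense just
#'   after the salt step and daily afterwards.
#' @return A `sr_protocol` list.
#' @export
make_protocol <- function(pre_medium, salt_medium, salt_onset = 0,
                          duration = 86400, times = NULL) {
  if (duration <= 0) stop("protocol: duration must be > 0")
  if (is.null(times)) {
    post <- salt_onset + unique(c(0, 10^seq(1, log10(max(duration - salt_onset, 10)),
                                            length.out = 25)))
    times <- sort(unique(c(0, salt_onset, post, seq(0, duration, length.out = 16))))
    times <- times[times <= duration]
  }
  if (is.unsorted(times) || any(times < 0) || any(times > duration))
    stop("protocol: output times must be sorted within [0, duration]")
  structure(list(pre_medium = validate_medium(pre_medium),
                 salt_medium = validate_medium(salt_medium),
                 salt_onset = salt_onset, duration = duration,
                 times = times), class = "sr_protocol")
}

#' Run a salt-step protocol
#'
#' Stiff variable-order integration (Radau IIA with banded Jacobian and the
#' DAE mass matrix) of the model from a consistent state. The salt step is
#' applied as an instantaneous medium switch; the algebraic variables are
#' re-solved at the switch so every segment starts consistent.
#'
#' @param model An `sr_model` (with initialized anion pools; use the model
#'   attached to the steady state when in doubt).
#' @param state0 Consistent initial state (e.g. from
#'   [solve_presalt_steady_state()]).
#' @param protocol An `sr_protocol`.
#' @param rtol Relative tolerance.
#' @param use_cpp Use the compiled right-hand side.
#' @return An `sr_trajectory`: list with `times`, state matrix `Y` (one row
#'   per time), `model`, `protocol` and solver diagnostics.
#' @export
run_protocol <- function(model, state0, protocol, rtol = 1e-6,
                         use_cpp = TRUE) {
  if (!is.null(attr(state0, "model"))) model <- attr(state0, "model")
  on <- protocol$salt_onset
  tt <- protocol$times
  Y <- matrix(NA_real_, length(tt), 6 * model$n_comp)
  y <- as.numeric(state0)
  pre_t <- tt[tt <= on]
  diag_steps <- 0
  # one retry at a tighter tolerance if a segment fails outright
  robust_segment <- function(bc_seg, y_seg, seg) {
    tryCatch(
      integrate_segment(model, bc_seg, y_seg, seg, rtol = rtol,
                        use_cpp = use_cpp),
      error = function(e)
        integrate_segment(model, bc_seg, y_seg, seg, rtol = rtol / 5,
                          use_cpp = use_cpp, hini = 1e-3))
  }
  if (length(pre_t) > 0 && on > 0) {
    seg <- unique(c(0, pre_t))
    out <- robust_segment(protocol$pre_medium, y, seg)
    Y[tt <= on, ] <- out[match(pre_t, out[, 1]), -1, drop = FALSE]
    y <- as.numeric(out[nrow(out), -1])
    diag_steps <- diag_steps + attr(out, "istate")[3]
  } else if (length(pre_t) > 0) {
    Y[tt <= on, ] <- matrix(y, length(pre_t), length(y), byrow = TRUE)
  }
  # medium switch: re-solve algebraic variables for consistency
  y <- solve_algebraic(model, protocol$salt_medium, y, use_cpp = use_cpp)
  post_t <- tt[tt > on]
  if (length(post_t) > 0) {
    seg <- unique(c(on, post_t))
    out <- robust_segment(protocol$salt_medium, y, seg)
    Y[tt > on, ] <- out[match(post_t, out[, 1]), -1, drop = FALSE]
    diag_steps <- diag_steps + attr(out, "istate")[3]
  }
  structure(list(times = tt, Y = Y, model = model, protocol = protocol,
                 diagnostics = list(steps = diag_steps, rtol = rtol)),
            class = "sr_trajectory")
}

#' @export
print.sr_trajectory <- function(x, ...) {
  cat("saltroot trajectory:", length(x$times), "snapshots over",
      format(max(x$times) / 86400, digits = 3), "days\n")
  invisible(x)
}

snapshot_index <- function(traj, t) {
  i <- which.min(abs(traj$times - t))
  if (abs(traj$times[i] - t) > 1e-6 * max(t, 1) + 1e-9)
    warning("requested time ", t, " s not on the output grid; using nearest ",
            traj$times[i], " s")
  i
}

medium_at <- function(traj, t) {
  if (t >= traj$protocol$salt_onset) traj$protocol$salt_medium
  else traj$protocol$pre_medium
}

snapshot_detail <- function(traj, t) {
  i <- snapshot_index(traj, t)
  y <- traj$Y[i, ]
  assemble_residual(traj$times[i], y, traj$model, medium_at(traj, t),
                    detail = TRUE)
}

state_mat <- function(traj, t) {
  i <- snapshot_index(traj, t)
  matrix(traj$Y[i, ], nrow = 6L)
}

#' Root ion content per fresh weight
#'
#' Total amount of a species over every root compartment divided by the
#' root fresh weight.
#'
#' @param traj An `sr_trajectory`.
#' @param t Time (s), must be on the output grid.
#' @param species `"Na"`, `"K"`, `"Cl"` or `"H"`.
#' @return Content in mol per kg fresh weight.
#' @export
root_ion_content_per_fw <- function(traj, t, species = "Na") {
  s <- match.arg(species, c("Na", "K", "Cl", "H"))
  Y <- state_mat(traj, t)
  m <- traj$model
  sum(Y[match(s, c("Na", "K", "Cl", "H")), ] * Y[5, ]) /
    m$geometry$fresh_weight
}

#' Species flux to the shoot
#'
#' Advective-diffusive flux of a species through the top of the xylem
#' conduit, positive toward the shoot.
#'
#' @inheritParams root_ion_content_per_fw
#' @param per_fw Normalize by root fresh weight (mol s-1 kg-1); see
#'   [mol_s_kg_to_nmol_min_g()] for the conventional reporting unit.
#' @return Flux in mol s-1 (or mol s-1 kg-1).
#' @export
flux_to_shoot <- function(traj, t, species = "Na", per_fw = FALSE) {
  s <- match(match.arg(species, c("Na", "K", "Cl", "H")),
             c("Na", "K", "Cl", "H"))
  d <- snapshot_detail(traj, t)
  f <- sum(d$det$top$Js[[s]])
  if (per_fw) f / traj$model$geometry$fresh_weight else f
}

#' Water flux to the shoot
#'
#' @inheritParams root_ion_content_per_fw
#' @return Volumetric flow through the top of the xylem (m3 s-1), positive
#'   toward the shoot.
#' @export
water_flux_to_shoot <- function(traj, t) {
  d <- snapshot_detail(traj, t)
  sum(d$det$top$q)
}

#' Epidermal trans-membrane potential
#'
#' `phi_cytosol - phi_apoplast` of an epidermal cell.
#'
#' @inheritParams root_ion_content_per_fw
#' @param layer Axial layer (0-based); defaults to the middle of the mature
#'   zone.
#' @return Potential (V), negative at rest.
#' @export
epidermal_membrane_potential <- function(traj, t, layer = NULL) {
  m <- traj$model
  if (is.null(layer))
    layer <- m$geometry$apex_layers +
      (m$geometry$n_axial - m$geometry$apex_layers) %/% 2
  Y <- state_mat(traj, t)
  comp <- m$comp
  cyt <- comp$idx[comp$layer == layer & comp$tissue == "epidermis" &
                    comp$kind == "cytosol"]
  apo <- comp$idx[comp$layer == layer & comp$tissue == "epidermis" &
                    comp$kind == "apoplast"]
  if (length(cyt) != 1 || length(apo) != 1)
    stop("epidermal_membrane_potential: no epidermal cell in layer ", layer)
  Y[6, cyt] - Y[6, apo]
}

#' Volume-weighted mean cytosolic concentration in a zone
#'
#' @inheritParams root_ion_content_per_fw
#' @param zone `"mature"` or `"apex"`.
#' @return Concentration (mol m-3).
#' @export
mean_cytosolic_concentration <- function(traj, t, zone = "mature",
                                         species = "Na") {
  zone <- match.arg(zone, c("mature", "apex"))
  s <- match(match.arg(species, c("Na", "K", "Cl", "H")),
             c("Na", "K", "Cl", "H"))
  m <- traj$model
  Y <- state_mat(traj, t)
  sel <- m$comp$kind == "cytosol" & m$comp$zone == zone
  if (!any(sel)) stop("no cytosols in zone ", zone)
  V <- Y[5, sel]
  sum(Y[s, sel] * V) / sum(V)
}

zone_fresh_weight <- function(model, zone) {
  sel <- model$comp$zone == zone
  sum(model$comp$V0[sel]) * sr_const$rho_w
}

#' Net species efflux across the external surface of a root zone
#'
#' Net flux of a species from the root into the external medium across the
#' epidermal surface of one developmental zone, normalized by the zone
#' fresh weight. Positive = efflux.
#'
#' @inheritParams mean_cytosolic_concentration
#' @return Efflux in mol s-1 per kg FW of the zone.
#' @export
zone_surface_efflux <- function(traj, t, zone = "mature", species = "Na") {
  zone <- match.arg(zone, c("mature", "apex"))
  s <- match(match.arg(species, c("Na", "K", "Cl", "H")),
             c("Na", "K", "Cl", "H"))
  m <- traj$model
  d <- snapshot_detail(traj, t)
  lay <- m$comp$zone[d$det$ext$a] == zone
  sum(d$det$ext$Js[[s]][lay]) / zone_fresh_weight(m, zone)
}

#' Na+ loading into the xylem through plasma-membrane antiporters
#'
#' Summed Na+/H+ antiporter Na+ flux across mature xylem-parenchyma plasma
#' membranes, oriented positive toward the stelar apoplast and hence the
#' xylem transpiration stream. Negative values would indicate active
#' unloading.
#'
#' @inheritParams root_ion_content_per_fw
#' @param per_fw Normalize by the root fresh weight.
#' @return Flux in mol s-1 (or mol s-1 kg-1 FW).
#' @export
antiporter_xylem_loading <- function(traj, t, per_fw = FALSE) {
  m <- traj$model
  d <- snapshot_detail(traj, t)
  pm <- d$det$pm
  sel <- pm$tissue == "xylem_parenchyma" & pm$zone == "mature"
  f <- sum(pm$J_ap_Na[sel] * pm$area[sel])
  if (per_fw) f / m$geometry$fresh_weight else f
}

#' Net species influx across the entire external root surface
#'
#' Conservation counterpart of [flux_to_shoot()]: at steady state the net
#' uptake across the root surface equals the flux leaving through the xylem
#' top, per species.
#'
#' @inheritParams root_ion_content_per_fw
#' @return Influx in mol s-1 (positive into the root).
#' @export
surface_influx <- function(traj, t, species = "Na") {
  s <- match(match.arg(species, c("Na", "K", "Cl", "H")),
             c("Na", "K", "Cl", "H"))
  d <- snapshot_detail(traj, t)
  -sum(d$det$ext$Js[[s]])
}

#' Net water uptake across the external root surface
#'
#' @inheritParams root_ion_content_per_fw
#' @return Volumetric uptake (m3 s-1, positive into the root).
#' @export
surface_water_influx <- function(traj, t) {
  d <- snapshot_detail(traj, t)
  -sum(d$det$ext$q)
}

#' Serialize a state snapshot as a tidy table
#'
#' @inheritParams root_ion_content_per_fw
#' @return A data.frame with columns `compartment`, `kind`, `layer`,
#'   `ring`, `tissue`, `zone`, `species`, `value` covering the four ion
#'   concentrations (mol m-3), volume (m3), potential (V).
#' @export
state_table <- function(traj, t) {
  m <- traj$model
  Y <- state_mat(traj, t)
  comp <- m$comp
  species <- c("Na", "K", "Cl", "H", "volume_or_pressure", "phi")
  do.call(rbind, lapply(1:6, function(s) {
    data.frame(compartment = comp$idx, kind = comp$kind, layer = comp$layer,
               ring = comp$ring, tissue = comp$tissue, zone = comp$zone,
               species = species[s], value = Y[s, ],
               stringsAsFactors = FALSE)
  }))
}

#' Export observable time series as a tidy CSV
#'
#' @param traj An `sr_trajectory`.
#' @param path Output path.
#' @param times Times to evaluate (default: the trajectory grid).
#' @return The table, invisibly; written to `path`.
#' @export
write_observables_csv <- function(traj, path, times = traj$times) {
  rows <- lapply(times, function(t) {
    data.frame(
      time_s = t,
      observable = c("root_Na_content", "root_K_content", "Na_flux_to_shoot",
                     "water_flux_to_shoot", "epidermal_potential",
                     "cyt_Na_mature", "cyt_Na_apex"),
      value = c(root_ion_content_per_fw(traj, t, "Na"),
                root_ion_content_per_fw(traj, t, "K"),
                mol_s_kg_to_nmol_min_g(flux_to_shoot(traj, t, "Na", per_fw = TRUE)),
                water_flux_to_shoot(traj, t),
                epidermal_membrane_potential(traj, t),
                mean_cytosolic_concentration(traj, t, "mature", "Na"),
                mean_cytosolic_concentration(traj, t, "apex", "Na")),
      units = c("mol/kgFW", "mol/kgFW", "nmol/min/gFW", "m3/s", "V",
                "mol/m3", "mol/m3"),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

#' Xylem sap concentration
#'
#' Volume-weighted mean concentration in the mature xylem conduit
#' (apoplastic) compartments, the model counterpart of xylem sap sampled
#' from intact plants.
#'
#' @inheritParams root_ion_content_per_fw
#' @return Concentration (mol m-3).
#' @export
xylem_concentration <- function(traj, t, species = "Na") {
  s <- match(match.arg(species, c("Na", "K", "Cl", "H")),
             c("Na", "K", "Cl", "H"))
  m <- traj$model
  Y <- state_mat(traj, t)
  sel <- m$comp$tissue == "xylem" & m$comp$zone == "mature" &
    m$comp$kind == "apoplast"
  if (!any(sel)) stop("xylem_concentration: no mature xylem compartments")
  sum(Y[s, sel] * Y[5, sel]) / sum(Y[5, sel])
}
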