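# Time integration, protocols and observables.

test_that("a fully passive-free system stays at its initial guess", {
  cfg <- toy_config()
  cfg$geometry <- list(n_axial = 2L, apex_layers = 1L)
  for (nm in c("P_nscc", "P_kir", "P_kor", "P_hkt", "P_anion_outer",
               "P_anion_stele", "P_H_pm", "P_H_ton", "N_pump", "N_khsym",
               "N_clhsym", "k_chx", "k_ap_outer", "k_ap_stele", "P_ton_K",
               "P_ton_Na", "P_ton_Cl", "N_vpump", "k_nhx", "k_khton",
               "Lp_pm", "Lp_ton", "Lp_pd", "k_h_wall", "k_h_xylem",
               "k_h_surface"))
    cfg$params[[nm]] <- 0
  cfg$params$D_Na <- 0; cfg$params$D_K <- 0; cfg$params$D_Cl <- 0
  cfg$params$D_H <- 0
  model <- build_model(cfg)
  bc <- presalt_medium(medium_preset("flux_content"))
  ini <- initialize_model(model, bc)
  ss <- solve_presalt_steady_state(ini$model, bc, y0 = ini$y)
  expect_equal(as.numeric(ss), as.numeric(ini$y), tolerance = 1e-12)
})

test_that("the pre-salt steady state satisfies its own definition", {
  ss <- toy_steady()
  expect_lt(attr(ss, "rate"), 1e-9)
  model <- attr(ss, "model")
  bc <- presalt_medium(medium_preset("flux_content"))
  # membrane potential has the physiological orientation at rest
  Y <- matrix(as.numeric(ss), nrow = 6)
  cyt <- model$kind == 1; apo <- model$comp$ring == 0 & model$kind == 0
  expect_true(all(Y[6, cyt] < 0))
  # volumes stayed positive
  expect_true(all(Y[5, ] > 0))
})

test_that("steady state is independent of the documented initial guesses", {
  ss1 <- toy_steady()
  model <- build_model(toy_config())
  bc <- presalt_medium(medium_preset("flux_content"))
  y0 <- initial_state(model, bc, guess = list(phi_apo = -0.02,
                                              phi_cyt = -0.08,
                                              phi_vac = -0.06))
  model$A_amt <- attr(y0, "A_amt"); attr(y0, "A_amt") <- NULL
  ini <- initialize_model(model, bc, y = y0)
  ss2 <- solve_presalt_steady_state(model, bc, y0 = ini$y)
  sel <- which(matrix(TRUE, 6, attr(ss1, "model")$n_comp)[1:4, , drop = FALSE])
  Y1 <- matrix(as.numeric(ss1), nrow = 6)[1:4, ]
  Y2 <- matrix(as.numeric(ss2), nrow = 6)[1:4, ]
  expect_lt(max(abs(Y1 - Y2) / pmax(abs(Y2), 1e-3)), 1e-5)
})

test_that("a no-perturbation protocol stays at the steady state", {
  ss <- toy_steady()
  model <- attr(ss, "model")
  bc <- presalt_medium(medium_preset("flux_content"))
  traj <- run_protocol(model, ss, make_protocol(pre_medium = bc,
                                                salt_medium = bc,
                                                duration = 86400))
  Y0 <- matrix(as.numeric(ss), nrow = 6)
  YT <- saltroot:::state_mat(traj, 86400)
  expect_lt(max(abs(YT[1:4, ] - Y0[1:4, ]) / pmax(abs(Y0[1:4, ]), 1e-3)), 1e-4)
})

test_that("protocol validation and construction", {
  bc <- presalt_medium(medium_preset("flux_content"))
  expect_error(make_protocol(bc, bc, duration = -1), "duration")
  expect_error(make_protocol(bc, bc, duration = 10, times = c(5, 2)), "sorted")
  pr <- make_protocol(bc, medium_preset("flux_content"), duration = 3600)
  expect_true(all(diff(pr$times) > 0))
  expect_equal(max(pr$times), 3600)
})

test_that("salt step depolarizes the epidermis with a fast step response", {
  ss <- toy_steady("potentials")
  med <- medium_preset("potentials")
  traj <- run_salt(ss, med, days = 1, rtol = 1e-6)
  v0 <- epidermal_membrane_potential(traj, 0)
  tt <- traj$times[traj$times > 0]
  vt <- vapply(tt, function(t) epidermal_membrane_potential(traj, t), 0)
  # substantial depolarization relative to rest
  expect_gt(max(vt) - v0, 0.02)
  # step-response character: most of the day-scale change happens within
  # the first hour of exposure
  v1h <- vt[which.min(abs(tt - 3600))]
  expect_gt(v1h - v0, 0.5 * (vt[length(tt)] - v0))
  # the stressed membrane stays polarized (between rest and zero)
  expect_lt(vt[length(tt)], 0)
  expect_gt(vt[length(tt)], v0)
})

test_that("ion content per fresh weight matches a direct summation oracle", {
  ss <- toy_steady()
  model <- attr(ss, "model")
  bc <- presalt_medium(medium_preset("flux_content"))
  traj <- run_protocol(model, ss, make_protocol(pre_medium = bc,
    salt_medium = medium_preset("flux_content"), duration = 7200))
  tab <- state_table(traj, 7200)
  for (sp in c("Na", "K", "Cl")) {
    vols <- tab$value[tab$species == "volume_or_pressure"]
    conc <- tab$value[tab$species == sp]
    oracle <- sum(conc * vols) / model$geometry$fresh_weight
    expect_equal(root_ion_content_per_fw(traj, 7200, sp), oracle,
                 tolerance = 1e-12)
  }
  # uniform-state sanity: content of a synthetic uniform snapshot
  traj2 <- traj
  Y <- matrix(traj$Y[length(traj$times), ], nrow = 6)
  Y[1, ] <- 10
  traj2$Y[length(traj$times), ] <- as.numeric(Y)
  V <- Y[5, ]
  expect_equal(root_ion_content_per_fw(traj2, 7200, "Na"),
               10 * sum(V) / model$geometry$fresh_weight)
})

test_that("flux to the shoot equals surface influx at steady state", {
  ss <- toy_steady()
  model <- attr(ss, "model")
  bc <- presalt_medium(medium_preset("flux_content"))
  traj <- run_protocol(model, ss, make_protocol(pre_medium = bc,
                                                salt_medium = bc,
                                                duration = 1000))
  for (sp in c("Na", "K", "Cl")) {
    fs <- flux_to_shoot(traj, 0, sp)
    si <- surface_influx(traj, 0, sp)
    expect_lt(abs(fs - si) / max(abs(fs), abs(si), 1e-30), 1e-6)
  }
  expect_lt(abs(water_flux_to_shoot(traj, 0) - surface_water_influx(traj, 0)) /
              abs(water_flux_to_shoot(traj, 0)), 1e-6)
})

test_that("epidermal potential equals the difference of stored potentials", {
  ss <- toy_steady()
  model <- attr(ss, "model")
  bc <- presalt_medium(medium_preset("flux_content"))
  traj <- run_protocol(model, ss, make_protocol(pre_medium = bc,
                                                salt_medium = bc,
                                                duration = 10))
  layer <- 4
  Y <- saltroot:::state_mat(traj, 10)
  comp <- model$comp
  cyt <- comp$idx[comp$layer == layer & comp$tissue == "epidermis" &
                    comp$kind == "cytosol"]
  apo <- comp$idx[comp$layer == layer & comp$tissue == "epidermis" &
                    comp$kind == "apoplast"]
  expect_equal(epidermal_membrane_potential(traj, 10, layer),
               Y[6, cyt] - Y[6, apo])
  expect_lt(epidermal_membrane_potential(traj, 10), 0)
})

test_that("zone means and surface effluxes pass their partition identities", {
  ss <- toy_steady()
  model <- attr(ss, "model")
  bc <- presalt_medium(medium_preset("flux_content"))
  traj <- run_protocol(model, ss, make_protocol(pre_medium = bc,
    salt_medium = medium_preset("flux_content"), duration = 3600))
  # volume-weighted mean against a direct recomputation
  Y <- saltroot:::state_mat(traj, 3600)
  sel <- model$comp$kind == "cytosol" & model$comp$zone == "mature"
  oracle <- sum(Y[1, sel] * Y[5, sel]) / sum(Y[5, sel])
  expect_equal(mean_cytosolic_concentration(traj, 3600, "mature", "Na"),
               oracle, tolerance = 1e-12)
  # zone effluxes weighted by zone FW sum to the whole-root surface flux
  fw_a <- saltroot:::zone_fresh_weight(model, "apex")
  fw_m <- saltroot:::zone_fresh_weight(model, "mature")
  total <- zone_surface_efflux(traj, 3600, "apex", "Na") * fw_a +
    zone_surface_efflux(traj, 3600, "mature", "Na") * fw_m
  expect_equal(total, -surface_influx(traj, 3600, "Na"), tolerance = 1e-12)
})

test_that("antiporter xylem loading vanishes without stelar antiporters", {
  cfg <- set_scenario(toy_config(), pattern = "mature_epidermis", k_ap = 1e-6)
  model <- build_model(cfg)
  bc <- presalt_medium(medium_preset("flux_content"))
  ss <- solve_presalt_steady_state(model, bc, rate_tol = 1e-7)
  traj <- run_protocol(attr(ss, "model"), ss, make_protocol(pre_medium = bc,
    salt_medium = medium_preset("flux_content"), duration = 3600))
  expect_equal(antiporter_xylem_loading(traj, 3600), 0)
})

test_that("unit conversions round-trip", {
  x <- c(1e-7, 3.2e-6, 5)
  expect_equal(nmol_min_g_to_mol_s_kg(mol_s_kg_to_nmol_min_g(x)), x)
  expect_equal(mol_s_kg_to_nmol_min_g(1e-6), 60)
  expect_equal(umol_g_to_mol_kg(mol_kg_to_umol_g(x)), x)
  expect_equal(conc_to_ph(ph_to_conc(5.5)), 5.5)
})

test_that("observable time series export as tidy CSV", {
  ss <- toy_steady()
  model <- attr(ss, "model")
  bc <- presalt_medium(medium_preset("flux_content"))
  traj <- run_protocol(model, ss, make_protocol(pre_medium = bc,
    salt_medium = medium_preset("flux_content"), duration = 600,
    times = c(0, 600)))
  path <- tempfile(fileext = ".csv")
  tab <- write_observables_csv(traj, path, times = c(0, 600))
  expect_true(file.exists(path))
  expect_setequal(names(tab), c("time_s", "observable", "value", "units"))
  expect_equal(nrow(tab), 14)
})
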