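# SOS1 scenario enumeration, strength grid, sweep, classification.

test_that("the scenario list enumerates exactly the six printed groups", {
  sc <- enumerate_scenarios()
  expect_equal(nrow(sc), 17)
  expect_equal(sum(sc$group == "mature_individual"), 4)
  expect_equal(sum(sc$group == "apex_individual"), 5)
  expect_equal(sum(sc$group == "mature_combination"), 4)
  expect_equal(sum(sc$group == "mature_apex_combination"), 2)
  expect_equal(sum(sc$group == "apex_all"), 1)
  expect_equal(sum(sc$group == "all_tissues"), 1)
  expect_true("apex_nonfunctional_xylem" %in% sc$name)
  expect_false(any(duplicated(sc$name)))
})

test_that("mature patterns carry no apex antiporters and vice versa", {
  sc <- enumerate_scenarios()
  for (nm in sc$name[startsWith(sc$name, "mature_")]) {
    m <- scenario_antiporter_map(nm)
    expect_false(any(m["apex", ]), info = nm)
  }
  for (nm in c("apex_epidermis", "apex_cortex", "apex_endodermis",
               "apex_xylem_parenchyma", "apex_nonfunctional_xylem",
               "apex_all")) {
    m <- scenario_antiporter_map(nm)
    expect_false(any(m["mature", ]), info = nm)
  }
  m <- scenario_antiporter_map("apex_epidermis_mature_xylem_parenchyma")
  expect_true(m["apex", "epidermis"] && m["mature", "xylem_parenchyma"])
  expect_equal(sum(m), 2)
  expect_error(scenario_antiporter_map("bogus"), "unknown scenario")
})

test_that("the strength grid is the printed four-point decade ladder", {
  g <- strength_grid()
  expect_equal(g, c(1e-8, 1e-7, 1e-6, 1e-5))
  expect_true(all(diff(g) > 0))
})

test_that("classification against wild-type references is inclusive at 50%", {
  ref <- list(content = 0.04, flux = 58)
  expect_true(classify_reasonable(list(content = 0.04, flux = 58), ref))
  expect_true(classify_reasonable(list(content = 0.06, flux = 58), ref))
  expect_false(classify_reasonable(list(content = 0.04 * 1.51, flux = 58), ref))
  expect_false(classify_reasonable(list(content = 0.04, flux = 58 * 0.4), ref))
  # exactly 1.5x is inside (inclusive reading of "within 50%")
  expect_true(classify_reasonable(list(content = 0.06, flux = 87), ref))
  expect_error(classify_reasonable(list(content = 1, flux = 1),
                                   list(content = -1, flux = 1)), "positive")
  # invariance to the unit system (same relative deviations)
  s <- 1e3
  expect_equal(classify_reasonable(list(content = 0.05, flux = 70), ref),
               classify_reasonable(list(content = 0.05 * s, flux = 70 * s),
                                   list(content = ref$content * s,
                                        flux = ref$flux * s)))
})

test_that("a 1x1 sweep reproduces a direct pipeline run", {
  cfg <- toy_config()
  med <- medium_preset("cytosolic_100")
  tab <- run_sweep(cfg, patterns = "mature_all", strengths = 1e-6,
                   medium = med, duration = 7200)
  expect_equal(nrow(tab), 1)
  expect_true(tab$ok)
  cfg2 <- set_scenario(cfg, "mature_all", k_ap = 1e-6)
  model <- build_model(cfg2)
  bc0 <- presalt_medium(med)
  ss <- solve_presalt_steady_state(model, bc0)
  traj <- run_protocol(attr(ss, "model"), ss, make_protocol(
    pre_medium = bc0, salt_medium = med, duration = 7200))
  expect_equal(tab$content_Na, root_ion_content_per_fw(traj, 7200, "Na"),
               tolerance = 1e-8)
  expect_equal(tab$flux_Na,
               mol_s_kg_to_nmol_min_g(flux_to_shoot(traj, 7200, "Na",
                                                    per_fw = TRUE)),
               tolerance = 1e-6)
})

test_that("sweeps have one row per combination and record failures per row", {
  cfg <- toy_config()
  tab <- run_sweep(cfg, patterns = c("mature_epidermis", "apex_all"),
                   strengths = c(0, 1e-7),
                   medium = medium_preset("cytosolic_100"), duration = 3600)
  expect_equal(nrow(tab), 4)
  # zero-strength rows coincide across patterns (patterns inert at k_ap = 0)
  z <- tab[tab$strength == 0, ]
  expect_equal(z$content_Na[1], z$content_Na[2], tolerance = 1e-8)
  expect_equal(z$flux_Na[1], z$flux_Na[2], tolerance = 1e-8)
  # a broken configuration is flagged, not fatal
  cfg_bad <- cfg
  cfg_bad$params$P_nscc <- -1
  tab2 <- run_sweep(cfg_bad, patterns = "all", strengths = 1e-7,
                    medium = medium_preset("cytosolic_100"), duration = 3600)
  expect_false(tab2$ok)
  expect_true(nzchar(tab2$message))
})

test_that("the sos1 genotype applies the residual-activity scaling", {
  cfg <- set_scenario(toy_config(), "all", genotype = "sos1")
  model <- build_model(cfg)
  cfg_wt <- set_scenario(toy_config(), "all", genotype = "wild_type")
  model_wt <- build_model(cfg_wt)
  frac <- cfg$params$sos1_residual_frac
  expect_equal(model$pm$k_ap, model_wt$pm$k_ap * frac)
  expect_true(all(model$pm$k_ap[model_wt$pm$k_ap > 0] > 0))
  expect_error(set_scenario(toy_config(), "all", k_ap = -1), "k_ap")
})
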