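# System assembly: residual structure, conservation, consistency of the
# reference and compiled right-hand sides, electroneutral initialization.

test_that("compiled and reference residuals agree elementwise", {
  cfg <- toy_config()
  model <- build_model(cfg)
  bc <- presalt_medium(medium_preset("flux_content"))
  ini <- initialize_model(model, bc)
  model <- ini$model; y <- ini$y
  f_cpp <- saltroot:::rhs_fun(model, bc, use_cpp = TRUE)
  set.seed(5)
  for (i in 1:5) {
    yp <- y * (1 + stats::runif(length(y), -0.05, 0.05))
    dr <- assemble_residual(0, yp, model, saltroot:::validate_medium(bc))
    dc <- f_cpp(0, yp)
    expect_lt(max(abs(dr - dc)) / max(abs(dr)), 1e-10)
  }
})

test_that("closed system conserves every species by construction", {
  cfg <- toy_config()
  cfg$closed <- TRUE
  model <- build_model(cfg)
  bc <- presalt_medium(medium_preset("flux_content"))
  ini <- initialize_model(model, bc)
  model <- ini$model; y <- ini$y
  set.seed(9)
  for (rep in 1:4) {
    yp <- y * (1 + stats::runif(length(y), -0.1, 0.1))
    dy <- assemble_residual(0, yp, model, saltroot:::validate_medium(bc))
    Y <- matrix(yp, nrow = 6); dY <- matrix(dy, nrow = 6)
    V <- Y[5, ]; dV <- dY[5, ]
    for (s in 1:4) {
      damount <- V * dY[s, ] + Y[s, ] * dV
      gross <- sum(abs(damount))
      expect_lt(abs(sum(damount)), 1e-12 * max(gross, 1e-30))
    }
  }
})

test_that("residual errors name the offending compartment", {
  model <- build_model(toy_config())
  bc <- saltroot:::validate_medium(presalt_medium(medium_preset("flux_content")))
  y <- initial_state(model, bc)
  y[1] <- NaN
  expect_error(assemble_residual(0, as.numeric(y), model, bc), "non-finite")
})

test_that("initialization yields an exactly electroneutral, consistent state", {
  model <- build_model(toy_config())
  bc <- presalt_medium(medium_preset("flux_content"))
  ini <- initialize_model(model, bc)
  model <- ini$model; y <- ini$y
  Y <- matrix(y, nrow = 6)
  V <- Y[5, ]
  Hf <- saltroot:::free_H(model, Y[4, ], V)
  Hb <- pmax(Y[4, ], 0) - Hf
  B <- model$B_amt / V
  r <- electroneutrality_residual(Y[1, ], Y[2, ], Y[3, ], Hf,
                                  B_total = B, H_bound = Hb,
                                  fixed_anion = model$A_amt / V)
  expect_lt(max(abs(r)), 1e-8)
  # algebraic rows solved (charge-balance rows are mol m-3 s-1; the raw
  # initial imbalance is of order 1e4, so 1e-3 is ~1e-7 relative)
  dy <- assemble_residual(0, y, model, saltroot:::validate_medium(bc))
  expect_lt(max(abs(dy[model$mass == 0])), 1e-3)
})

test_that("GHK-only single-membrane potential matches a root-finding oracle", {
  cfg <- toy_config()
  cfg$geometry <- list(n_axial = 2L, apex_layers = 2L)
  p <- cfg$params
  for (nm in c("P_kir", "P_kor", "P_hkt", "P_anion_outer", "P_anion_stele",
               "P_H_pm", "P_H_ton", "N_pump", "N_khsym", "N_clhsym",
               "k_chx", "P_ton_K", "P_ton_Na", "P_ton_Cl", "N_vpump",
               "k_nhx", "k_khton"))
    cfg$params[[nm]] <- 0
  cfg$distribution <- default_distribution(scenario_antiporter_map("none"))
  cfg$barriers <- list(passage_cell_fraction = 0)
  # fully isolate each cell so the scalar oracle is exact: no apoplastic or
  # symplastic coupling, identical wall charges everywhere
  cfg$params$D_Na <- 0; cfg$params$D_K <- 0; cfg$params$D_Cl <- 0
  cfg$params$D_H <- 0
  cfg$params$k_h_wall <- 0; cfg$params$k_h_surface <- 0
  cfg$params$k_h_xylem <- 0; cfg$params$Lp_pd <- 0
  cfg$params$xylem_wall_charge <- cfg$params$wall_charge
  model <- build_model(cfg)
  bc <- saltroot:::validate_medium(presalt_medium(medium_preset("flux_content")))
  ini <- initialize_model(model, bc)
  model <- ini$model; y <- ini$y
  Y <- matrix(y, nrow = 6)
  cyt <- which(model$kind == 1)[1]
  apo <- which(model$kind == 0 & model$comp$ring == 0)[1]
  Vm <- Y[6, cyt] - Y[6, apo]
  # oracle: scalar root of the summed NSCC charge flux with the same
  # concentrations (identical cells, so symplastic currents vanish)
  P_eff <- nscc_permeability(cfg$params$P_nscc, bc$Ca, cfg$params$K_Ca)
  f <- function(V) {
    ghk_flux(P_eff, 1, V, Y[1, cyt], Y[1, apo]) +
      ghk_flux(P_eff, 1, V, Y[2, cyt], Y[2, apo])
  }
  V_or <- stats::uniroot(f, c(-0.4, 0.2), tol = 1e-12)$root
  expect_equal(Vm, V_or, tolerance = 1e-5)
})

test_that("halving the axial step changes the steady xylem Na by < 5%", {
  med <- medium_preset("flux_content")
  xyl_na <- function(n_axial, apex_layers) {
    cfg <- toy_config()
    cfg$geometry <- list(n_axial = n_axial, apex_layers = apex_layers,
                         cell_height = 6e-4 / n_axial)
    model <- build_model(cfg)
    ss <- solve_presalt_steady_state(model, med, rate_tol = 1e-8)
    model <- attr(ss, "model")
    Y <- matrix(as.numeric(ss), nrow = 6)
    sel <- model$comp$tissue == "xylem" & model$comp$zone == "mature"
    top <- which(sel)[sum(sel)]
    Y[1, top]
  }
  a <- xyl_na(6L, 2L)
  b <- xyl_na(12L, 4L)
  expect_lt(abs(a - b) / abs(b), 0.05)
})
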