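# Membrane flux laws: closed-form checks against independent oracles.

test_that("GHK flux vanishes at the Nernst potential and has the V->0 limit", {
  for (z in c(1, -1)) {
    for (ratio in c(0.1, 1, 10)) {
      c_in <- 10; c_out <- c_in * ratio
      V_eq <- (sr_const$R * sr_const$Tref / (z * sr_const$F)) *
        log(c_out / c_in)
      expect_lt(abs(ghk_flux(1e-9, z, V_eq, c_in, c_out)), 1e-22)
    }
  }
  expect_equal(ghk_flux(1e-9, 1, 0, 25, 7), 1e-9 * (25 - 7), tolerance = 1e-12)
  # continuity through V = 0
  expect_equal(ghk_flux(1e-9, 1, 1e-12, 25, 7), ghk_flux(1e-9, 1, -1e-12, 25, 7),
               tolerance = 1e-6)
})

test_that("GHK flux matches a shooting solution of the constant-field problem", {
  # independent oracle: steady electrodiffusion across a slab with a linear
  # potential profile; c(L) is affine in the flux J, so two integrations of
  # the profile equation determine J to machine precision
  oracle <- function(D, z, V, c_in, c_out, L) {
    E <- -V / L   # field from inside (x=0) to outside (x=L)
    rhs <- function(x, c, J) list(-J / D + z * (sr_const$F /
      (sr_const$R * sr_const$Tref)) * c * V / L)
    cl <- function(J) {
      o <- deSolve::lsoda(c(c = c_in), seq(0, L, length.out = 5),
                          function(t, y, p) rhs(t, y, p), J,
                          rtol = 1e-12, atol = 1e-14)
      o[nrow(o), 2]
    }
    c0 <- cl(0); c1 <- cl(1)
    as.numeric((c_out - c0) / (c1 - c0))   # affine solve for J
  }
  D <- 1e-9; L <- 1
  for (case in list(c(1, -0.1, 10, 100), c(1, 0.05, 80, 2),
                    c(-1, -0.1, 30, 5))) {
    z <- case[1]; V <- case[2]; cin <- case[3]; cout <- case[4]
    J_or <- oracle(D, z, V, cin, cout, L)
    J_pk <- ghk_flux(D / L, z, V, cin, cout)
    expect_equal(J_pk, J_or, tolerance = 1e-8)
  }
})

test_that("GHK satisfies the independence antisymmetry relation", {
  set.seed(11)
  for (i in 1:25) {
    V <- stats::runif(1, -0.2, 0.2)
    cin <- stats::runif(1, 0.1, 200); cout <- stats::runif(1, 0.1, 200)
    z <- sample(c(-1, 1), 1)
    expect_equal(ghk_flux(1e-9, z, V, cin, cout),
                 -ghk_flux(1e-9, z, -V, cout, cin), tolerance = 1e-10)
  }
})

test_that("Boltzmann gating: midpoint, saturation, monotonicity", {
  expect_equal(boltzmann_open_probability(-0.05, -0.05, 0.01, "inward"), 0.5)
  expect_equal(boltzmann_open_probability(-0.05, -0.05, 0.01, "outward"), 0.5)
  expect_lt(boltzmann_open_probability(1, -0.05, 0.01, "inward"), 1e-10)
  expect_gt(boltzmann_open_probability(-1, -0.05, 0.01, "inward"), 1 - 1e-10)
  expect_lt(boltzmann_open_probability(-1, -0.05, 0.01, "outward"), 1e-10)
  V <- seq(-0.2, 0.1, by = 0.01)
  p_in <- boltzmann_open_probability(V, -0.05, 0.01, "inward")
  p_out <- boltzmann_open_probability(V, -0.05, 0.01, "outward")
  expect_true(all(diff(p_in) < 0))
  expect_true(all(diff(p_out) > 0))
  expect_true(all(boltzmann_open_probability(V, -0.05, 0.01, "none") == 1))
  expect_error(boltzmann_open_probability(0, 0, 0, "inward"), "slope")
})

test_that("KOR gating midpoint tracks E_K with the Nernst slope", {
  v1 <- kor_gating_midpoint(1)
  v10 <- kor_gating_midpoint(10)
  rtf_ <- sr_const$R * sr_const$Tref / sr_const$F
  expect_equal(v10 - v1, rtf_ * log(10), tolerance = 1e-12)
  expect_equal(v10 - v1, 0.0592, tolerance = 0.01)
  # unit ratio: V_half equals the offset
  expect_equal(kor_gating_midpoint(100, offset = 0.02, K_cytosol_ref = 100),
               0.02)
  ks <- c(0.5, 5, 50)
  expect_true(all(diff(kor_gating_midpoint(ks)) > 0))
  expect_error(kor_gating_midpoint(0), "K_apoplast")
})

test_that("NSCC calcium block is hyperbolic", {
  expect_equal(nscc_permeability(1e-9, 0, 0.3), 1e-9)
  expect_equal(nscc_permeability(1e-9, 0.3, 0.3), 0.5e-9)
  r <- nscc_permeability(1e-9, 0.5, 0.3) / nscc_permeability(1e-9, 2.0, 0.3)
  expect_equal(r, (0.3 / 0.8) / (0.3 / 2.3), tolerance = 1e-12)
  Ca <- seq(0, 5, by = 0.5)
  expect_true(all(diff(nscc_permeability(1e-9, Ca, 0.3)) < 0))
})

test_that("mass-action antiporter: equilibrium, knockout, coupling, sign", {
  # equal ratios -> equilibrium
  eq <- antiporter_flux(1e-7, Na_in = 10, Na_out = 50, H_in = 2e-4, H_out = 1e-3)
  expect_equal(eq$J_Na, 0)
  ko <- antiporter_flux(0, 10, 1, 1e-4, 1e-3)
  expect_equal(ko$J_Na, 0)
  # cytosolic Na against an inward pH gradient: efflux, H countercurrent,
  # exactly zero charge
  f <- antiporter_flux(1e-7, Na_in = 10, Na_out = 50,
                       H_in = ph_to_conc(7.2), H_out = ph_to_conc(5.3))
  expect_gt(f$J_Na, 0)
  expect_equal(f$J_H, -f$J_Na)
  expect_equal(f$J_charge, 0)
  expect_equal(f$J_Na, 1e-7 * (10 * ph_to_conc(5.3) - 50 * ph_to_conc(7.2)),
               tolerance = 1e-12)
})

test_that("four-state carrier cycle matches the master-equation oracle", {
  set.seed(42)
  for (i in 1:120) {
    k <- 10^stats::runif(8, -2, 4)
    z_t <- sample(c(-2, -1, 0, 1, 2), 1)
    dphi <- stats::runif(1, -0.2, 0.2)
    S_cis <- 10^stats::runif(1, -4, 2)
    S_trans <- 10^stats::runif(1, -4, 2)
    N <- 1e-8
    J <- carrier_cycle_flux(N, k, z_t, dphi, S_cis, S_trans)
    J_or <- carrier_oracle(N, k, z_t, dphi, S_cis, S_trans)
    expect_equal(J, J_or, tolerance = 1e-9)
  }
})

test_that("carrier cycle: detailed balance and linearity in carrier density", {
  # detailed balance: forward product equals backward product
  k <- c(2, 5, 3, 4, 7, 2, 10, 2 * 3 * 7 * 10 / (5 * 4 * 2))
  expect_equal(carrier_cycle_flux(1e-8, k), 0, tolerance = 1e-20)
  k2 <- c(10, 1, 20, 2, 30, 3, 40, 4)
  expect_equal(carrier_cycle_flux(2e-8, k2), 2 * carrier_cycle_flux(1e-8, k2))
  expect_equal(carrier_cycle_flux(1e-8, rep(0, 8)), 0)
})

test_that("water flux laws: balance points, signs, direct evaluation", {
  expect_equal(water_flux_plasma_membrane(1e-13, 0.9, 1e5, 1e5, 2e5, 2e5), 0)
  expect_equal(water_flux_plasma_membrane(1e-13, 1, 3e5, 1e5, 4e5, 2e5), 0)
  expect_equal(water_flux_plasma_membrane(1e-13, 0.9, 3e5, 1e5, 3e5, 2e5),
               1e-13 * (2e5 - 0.9 * 1e5), tolerance = 1e-15)
  # tonoplast: insensitive to hydraulic pressure by construction
  expect_equal(water_flux_tonoplast(1e-12, 1, 2e5, 2e5), 0)
  expect_lt(water_flux_tonoplast(1e-12, 1, 3e5, 2e5), 0)
  sweep <- seq(-2e5, 2e5, length.out = 11)
  expect_equal(water_flux_tonoplast(1e-12, 0.8, sweep + 1e5, 1e5),
               -1e-12 * 0.8 * sweep, tolerance = 1e-15)
  expect_equal(osmotic_pressure(200), sr_const$R * sr_const$Tref * 200)
})
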