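# Shared fixtures: memoized model builds and steady states so that multiple
# test files can reuse the expensive relaxations within one session.

sr_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = sr_cache)) assign(key, force(expr), envir = sr_cache)
  get(key, envir = sr_cache)
}

toy_config <- function() make_truth_config("toy")

toy_steady <- function(medium_name = "flux_content") {
  cached(paste0("toy_ss_", medium_name), {
    model <- build_model(toy_config())
    bc <- presalt_medium(medium_preset(medium_name))
    solve_presalt_steady_state(model, bc, rate_tol = 1e-9)
  })
}

default_steady <- function(medium_name = "flux_content", scenario = NULL,
                           k_ap = NULL, genotype = "wild_type",
                           rate_tol = 1e-7, rtol = 1e-5) {
  key <- paste("def_ss", medium_name, scenario %||% "wt", k_ap %||% "d",
               genotype, sep = "_")
  cached(key, {
    cfg <- make_truth_config("default")
    if (!is.null(scenario))
      cfg <- set_scenario(cfg, pattern = scenario, k_ap = k_ap,
                          genotype = genotype)
    else cfg$genotype <- genotype
    model <- build_model(cfg)
    bc <- presalt_medium(medium_preset(medium_name))
    solve_presalt_steady_state(model, bc, rate_tol = rate_tol, rtol = rtol)
  })
}

run_salt <- function(ss, medium, days, rtol = 1e-5) {
  model <- attr(ss, "model")
  bc0 <- presalt_medium(medium)
  run_protocol(model, ss, make_protocol(pre_medium = bc0,
                                        salt_medium = medium,
                                        duration = days * 86400),
               rtol = rtol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent master-equation oracle for the four-state carrier cycle
carrier_oracle <- function(N, k, z_t, dphi, S_cis, S_trans,
                           T = sr_const$Tref) {
  fv <- exp(-z_t * sr_const$F * dphi / (2 * sr_const$R * T))
  k12 <- k[1] * S_cis; k21 <- k[2]
  k23 <- k[3] * fv;    k32 <- k[4] / fv
  k34 <- k[5];         k43 <- k[6] * S_trans
  k41 <- k[7];         k14 <- k[8]
  Q <- matrix(0, 4, 4)
  Q[1, 2] <- k12; Q[2, 1] <- k21
  Q[2, 3] <- k23; Q[3, 2] <- k32
  Q[3, 4] <- k34; Q[4, 3] <- k43
  Q[4, 1] <- k41; Q[1, 4] <- k14
  A <- t(Q)
  diag(A) <- -rowSums(Q)
  # steady state: A p = 0, sum(p) = 1
  M <- rbind(A, rep(1, 4))
  p <- qr.solve(M, c(0, 0, 0, 0, 1))
  N * (p[1] * k12 - p[2] * k21)
}
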