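#' Antiporter placement map for a named SOS1 scenario
#'
#' A spatial pattern of plasma-membrane Na+/H+ antiporter activity: a 2 x 5
#' logical matrix (zones apex/mature by the five tissues). In the apex the
#' xylem column refers to the living "non-functional xylem" cells; in the
#' mature zone the xylem is an apoplastic conduit without a plasma membrane,
#' so its entry is ignored.
#'
#' @param name Scenario name from [enumerate_scenarios()], or `"all"` /
#'   `"none"`.
#' @return A logical matrix with rownames `c("apex", "mature")` and
#'   colnames the five tissues.
#' @export
scenario_antiporter_map <- function(name = "all") {
  m <- matrix(FALSE, 2, 5,
              dimnames = list(c("apex", "mature"), sr_tissues))
  on <- function(zone, tissues) {
    m[zone, tissues] <<- TRUE
  }
  outer3 <- c("epidermis", "cortex", "endodermis")
  switch(name,
    none = NULL,
    all = { on("apex", sr_tissues); on("mature", sr_tissues) },
    mature_epidermis        = on("mature", "epidermis"),
    mature_cortex           = on("mature", "cortex"),
    mature_endodermis       = on("mature", "endodermis"),
    mature_xylem_parenchyma = on("mature", "xylem_parenchyma"),
    apex_epidermis          = on("apex", "epidermis"),
    apex_cortex             = on("apex", "cortex"),
    apex_endodermis         = on("apex", "endodermis"),
    apex_xylem_parenchyma   = on("apex", "xylem_parenchyma"),
    apex_nonfunctional_xylem = on("apex", "xylem"),
    mature_epidermis_xylem_parenchyma =
      on("mature", c("epidermis", "xylem_parenchyma")),
    mature_cortex_xylem_parenchyma =
      on("mature", c("cortex", "xylem_parenchyma")),
    mature_outer            = on("mature", outer3),
    mature_all              = on("mature", sr_tissues),
    apex_epidermis_mature_xylem_parenchyma = {
      on("apex", "epidermis"); on("mature", "xylem_parenchyma")
    },
    apex_all_mature_xylem_parenchyma = {
      on("apex", sr_tissues); on("mature", "xylem_parenchyma")
    },
    apex_all                = on("apex", sr_tissues),
    stop("unknown scenario name: ", name)
  )
  m
}

#' Enumerate the SOS1 spatial-distribution scenarios
#'
#' The six scenario groups of the location study: antiporters in individual
#' mature tissues (4), individual apex tissues including non-functional
#' xylem (5), mature-zone tissue combinations (4), mature-and-apex
#' combinations (2), all apex tissues (1) and all root tissues (1) -- 17
#' spatial patterns in total. Mature-zone patterns carry no apex
#' antiporters and vice versa.
#'
#' @return A data.frame with columns `name` and `group`.
#' @export
enumerate_scenarios <- function() {
  data.frame(
    name = c(
      "mature_epidermis", "mature_cortex", "mature_endodermis",
      "mature_xylem_parenchyma",
      "apex_epidermis", "apex_cortex", "apex_endodermis",
      "apex_xylem_parenchyma", "apex_nonfunctional_xylem",
      "mature_epidermis_xylem_parenchyma", "mature_cortex_xylem_parenchyma",
      "mature_outer", "mature_all",
      "apex_epidermis_mature_xylem_parenchyma",
      "apex_all_mature_xylem_parenchyma",
      "apex_all", "all"
    ),
    group = c(
      rep("mature_individual", 4),
      rep("apex_individual", 5),
      rep("mature_combination", 4),
      rep("mature_apex_combination", 2),
      "apex_all", "all_tissues"
    ),
    stringsAsFactors = FALSE
  )
}

#' Antiporter strength grid of the scenario sweep
#'
#' @return The four antiporter mass-action coefficients considered for
#'   every spatial pattern: 1, 10, 100 and 1000 x 1e-8 m4 mol-1 s-1.
#' @export
strength_grid <- function() c(1e-8, 1e-7, 1e-6, 1e-5)

#' Classify a scenario outcome as reasonable
#'
#' A scenario is "reasonable" when both its root Na+ content and its Na+
#' flux to the shoot lie within 50 percent of the wild-type reference
#' values (inclusive at exactly 50 percent).
#'
#' @param row A list or one-row data.frame with elements `content` and
#'   `flux`.
#' @param wt_reference List with positive elements `content` and `flux`.
#' @return Logical.
#' @export
classify_reasonable <- function(row, wt_reference) {
  if (!is.list(wt_reference) ||
      is.null(wt_reference$content) || is.null(wt_reference$flux) ||
      wt_reference$content <= 0 || wt_reference$flux <= 0)
    stop("classify_reasonable: wt_reference must have positive content and flux")
  ok_c <- abs(row$content - wt_reference$content) / wt_reference$content <= 0.5
  ok_f <- abs(row$flux - wt_reference$flux) / wt_reference$flux <= 0.5
  isTRUE(ok_c && ok_f)
}

#' Run a scenario-by-strength sweep
#'
#' Runs the full pipeline (pre-salt steady state, salt protocol,
#' observables) for each combination of spatial pattern and antiporter
#' strength, holding every other parameter fixed. A failed simulation is
#' recorded in its row rather than aborting the sweep.
#'
#' @param config A model configuration, see [make_truth_config()].
#' @param patterns Character vector of scenario names.
#' @param strengths Numeric vector of antiporter coefficients
#'   (m4 mol-1 s-1).
#' @param medium Salt-stress medium (see [medium_preset()]).
#' @param duration Exposure time to evaluate observables at (s).
#' @param content_time,flux_time Optional distinct evaluation times (s);
#'   default `duration`.
#' @return A data.frame with one row per (pattern, strength): root Na+
#'   content per fresh weight (mol/kg), Na+ flux to the shoot
#'   (nmol min-1 g-1 FW), water flux to the shoot (m3/s), mean cytosolic
#'   Na+ by zone (mol/m3), and an `ok`/`message` status pair.
#' @export
run_sweep <- function(config, patterns = enumerate_scenarios()$name,
                      strengths = strength_grid(),
                      medium = medium_preset("content_100"),
                      duration = 10 * 86400,
                      content_time = duration, flux_time = duration) {
  grid <- expand.grid(pattern = patterns, strength = strengths,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    pat <- grid$pattern[i]; str <- grid$strength[i]
    out <- data.frame(pattern = pat, strength = str,
                      content_Na = NA_real_, flux_Na = NA_real_,
                      water_flux = NA_real_,
                      cyt_Na_mature = NA_real_, cyt_Na_apex = NA_real_,
                      ok = FALSE, message = "", stringsAsFactors = FALSE)
    res <- tryCatch({
      cfg <- set_scenario(config, pattern = pat, k_ap = str)
      model <- build_model(cfg)
      bc0 <- presalt_medium(medium)
      ss <- solve_presalt_steady_state(model, bc0)
      traj <- run_protocol(model, ss, protocol = make_protocol(
        pre_medium = bc0, salt_medium = medium, duration = duration))
      out$content_Na <- root_ion_content_per_fw(traj, content_time, "Na")
      out$flux_Na <- mol_s_kg_to_nmol_min_g(
        flux_to_shoot(traj, flux_time, "Na", per_fw = TRUE))
      out$water_flux <- water_flux_to_shoot(traj, flux_time)
      out$cyt_Na_mature <- mean_cytosolic_concentration(traj, content_time,
                                                        "mature", "Na")
      out$cyt_Na_apex <- mean_cytosolic_concentration(traj, content_time,
                                                      "apex", "Na")
      out$ok <- TRUE
      out
    }, error = function(e) {
      out$message <- conditionMessage(e)
      out
    })
    res
  })
  do.call(rbind, rows)
}

#' Apply an SOS1 scenario to a configuration
#'
#' Sets the plasma-membrane antiporter placement map and strength, and the
#' genotype (the `sos1` genotype scales all plasma-membrane antiporter
#' strengths by the configured residual fraction, reflecting the low -- as
#' opposed to absent -- activity required to reproduce sos1 measurements).
#'
#' @param config A model configuration.
#' @param pattern Scenario name (see [enumerate_scenarios()]), or an
#'   explicit placement matrix.
#' @param k_ap Optional uniform antiporter coefficient (m4 mol-1 s-1)
#'   applied wherever the map is active; when `NULL` the zone-specific
#'   fitted defaults (`k_ap_outer`, `k_ap_stele`) are kept.
#' @param genotype `"wild_type"` or `"sos1"`.
#' @return The modified configuration.
#' @export
set_scenario <- function(config, pattern = "all", k_ap = NULL,
                         genotype = c("wild_type", "sos1")) {
  genotype <- match.arg(genotype)
  map <- if (is.matrix(pattern)) pattern else scenario_antiporter_map(pattern)
  config$distribution$antiporter_map <- map
  if (!is.null(k_ap)) {
    if (k_ap < 0) stop("set_scenario: k_ap must be >= 0")
    config$params$k_ap_outer <- k_ap
    config$params$k_ap_stele <- k_ap
  }
  config$genotype <- genotype
  config
}
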