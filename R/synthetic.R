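# Synthetic experimental-target generation: forward simulation at known
# "true" parameters plus configurable multiplicative observation noise,
# so that the whole optimization pipeline is testable without any
# experimental download.

#' Model configuration presets with known true parameters
#'
#' `"toy"`: a 6-layer root (2 apex layers) that reaches its pre-salt steady
#' state in seconds -- the preset used throughout the test-suite.
#' `"default"`: the full 30-layer root (6 apex layers) used for the
#' scientific analyses.
#'
#' @param preset `"toy"` or `"default"`.
#' @return A validated configuration list (geometry arguments, barrier
#'   arguments, kinetic parameters, transporter distribution, genotype,
#'   solver settings).
#' @export
make_truth_config <- function(preset = c("toy", "default")) {
  preset <- match.arg(preset)
  geo <- if (preset == "toy") list(n_axial = 6L, apex_layers = 2L)
         else list(n_axial = 30L, apex_layers = 6L)
  cfg <- list(
    schema = "saltroot-config/1",
    preset = preset,
    geometry = geo,
    barriers = list(passage_cell_fraction = 0.25),
    params = default_params(),
    distribution = default_distribution(),
    genotype = "wild_type",
    P_top = -0.3e6,
    solver = list(rtol = 1e-6, atol_scale = 1)
  )
  validate_config(cfg)
}

#' Observation-noise model for synthetic targets
#'
#' @param sd Relative (log-scale) standard deviation of the multiplicative
#'   lognormal noise; 0 means noiseless.
#' @param seed RNG seed.
#' @return A `NoiseModel` list.
#' @export
noise_model <- function(sd = 0, seed = 1) {
  if (sd < 0) stop("noise_model: sd must be >= 0")
  list(sd = sd, seed = seed)
}

#' Default experimental conditions for target generation
#'
#' Media follow the four printed comparison media (see [medium_preset()]).
#' The toy set uses a single condition per genotype to keep the fitting
#' tests fast.
#'
#' @param preset `"toy"` or `"default"`.
#' @param duration Salt-exposure duration (s).
#' @return List of condition lists (`name`, `medium`, `genotype`, `time`).
#' @export
default_conditions <- function(preset = c("toy", "default"),
                               duration = 86400) {
  preset <- match.arg(preset)
  if (preset == "toy") {
    list(
      list(name = "flux_content_wt", medium = medium_preset("flux_content"),
           genotype = "wild_type", time = duration)
    )
  } else {
    list(
      list(name = "flux_content_wt", medium = medium_preset("flux_content"),
           genotype = "wild_type", time = duration),
      list(name = "flux_content_sos1", medium = medium_preset("flux_content"),
           genotype = "sos1", time = duration),
      list(name = "xylem_wt", medium = medium_preset("xylem"),
           genotype = "wild_type", time = duration),
      list(name = "potentials_wt", medium = medium_preset("potentials"),
           genotype = "wild_type", time = duration)
    )
  }
}

#' Generate a synthetic experimental-target table
#'
#' Forward-simulates the truth configuration under each condition and
#' genotype and emits the optimization observables (root Na+/K+ content and
#' epidermal potential for the outer stage; xylem Na+/K+/Cl- concentrations
#' and the Na+ flux to the shoot for the stele stage), perturbed by
#' multiplicative lognormal noise. A condition whose simulation fails is
#' omitted with a message rather than aborting.
#'
#' @param config Truth configuration (see [make_truth_config()]).
#' @param conditions Condition list (see [default_conditions()]).
#' @param noise A [noise_model()].
#' @param observables Observable names to emit per condition.
#' @param ... Passed to [evaluate_targets()].
#' @return A `TargetTable` data.frame with columns `observable`,
#'   `genotype`, `Na`, `K`, `Ca`, `pH`, `time`, `value`, `units`, `weight`,
#'   `stage`.
#' @export
generate_targets <- function(config,
                             conditions = default_conditions(config$preset),
                             noise = noise_model(0),
                             observables = c("root_Na_content",
                                             "root_K_content",
                                             "epidermal_potential",
                                             "xylem_Na", "xylem_K", "xylem_Cl",
                                             "Na_flux_to_shoot"),
                             ...) {
  rows <- list()
  for (cond in conditions) {
    med <- validate_medium(cond$medium)
    tab <- data.frame(
      observable = observables,
      genotype = cond$genotype,
      Na = med$Na, K = med$K, Ca = med$Ca, pH = med$pH,
      time = cond$time,
      value = NA_real_,
      units = vapply(observables, observable_units, ""),
      weight = 1,
      stage = vapply(observables, observable_stage, ""),
      stringsAsFactors = FALSE
    )
    ev <- tryCatch(evaluate_targets(config, tab, ...), error = function(e) {
      message("generate_targets: condition ", cond$name, " failed: ",
              conditionMessage(e))
      NULL
    })
    if (is.null(ev)) next
    tab$value <- ev$model
    rows[[length(rows) + 1]] <- tab
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (noise$sd > 0) {
    set.seed(noise$seed)
    out$value <- out$value * exp(stats::rnorm(nrow(out), 0, noise$sd))
  }
  validate_targets(out)
}

#' Validate a target table
#'
#' @param targets Candidate table.
#' @return The table, invisibly returned after validation.
#' @export
validate_targets <- function(targets) {
  need <- c("observable", "genotype", "Na", "K", "Ca", "pH", "time",
            "value", "units", "weight", "stage")
  miss <- setdiff(need, names(targets))
  if (length(miss))
    stop("target table: missing columns ", paste(miss, collapse = ", "))
  if (any(targets$weight <= 0)) stop("target table: weights must be > 0")
  if (!all(targets$stage %in% c("outer", "stele")))
    stop("target table: stage must be 'outer' or 'stele'")
  bad <- setdiff(unique(targets$observable),
                 c("root_Na_content", "root_K_content", "epidermal_potential",
                   "xylem_Na", "xylem_K", "xylem_Cl", "Na_flux_to_shoot",
                   "water_flux_to_shoot", "cyt_Na_mature", "cyt_Na_apex"))
  if (length(bad))
    stop("target table: unknown observables ", paste(bad, collapse = ", "))
  targets
}

#' Read / write target tables as CSV
#'
#' @param path File path.
#' @param targets Target table.
#' @return The table (read) or `path` invisibly (write).
#' @export
read_targets_csv <- function(path) {
  validate_targets(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_targets_csv
#' @export
write_targets_csv <- function(targets, path) {
  utils::write.csv(validate_targets(targets), path, row.names = FALSE)
  invisible(path)
}

#' Parameter-recovery experiment
#'
#' Generates synthetic targets from a truth configuration, perturbs the
#' free parameters away from their true values, refits them with
#' [two_stage_fit()], and reports per-parameter relative errors.
#'
#' @param config Truth configuration.
#' @param noise A [noise_model()].
#' @param outer_free,stele_free Bound lists (see [fit_stage()]).
#' @param start_factor Multiplicative offset applied to the true values to
#'   form the fitting start.
#' @param conditions,n_starts,maxit,... Passed through.
#' @return List with `targets`, `fit`, and `report` (data.frame of `param`,
#'   `truth`, `fitted`, `rel_error`, `identifiable`).
#' @export
recovery_experiment <- function(config, noise = noise_model(0),
                                outer_free = list(k_ap_outer = c(1e-9, 1e-5)),
                                stele_free = list(k_ap_stele = c(1e-9, 1e-5)),
                                start_factor = 3,
                                conditions = default_conditions(config$preset),
                                n_starts = 2, maxit = 25, ...) {
  targets <- generate_targets(config, conditions, noise, ...)
  truth <- config$params
  start_cfg <- config
  for (nm in c(names(outer_free), names(stele_free)))
    start_cfg$params[[nm]] <- truth[[nm]] * start_factor
  fit <- two_stage_fit(start_cfg, targets, outer_free = outer_free,
                       stele_free = stele_free, n_starts = n_starts,
                       seed = noise$seed, maxit = maxit, ...)
  par <- c(fit$outer$par, fit$stele$par)
  report <- data.frame(
    param = names(par),
    truth = vapply(names(par), function(n) truth[[n]], 0),
    fitted = unlist(par),
    stringsAsFactors = FALSE
  )
  report$rel_error <- abs(report$fitted - report$truth) / report$truth
  kap <- c(outer = fit$outer$fim_condition, stele = fit$stele$fim_condition)
  report$identifiable <- is.finite(kap[ifelse(report$param %in%
    names(fit$outer$par), "outer", "stele")]) &
    kap[ifelse(report$param %in% names(fit$outer$par), "outer", "stele")] < 1e8
  list(targets = targets, fit = fit, report = report)
}
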