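# Configuration schema, unit-aware loading, validation, serialization.

sr_unit_table <- c(
  "mol/m3" = 1, "mM" = 1, "M" = 1e3,
  "Pa" = 1, "kPa" = 1e3, "MPa" = 1e6,
  "V" = 1, "mV" = 1e-3,
  "m" = 1, "mm" = 1e-3, "um" = 1e-6,
  "s" = 1, "min" = 60, "h" = 3600, "day" = 86400,
  "m/s" = 1, "m2/s" = 1, "m3" = 1, "m2" = 1,
  "m/s/Pa" = 1, "m2/Pa/s" = 1, "mol/m2" = 1,
  "m4/mol/s" = 1, "1/s" = 1, "kg" = 1, "dimensionless" = 1
)

#' Parse a quantity with units to SI
#'
#' Configuration files may write any physical quantity as a string
#' `"<value> <unit>"` (e.g. `"1e-7 m4/mol/s"`, `"100 mM"`, `"-0.3 MPa"`);
#' bare numbers are taken as SI.
#'
#' @param x A number or a `"value unit"` string.
#' @return Numeric value in SI units.
#' @export
parse_quantity <- function(x) {
  if (is.numeric(x)) return(x)
  if (!is.character(x) || length(x) != 1)
    stop("parse_quantity: expected a number or 'value unit' string")
  parts <- strsplit(trimws(x), "\\s+")[[1]]
  v <- suppressWarnings(as.numeric(parts[1]))
  if (is.na(v)) stop("parse_quantity: cannot parse value in '", x, "'")
  if (length(parts) == 1) return(v)
  u <- paste(parts[-1], collapse = "")
  if (!u %in% names(sr_unit_table))
    stop("parse_quantity: unknown unit '", u, "' in '", x, "'")
  v * sr_unit_table[[u]]
}

normalize_units <- function(x) {
  if (is.list(x)) return(lapply(x, normalize_units))
  if (is.character(x) && length(x) == 1 &&
      grepl("^\\s*-?[0-9.eE+-]+\\s+\\S", x)) return(parse_quantity(x))
  x
}

config_top_keys <- c("schema", "preset", "geometry", "barriers", "params",
                     "distribution", "genotype", "P_top", "solver", "seed",
                     "closed", "output")

#' Validate a model configuration
#'
#' Checks the schema id, rejects unknown top-level keys, verifies required
#' sections and elementary physical constraints, collecting all problems
#' into a single error message.
#'
#' @param config Candidate configuration list.
#' @return The configuration, invisibly valid.
#' @export
validate_config <- function(config) {
  probs <- character(0)
  note <- function(...) probs <<- c(probs, paste0(...))
  if (!identical(config$schema, "saltroot-config/1"))
    note("schema: must be 'saltroot-config/1'")
  unknown <- setdiff(names(config), config_top_keys)
  if (length(unknown))
    note("unknown top-level keys: ", paste(unknown, collapse = ", "))
  for (sec in c("geometry", "params", "distribution"))
    if (is.null(config[[sec]])) note(sec, ": section missing")
  p <- config$params
  if (!is.null(p)) {
    for (nm in c("P_nscc", "P_kir", "P_kor", "P_hkt", "k_ap_outer",
                 "k_ap_stele", "N_pump", "Lp_pm", "Lp_ton"))
      if (!is.null(p[[nm]]) && p[[nm]] < 0) note("params$", nm, ": must be >= 0")
    for (nm in c("sigma_pm", "sigma_ton", "sigma_pd"))
      if (!is.null(p[[nm]]) && (p[[nm]] < 0 || p[[nm]] > 1))
        note("params$", nm, ": must be in [0, 1]")
  }
  g <- config$geometry
  if (!is.null(g$n_axial) && g$n_axial < 1) note("geometry$n_axial: must be >= 1")
  if (!is.null(g$n_axial) && !is.null(g$apex_layers) &&
      (g$apex_layers < 0 || g$apex_layers > g$n_axial))
    note("geometry$apex_layers: must be in [0, n_axial]")
  if (!is.null(config$genotype) &&
      !config$genotype %in% c("wild_type", "sos1"))
    note("genotype: must be 'wild_type' or 'sos1'")
  if (length(probs))
    stop("invalid configuration:\n  - ", paste(probs, collapse = "\n  - "),
         call. = FALSE)
  invisible(config)
}

#' Load a configuration from a YAML file
#'
#' Quantities written as `"value unit"` strings are converted to SI on
#' load; the result is schema-validated.
#'
#' @param path YAML file path.
#' @return A validated configuration list.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg <- normalize_units(cfg)
  # yaml drops the matrix class of the antiporter map; restore it
  am <- cfg$distribution$antiporter_map
  if (!is.null(am) && !is.matrix(am)) {
    cfg$distribution$antiporter_map <-
      matrix(unlist(am), nrow = 2, byrow = TRUE,
             dimnames = list(c("apex", "mature"), sr_tissues))
  }
  for (nm in intersect(names(cfg$params),
                       c("pump_rates", "khsym_rates", "clhsym_rates",
                         "vpump_rates")))
    cfg$params[[nm]] <- as.numeric(unlist(cfg$params[[nm]]))
  validate_config(cfg)
  cfg
}

#' Write a configuration to a YAML file
#'
#' @param config Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  cfg <- config
  am <- cfg$distribution$antiporter_map
  if (is.matrix(am))
    cfg$distribution$antiporter_map <-
      list(apex = as.logical(am["apex", ]), mature = as.logical(am["mature", ]))
  yaml::write_yaml(cfg, path, precision = 17)
  invisible(path)
}

#' Provenance block for reproducible outputs
#'
#' @param config Configuration used.
#' @param seed RNG seed.
#' @return Named list with config hash, package version, seed, timestamp.
#' @export
provenance <- function(config, seed = NULL) {
  raw <- serialize(config, NULL)
  list(
    config_hash = sprintf("%08x", sum(as.integer(raw) *
                                        (seq_along(raw) %% 97 + 1)) %% .Machine$integer.max),
    package_version = as.character(utils::packageVersion("saltroot")),
    seed = seed,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
}
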