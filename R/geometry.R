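#' Default tissue-ring specification for an Arabidopsis-like root
#'
#' Five concentric tissues, outermost to innermost: epidermis, cortex,
#' endodermis, xylem parenchyma, xylem. Radii are representative of an
#' Arabidopsis primary root (outer radius 60 um); they scale the absolute
#' observables but not the qualitative transport behavior.
#'
#' @param r_bounds Radial boundaries in m, length 6, strictly decreasing,
#'   from the root surface to the axis.
#' @return A data.frame with columns `name`, `radial_index`, `r_outer`,
#'   `r_inner`.
#' @export
default_ring_spec <- function(r_bounds = c(60, 45, 30, 20, 10, 0) * 1e-6) {
  names_ <- c("epidermis", "cortex", "endodermis", "xylem_parenchyma", "xylem")
  if (length(r_bounds) != 6) stop("ring_spec: r_bounds must have length 6")
  data.frame(
    name = names_,
    radial_index = 0:4,
    r_outer = r_bounds[1:5],
    r_inner = r_bounds[2:6],
    stringsAsFactors = FALSE
  )
}

sr_tissues <- c("epidermis", "cortex", "endodermis", "xylem_parenchyma", "xylem")

validate_ring_spec <- function(ring_spec) {
  if (!all(c("name", "r_outer", "r_inner") %in% names(ring_spec)))
    stop("ring_spec: must have columns name, r_outer, r_inner")
  if (nrow(ring_spec) != 5 || !identical(ring_spec$name, sr_tissues))
    stop("ring_spec: must list the five tissues in order ",
         paste(sr_tissues, collapse = ", "))
  if (any(ring_spec$r_outer <= ring_spec$r_inner))
    stop("ring_spec: r_outer must exceed r_inner in every ring")
  if (any(diff(ring_spec$r_outer) >= 0))
    stop("ring_spec: r_outer must be strictly decreasing inward")
  if (any(ring_spec$r_outer <= 0) || any(ring_spec$r_inner < 0))
    stop("ring_spec: radii must be positive (r_inner of the axis ring may be 0)")
  invisible(ring_spec)
}

#' Build the discretized root cylinder
#'
#' Constructs the compartment set of a model root: `n_axial` single-cell
#' layers of five concentric tissue rings, each ring split into apoplastic,
#' cytosolic and vacuolar compartments. Layers `0 .. apex_layers-1`
#' (layer 0 at the root tip) form the apex zone; the remainder is the
#' mature zone. Mature xylem is a purely apoplastic conduit (no cytosol or
#' vacuole); apex xylem ("non-functional xylem") is a living cell with all
#' three compartments. Indexing is deterministic: layer-major, then ring,
#' then kind (apoplast, cytosol, vacuole).
#'
#' @param n_axial Number of axial layers (>= 1).
#' @param apex_layers Number of apex layers (0 <= apex_layers <= n_axial).
#' @param ring_spec Tissue-ring table, see [default_ring_spec()].
#' @param cell_height Axial height of one cell layer (m).
#' @param f_apoplast Volume fraction of each ring occupied by cell wall
#'   (apoplast).
#' @param f_cytosol Fraction of the protoplast volume that is cytosol (the
#'   remainder is vacuole).
#' @param f_tonoplast Tonoplast area as a fraction of plasma-membrane area.
#' @param fresh_weight Optional override for the total fresh weight (kg);
#'   defaults to total compartment volume times 1000 kg m-3.
#' @return An object of class `sr_geometry`: a list with the arguments, the
#'   compartment table `comp` (columns `idx`, `layer`, `ring`, `tissue`,
#'   `kind`, `zone`, `living`, `V0`, `area_pm`, `area_ton`) and
#'   `fresh_weight`.
#' @export
build_root_grid <- function(n_axial = 30, apex_layers = 6,
                            ring_spec = default_ring_spec(),
                            cell_height = 1e-4,
                            f_apoplast = 0.05, f_cytosol = 0.25,
                            f_tonoplast = 0.8,
                            fresh_weight = NULL) {
  if (!is.numeric(n_axial) || n_axial < 1) stop("n_axial: must be >= 1")
  if (apex_layers < 0 || apex_layers > n_axial)
    stop("apex_layers: must satisfy 0 <= apex_layers <= n_axial")
  if (cell_height <= 0) stop("cell_height: must be > 0")
  if (f_apoplast <= 0 || f_apoplast >= 1) stop("f_apoplast: must be in (0,1)")
  if (f_cytosol <= 0 || f_cytosol >= 1) stop("f_cytosol: must be in (0,1)")
  validate_ring_spec(ring_spec)
  n_axial <- as.integer(n_axial); apex_layers <- as.integer(apex_layers)

  h <- cell_height
  rows <- vector("list", n_axial * 5 * 3)
  ii <- 0
  for (l in seq_len(n_axial) - 1L) {
    zone <- if (l < apex_layers) "apex" else "mature"
    for (r in 0:4) {
      tis <- ring_spec$name[r + 1]
      ro <- ring_spec$r_outer[r + 1]; ri <- ring_spec$r_inner[r + 1]
      Vr <- pi * (ro^2 - ri^2) * h
      a_pm <- 2 * pi * (ro + ri) * h + 2 * pi * (ro^2 - ri^2)
      living <- !(tis == "xylem" && zone == "mature")
      if (living) {
        V_apo <- f_apoplast * Vr
        V_pro <- (1 - f_apoplast) * Vr
        kinds <- c("apoplast", "cytosol", "vacuole")
        vols <- c(V_apo, f_cytosol * V_pro, (1 - f_cytosol) * V_pro)
      } else {
        kinds <- "apoplast"
        vols <- Vr   # open conduit: full lumen is apoplastic space
      }
      for (k in seq_along(kinds)) {
        ii <- ii + 1
        rows[[ii]] <- data.frame(
          layer = l, ring = r, tissue = tis, kind = kinds[k], zone = zone,
          living = living && kinds[k] != "apoplast",
          V0 = vols[k],
          area_pm = if (kinds[k] == "cytosol") a_pm else 0,
          area_ton = if (kinds[k] == "vacuole") f_tonoplast * a_pm else 0,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  comp <- do.call(rbind, rows[seq_len(ii)])
  comp$idx <- seq_len(nrow(comp))
  comp <- comp[, c("idx", "layer", "ring", "tissue", "kind", "zone", "living",
                   "V0", "area_pm", "area_ton")]
  if (any(comp$V0 <= 0)) stop("V0: all compartment volumes must be > 0")
  fw <- if (is.null(fresh_weight)) sum(comp$V0) * sr_const$rho_w else fresh_weight
  structure(list(
    n_axial = n_axial, apex_layers = apex_layers, rings = ring_spec,
    cell_height = h, f_apoplast = f_apoplast, f_cytosol = f_cytosol,
    f_tonoplast = f_tonoplast, comp = comp, fresh_weight = fw
  ), class = "sr_geometry")
}

#' @export
print.sr_geometry <- function(x, ...) {
  cat("saltroot geometry:", x$n_axial, "layers (", x$apex_layers, "apex ),",
      nrow(x$comp), "compartments, fresh weight",
      format(x$fresh_weight, digits = 3), "kg\n")
  invisible(x)
}

comp_lookup <- function(comp) {
  # idx by (layer, ring, kind); NA when absent
  key <- paste(comp$layer, comp$ring, comp$kind, sep = "/")
  idx <- comp$idx
  names(idx) <- key
  idx
}

#' Build the connectivity graph and apply developmental-zone barriers
#'
#' Enumerates every transport pathway of the model as an edge list and
#' marks barrier-blocked edges. Plasmodesmata connect all axially and
#' radially adjacent cytosols; tonoplast edges connect each cytosol to its
#' own vacuole; radial apoplastic edges across the mature endodermis are
#' blocked (Casparian strip); mature-endodermis plasma-membrane edges are
#' blocked except in passage-cell layers (suberin lamellae). Passage-cell
#' layers are placed deterministically: every `round(1/passage_cell_fraction)`-th
#' mature layer, starting with the first.
#'
#' @param geometry An `sr_geometry` object.
#' @param passage_cell_fraction Fraction of mature endodermal layers lacking
#'   suberin lamellae, in `[0, 1]`.
#' @param f_wall Area fraction of a radial cell-wall interface available to
#'   apoplastic transport.
#' @param f_pd Area fraction of a cell-cell interface occupied by
#'   plasmodesmata.
#' @param L_pd Plasmodesmal path length (wall thickness, m).
#' @return An object of class `sr_connectivity`: a data.frame of edges with
#'   columns `a`, `b` (compartment indices; 0 = external medium or shoot
#'   boundary), `pathway`, `area_m2`, `length_m`, `blocked`. Every edge is
#'   traversable in both directions with positive sign a to b.
#' @export
apply_barriers <- function(geometry, passage_cell_fraction = 0.25,
                           f_wall = 0.05, f_pd = 0.005, L_pd = 1e-6) {
  stopifnot(inherits(geometry, "sr_geometry"))
  if (passage_cell_fraction < 0 || passage_cell_fraction > 1)
    stop("passage_cell_fraction: must be in [0, 1]")
  comp <- geometry$comp
  rs <- geometry$rings
  h <- geometry$cell_height
  look <- comp_lookup(comp)
  gidx <- function(l, r, k) {
    v <- look[paste(l, r, k, sep = "/")]
    ifelse(is.na(v), NA_integer_, v)
  }
  n_mature <- geometry$n_axial - geometry$apex_layers
  if (n_mature == 0 && passage_cell_fraction > 0)
    warning("no mature layers: passage_cell_fraction has no effect")
  mature_layers <- if (n_mature > 0)
    seq(geometry$apex_layers, geometry$n_axial - 1L) else integer(0)
  passage <- rep(FALSE, length(mature_layers))
  if (passage_cell_fraction > 0 && length(mature_layers) > 0) {
    k <- max(1L, as.integer(round(1 / passage_cell_fraction)))
    passage <- (seq_along(mature_layers) - 1L) %% k == 0L
  }
  is_passage_layer <- function(l) {
    m <- match(l, mature_layers)
    !is.na(m) && passage[m]
  }
  zone_of <- function(l) if (l < geometry$apex_layers) "apex" else "mature"

  E <- list(); ei <- 0
  add <- function(a, b, pathway, area, len, blocked = FALSE) {
    ei <<- ei + 1
    E[[ei]] <<- data.frame(a = a, b = b, pathway = pathway, area_m2 = area,
                           length_m = len, blocked = blocked,
                           stringsAsFactors = FALSE)
  }

  for (l in seq_len(geometry$n_axial) - 1L) {
    mature <- zone_of(l) == "mature"
    # radial apoplast edges between adjacent rings
    for (r in 0:3) {
      a <- gidx(l, r, "apoplast"); b <- gidx(l, r + 1, "apoplast")
      ri <- rs$r_inner[r + 1]
      area <- 2 * pi * ri * h * f_wall
      len <- (rs$r_outer[r + 1] + rs$r_inner[r + 1]) / 2 -
             (rs$r_outer[r + 2] + rs$r_inner[r + 2]) / 2
      # Casparian strip: both radial apoplastic edges incident on the mature
      # endodermis wall are blocked
      blocked <- mature && (r == 1 || r == 2)
      add(a, b, "apoplast_radial", area, len, blocked)
    }
    # external boundary at the epidermis surface
    a <- gidx(l, 0, "apoplast")
    add(a, 0L, "boundary_external", 2 * pi * rs$r_outer[1] * h,
        (rs$r_outer[1] - rs$r_inner[1]) / 2)
    # plasma membranes and tonoplasts
    for (r in 0:4) {
      cyt <- gidx(l, r, "cytosol")
      if (is.na(cyt)) next
      apo <- gidx(l, r, "apoplast")
      vac <- gidx(l, r, "vacuole")
      pm_blocked <- mature && rs$name[r + 1] == "endodermis" &&
        !is_passage_layer(l)
      add(cyt, apo, "plasma_membrane", comp$area_pm[cyt], 1e-8, pm_blocked)
      add(cyt, vac, "tonoplast", comp$area_ton[vac], 1e-8)
    }
    # radial plasmodesmata
    for (r in 0:3) {
      ca <- gidx(l, r, "cytosol"); cb <- gidx(l, r + 1, "cytosol")
      if (is.na(ca) || is.na(cb)) next
      area <- 2 * pi * rs$r_inner[r + 1] * h * f_pd
      add(ca, cb, "plasmodesma", area, L_pd)
    }
    # axial edges to the next layer
    if (l < geometry$n_axial - 1L) {
      for (r in 0:4) {
        ro <- rs$r_outer[r + 1]; ri <- rs$r_inner[r + 1]
        a <- gidx(l, r, "apoplast"); b <- gidx(l + 1, r, "apoplast")
        ann <- pi * (ro^2 - ri^2)
        xylem_conduit <- rs$name[r + 1] == "xylem" &&
          (zone_of(l) == "mature" || zone_of(l + 1) == "mature")
        area <- if (xylem_conduit) ann else ann * geometry$f_apoplast
        add(a, b, "apoplast_axial", area, h)
        ca <- gidx(l, r, "cytosol"); cb <- gidx(l + 1, r, "cytosol")
        if (!is.na(ca) && !is.na(cb))
          add(ca, cb, "plasmodesma", ann * (1 - geometry$f_apoplast) * f_pd,
              L_pd)
      }
    }
  }
  # top of the xylem conduit: boundary to the shoot
  top <- geometry$n_axial - 1L
  xa <- gidx(top, 4, "apoplast")
  add(xa, 0L, "boundary_xylem_top", pi * rs$r_outer[5]^2, h)

  edges <- do.call(rbind, E[seq_len(ei)])
  rownames(edges) <- NULL
  structure(edges, class = c("sr_connectivity", "data.frame"))
}

#' Export a connectivity graph as an edge-list CSV
#'
#' @param edges An `sr_connectivity` object from [apply_barriers()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_connectivity_csv <- function(edges, path) {
  utils::write.csv(as.data.frame(edges), path, row.names = FALSE)
  invisible(path)
}
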