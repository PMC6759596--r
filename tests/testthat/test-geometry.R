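# Discretized root geometry and barrier connectivity.

test_that("default grid has the documented layer/ring/compartment structure", {
  g <- build_root_grid(n_axial = 30, apex_layers = 6)
  expect_s3_class(g, "sr_geometry")
  expect_equal(g$n_axial, 30L)
  expect_equal(length(unique(g$comp$ring)), 5)
  expect_identical(unique(g$comp$tissue),
                   c("epidermis", "cortex", "endodermis",
                     "xylem_parenchyma", "xylem"))
  # mature xylem is a purely apoplastic conduit; apex xylem is a living cell
  mx <- g$comp[g$comp$tissue == "xylem" & g$comp$zone == "mature", ]
  expect_true(all(mx$kind == "apoplast"))
  ax <- g$comp[g$comp$tissue == "xylem" & g$comp$zone == "apex", ]
  expect_setequal(unique(ax$kind), c("apoplast", "cytosol", "vacuole"))
  # every living cell has exactly one compartment of each kind
  liv <- g$comp[!(g$comp$tissue == "xylem" & g$comp$zone == "mature"), ]
  counts <- table(liv$layer, liv$ring)
  expect_true(all(counts[, 1:4] == 3))
  expect_true(all(counts[1:6, 5] == 3))     # apex xylem cells
  expect_true(all(counts[7:30, 5] == 0))    # mature xylem: conduit only
  expect_true(all(g$comp$V0 > 0))
  expect_equal(g$fresh_weight, sum(g$comp$V0) * 1000)
})

test_that("degenerate and hand-enumerated grids have the right counts", {
  g1 <- build_root_grid(n_axial = 1, apex_layers = 1)
  expect_equal(sum(g1$comp$zone == "mature"), 0)
  expect_equal(nrow(g1$comp), 5 * 3)   # all-apex: every ring living
  # 3 layers, 1 apex: brute-force enumeration oracle
  g3 <- build_root_grid(n_axial = 3, apex_layers = 1)
  n_expected <- 0
  for (l in 0:2) for (r in 0:4) {
    living <- !(r == 4 && l >= 1)
    n_expected <- n_expected + if (living) 3 else 1
  }
  expect_equal(nrow(g3$comp), n_expected)
  # indexing is layer-major and 0-based with layer 0 at the tip
  expect_true(all(diff(g3$comp$layer) >= 0))
  expect_equal(min(g3$comp$layer), 0)
})

test_that("grid validation errors name the offending field", {
  expect_error(build_root_grid(n_axial = 0), "n_axial")
  expect_error(build_root_grid(apex_layers = 99), "apex_layers")
  expect_error(build_root_grid(cell_height = -1), "cell_height")
  rs <- default_ring_spec()
  rs$name[2] <- "pith"
  expect_error(build_root_grid(ring_spec = rs), "ring_spec")
  rs2 <- default_ring_spec(c(60, 45, 50, 20, 10, 0) * 1e-6)
  expect_error(build_root_grid(ring_spec = rs2), "ring_spec")
})

test_that("rebuilding with identical inputs is byte-identical", {
  g1 <- build_root_grid(n_axial = 4, apex_layers = 2)
  g2 <- build_root_grid(n_axial = 4, apex_layers = 2)
  expect_identical(serialize(g1, NULL), serialize(g2, NULL))
  e1 <- apply_barriers(g1, 0.25)
  e2 <- apply_barriers(g2, 0.25)
  expect_identical(serialize(e1, NULL), serialize(e2, NULL))
})

test_that("apex-only geometry has no blocked edges", {
  g <- build_root_grid(n_axial = 3, apex_layers = 3)
  expect_warning(e <- apply_barriers(g, 0.25), "no mature layers")
  expect_equal(sum(e$blocked), 0)
})

test_that("barriers block mature endodermal walls and membranes", {
  g <- build_root_grid(n_axial = 30, apex_layers = 6)
  e <- apply_barriers(g, passage_cell_fraction = 0)
  comp <- g$comp
  # every mature endodermis plasma-membrane edge blocked at fraction 0
  pm <- e[e$pathway == "plasma_membrane", ]
  endo_pm <- comp$tissue[pm$a] == "endodermis" & comp$zone[pm$a] == "mature"
  expect_true(all(pm$blocked[endo_pm]))
  expect_true(all(!pm$blocked[!endo_pm]))
  # every mature radial apoplastic edge across the endodermis blocked
  ar <- e[e$pathway == "apoplast_radial", ]
  endo_wall <- (comp$tissue[ar$a] == "endodermis" |
                comp$tissue[ar$b] == "endodermis") &
    comp$zone[ar$a] == "mature"
  expect_true(all(ar$blocked[endo_wall]))
  expect_true(all(!ar$blocked[!endo_wall]))
  # no apex edge is blocked
  apex_edge <- comp$zone[e$a] == "apex"
  expect_equal(sum(e$blocked[apex_edge]), 0)
})

test_that("blocked-edge count matches an independent recount on a toy grid", {
  g <- build_root_grid(n_axial = 3, apex_layers = 1)
  e <- apply_barriers(g, passage_cell_fraction = 0)
  comp <- g$comp
  # oracle: filter the full edge list by the barrier rules (boundary rows
  # have b = 0 and never match)
  tis_b <- ifelse(e$b > 0, comp$tissue[pmax(e$b, 1)], "")
  oracle <- sum((e$pathway == "plasma_membrane" &
                   comp$tissue[e$a] == "endodermis" &
                   comp$zone[e$a] == "mature") |
                (e$pathway == "apoplast_radial" &
                   comp$zone[e$a] == "mature" &
                   (comp$tissue[e$a] == "endodermis" | tis_b == "endodermis")))
  expect_equal(sum(e$blocked), oracle)
  # passage cells reopen some membranes deterministically
  e1 <- apply_barriers(g, passage_cell_fraction = 1)
  pm1 <- e1[e1$pathway == "plasma_membrane", ]
  expect_equal(sum(pm1$blocked), 0)
})

test_that("connectivity invariants: plasmodesmata, tonoplasts, boundaries", {
  g <- build_root_grid(n_axial = 4, apex_layers = 2)
  e <- apply_barriers(g, 0.25)
  comp <- g$comp
  pd <- e[e$pathway == "plasmodesma", ]
  expect_true(all(comp$kind[pd$a] == "cytosol" & comp$kind[pd$b] == "cytosol"))
  # plasmodesmata connect every radially/axially adjacent cytosol pair
  cy <- comp[comp$kind == "cytosol", ]
  n_expected <- 0
  for (i in seq_len(nrow(cy))) for (j in seq_len(nrow(cy))) {
    if (i >= j) next
    dl <- abs(cy$layer[i] - cy$layer[j]); dr <- abs(cy$ring[i] - cy$ring[j])
    if ((dl == 0 && dr == 1) || (dl == 1 && dr == 0)) n_expected <- n_expected + 1
  }
  expect_equal(nrow(pd), n_expected)
  ton <- e[e$pathway == "tonoplast", ]
  expect_true(all(comp$kind[ton$a] == "cytosol" & comp$kind[ton$b] == "vacuole"))
  expect_true(all(comp$layer[ton$a] == comp$layer[ton$b] &
                    comp$ring[ton$a] == comp$ring[ton$b]))
  # one external boundary edge per layer, one xylem-top edge in total
  expect_equal(sum(e$pathway == "boundary_external"), g$n_axial)
  expect_equal(sum(e$pathway == "boundary_xylem_top"), 1)
  top <- e[e$pathway == "boundary_xylem_top", ]
  expect_equal(comp$layer[top$a], g$n_axial - 1L)
  expect_equal(comp$tissue[top$a], "xylem")
  expect_true(all(e$area_m2 > 0 & e$length_m > 0))
})

test_that("connectivity exports to an edge-list CSV", {
  g <- build_root_grid(n_axial = 2, apex_layers = 1)
  e <- apply_barriers(g, 0)
  path <- tempfile(fileext = ".csv")
  write_connectivity_csv(e, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(e))
  expect_setequal(names(back), c("a", "b", "pathway", "area_m2", "length_m",
                                 "blocked"))
})
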