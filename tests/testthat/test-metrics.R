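mk_profile <- function(values, abscissa = seq_along(values)) {
  structure(list(surface = "wall", component = "T_n",
                 profile = data.frame(abscissa = abscissa, mean = values,
                                      std = 0, n = 1)),
            class = "traction_profiles")
}

test_that("mean traction respects weights and signs", {
  expect_equal(mean_traction(mk_profile(rep(42, 5))), 42)
  expect_equal(mean_traction(mk_profile(c(-700, -700, 700, 700))), 0)
  expect_equal(mean_traction(mk_profile(c(100, 300)), weights = c(1, 3)), 250)
})

test_that("coefficient of variation follows the sample definition", {
  expect_equal(coefficient_of_variation(mk_profile(rep(5, 4))), 0)
  expect_equal(coefficient_of_variation(mk_profile(c(100, 200, 300))), 0.5)
  expect_error(coefficient_of_variation(mk_profile(c(-1, 1))), "undefined")
  # scale invariance
  v <- c(80, 120, 150, 90)
  expect_equal(coefficient_of_variation(mk_profile(v * 7.3)),
               coefficient_of_variation(mk_profile(v)))
})

test_that("signal-to-noise ratio is the ratio of mean absolute profiles", {
  s <- mk_profile(c(90, -180, 270))
  n1 <- mk_profile(c(10, -20, 30))
  expect_equal(snr(s, n1), 9)
  expect_equal(snr(s, s), 1)
  expect_identical(snr(s, mk_profile(c(0, 0, 0))), Inf)
})

test_that("net force arithmetic matches the printed pairing", {
  # uniform outward 180 Pa over 500 um2 of wall: 90 nN
  n <- 10
  th <- 2 * pi * (seq_len(n) - 1) / n
  tf <- traction_field(seq_len(n), 180 * cbind(cos(th), sin(th), 0),
                       rep(50, n))
  outward <- cbind(cos(th), sin(th), 0)
  expect_equal(net_force(tf, component = outward, sign_filter = "positive"),
               90)
  zero <- traction_field(seq_len(n), matrix(0, n, 3), rep(50, n))
  expect_equal(net_force(zero), 0)
  expect_error(net_force(tf, nodes = 99), "unknown")
})

test_that("net force of a forward ring matches the prescribed integral", {
  case <- small_ring_case()
  tf <- case$truth
  # signed vertical force is zero; inward radial magnitude integrates to
  # |T| * band area
  expect_equal(net_force(tf, component = "z"), 0, tolerance = 1e-9)
  expect_equal(net_force(tf, component = "magnitude"),
               500 * sum(tf$area * wellTFM::ring_weight(
                 case$mesh$nodes[tf$node, 3], -4, 3)) * 1e-3,
               tolerance = 0.01)
})

test_that("contact area reproduces the closed-bottom cylinder", {
  g <- well_geometry(5.5, 11.5, fillet_bottom = 0, fillet_top = 0)
  expect_equal(contact_area(g), pi * 11 * 11.5 + pi * 5.5^2, tolerance = 1e-12)
  g2 <- well_geometry(1, 1, gel_height = 10, lateral_extent = 10,
                      fillet_bottom = 0, fillet_top = 0)
  expect_equal(contact_area(g2), 3 * pi, tolerance = 1e-12)
  # with fillets the area equals the meshed well surface within tolerance
  gm <- small_geometry()
  mesh <- small_mesh()
  mesh_area <- sum(wellTFM:::facet_areas(mesh, mesh$surface$well_wall)) +
    sum(wellTFM:::facet_areas(mesh, mesh$surface$well_bottom))
  expect_equal(contact_area(gm), mesh_area, tolerance = 0.02)
})

test_that("cell volume approximates the printed well volumes", {
  g <- well_geometry(5.25, 12)
  expect_equal(cell_volume(g), pi * 5.25^2 * 12, tolerance = 1e-12)
  expect_equal(cell_volume(g), 1039, tolerance = 0.001) # small well ~1060 um3
  g2 <- well_geometry(1, 1, gel_height = 10, lateral_extent = 10,
                      fillet_bottom = 0, fillet_top = 0)
  expect_equal(cell_volume(g2), pi, tolerance = 1e-12)
  # fillet-corrected volume equals the meshed cavity volume
  gm <- small_geometry()
  mesh <- small_mesh()
  cav <- gm$lateral_extent^2 * gm$gel_height -
    sum(wellTFM:::tet_volumes(mesh$nodes, mesh$tets))
  expect_equal(cell_volume(gm, fillet_correct = TRUE), cav, tolerance = 0.01)
})

test_that("well metrics bundle is consistent with its parts", {
  case <- small_ring_case()
  mesh <- case$mesh
  wall <- surface_nodes(mesh, "well_wall")
  sel <- case$truth$node %in% wall
  tf <- traction_field(case$truth$node[sel], case$truth$traction[sel, ],
                       case$truth$area[sel])
  wc <- decompose_wall(tf, mesh)
  m <- well_metrics(wc, small_geometry())
  expect_lt(m$mean_Tn_wall, 0) # contractile ring
  expect_equal(m$contact_area_um2, contact_area(small_geometry()))
  expect_equal(m$net_extensile_force_nN, 0, tolerance = 1e-9)
  expect_lt(m$net_contractile_force_nN, 0)
})
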