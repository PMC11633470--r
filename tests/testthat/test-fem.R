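confined_slab <- function(material, p = -100) {
  m <- memo("slab_mesh", build_box_mesh(10, 10, 5, n = c(4, 4, 4)))
  top_n <- surface_nodes(m, "top")
  areas <- surface_node_areas(m, "top")
  tf <- traction_field(top_n, cbind(0, 0, rep(p, length(top_n))),
                       unname(areas[as.character(top_n)]))
  base_n <- surface_nodes(m, "base")
  dr <- unique(rbind(
    data.frame(node = rep(base_n, each = 3), dof = rep(1:3, length(base_n)),
               value = 0),
    data.frame(node = surface_nodes(m, c("xmin", "xmax")), dof = 1, value = 0),
    data.frame(node = surface_nodes(m, c("ymin", "ymax")), dof = 2, value = 0)))
  list(mesh = m, tf = tf, dr = dr, top = top_n)
}

test_that("material model rejects unphysical parameters", {
  expect_error(material_model(-1), "modulus")
  expect_error(material_model(1000, 0.5), "Poisson")
  expect_error(material_model(1000, -1), "Poisson")
})

test_that("confined compression matches the closed form exactly", {
  E <- 15000; nu <- 0.45; p <- -100; h <- 5
  cs <- confined_slab(material_model(E, nu), p)
  sol <- solve_forward(cs$mesh, material_model(E, nu), cs$tf, dirichlet = cs$dr)
  uz_exact <- p * h * (1 + nu) * (1 - 2 * nu) / (E * (1 - nu))
  expect_equal(mean(sol$u[cs$top, 3]), uz_exact, tolerance = 1e-9)
  expect_lt(sol$residual, 1e-8)
})

test_that("zero load gives zero displacement; missing constraints error out", {
  mesh <- small_mesh()
  sol <- solve_forward(mesh, small_material(), NULL, system = small_system())
  expect_equal(max(abs(sol$u)), 0)
  expect_error(fem_system(mesh, small_material(), fixed_nodes = integer(0)),
               "singular|constraints")
})

test_that("global equilibrium: base reactions balance the applied load", {
  case <- small_ring_case()
  applied <- colSums(case$truth$traction * case$truth$area)
  reac <- colSums(case$forward$reactions)
  expect_equal(reac, applied, tolerance = 1e-6)
})

test_that("linear solver scales linearly with the load", {
  mesh <- small_mesh()
  tf <- ring_traction(mesh, -500, width = 3)
  tf2 <- tf
  tf2$traction <- tf$traction * 2.5
  u1 <- solve_forward(mesh, small_material(), tf, system = small_system())$u
  u2 <- solve_forward(mesh, small_material(), tf2, system = small_system())$u
  expect_equal(u2, 2.5 * u1, tolerance = 1e-10)
})

test_that("mirror-symmetric load yields a mirror-symmetric field", {
  # uniform pressure on the well floor is symmetric about the x-z plane; the
  # node set mirrors onto itself, but the tet face diagonals do not, so the
  # discrete solution is symmetric only up to discretization error
  mesh <- small_mesh()
  bot <- surface_nodes(mesh, "well_bottom")
  a <- surface_node_areas(mesh, c("well_wall", "well_bottom"))
  tf <- traction_field(bot, cbind(0, 0, rep(-200, length(bot))),
                       unname(a[as.character(bot)]))
  u <- solve_forward(mesh, small_material(), tf, system = small_system())$u
  key <- function(p) paste(round(p[, 1], 6), round(p[, 2], 6),
                           round(p[, 3], 6))
  mirror <- match(key(cbind(mesh$nodes[, 1], -mesh$nodes[, 2],
                            mesh$nodes[, 3])), key(mesh$nodes))
  ok <- !is.na(mirror)
  expect_gt(mean(ok), 0.99)
  ref <- cbind(u[mirror[ok], 1], -u[mirror[ok], 2], u[mirror[ok], 3])
  asym <- sqrt(sum((u[ok, ] - ref)^2)) / sqrt(sum(u[ok, ]^2))
  expect_lt(asym, 0.05)
})

test_that("Neo-Hookean law converges and agrees with linear at small strain", {
  E <- 15000; nu <- 0.45; p <- -50
  cs <- confined_slab(material_model(E, nu), p)
  lin <- solve_forward(cs$mesh, material_model(E, nu), cs$tf, dirichlet = cs$dr)
  nh <- solve_forward(cs$mesh, material_model(E, nu, law = "neo_hookean"),
                      cs$tf, dirichlet = cs$dr)
  expect_lt(nh$residual, 1e-8)
  expect_equal(mean(nh$u[cs$top, 3]), mean(lin$u[cs$top, 3]), tolerance = 0.01)
})

test_that("nodal force to traction conversion conserves force exactly", {
  mesh <- small_mesh()
  wall <- surface_nodes(mesh, "well_wall")
  areas <- surface_node_areas(mesh, c("well_wall", "well_bottom"))
  f <- matrix(rnorm(3 * length(wall)), ncol = 3)
  tf <- nodal_force_to_traction(mesh, wall, f)
  expect_equal(tf$traction * tf$area, f, tolerance = 1e-12)
  # 1 Pa = 1 pN/um2: force (2, 0, 0) pN on a 2 um2 node is 1 Pa
  one <- nodal_force_to_traction(mesh, wall[1], matrix(c(2, 0, 0), 1))
  expect_equal(one$traction[1, 1] * one$area[1], 2)
  expect_error(nodal_force_to_traction(mesh, max(wall) + 1e5,
                                       matrix(0, 1, 3)), "not on")
})

test_that("uniform pressure round-trips through assembly and inversion", {
  mesh <- small_mesh()
  bot <- surface_nodes(mesh, "well_bottom")
  areas <- surface_node_areas(mesh, c("well_wall", "well_bottom"))
  a <- unname(areas[as.character(bot)])
  p <- 200
  tf <- traction_field(bot, cbind(0, 0, rep(p, length(bot))), a)
  forces <- tf$traction * tf$area
  rec <- nodal_force_to_traction(mesh, bot, forces)
  expect_equal(rec$traction[, 3], rep(p, length(bot)), tolerance = 1e-9)
})

test_that("probe displacement is mesh-converged within 2% under halving", {
  # smooth-field probe in the gel below the well; the response is normalized
  # by the realized total load so only discretization of the solution is
  # measured, not the surface-area quadrature of the load band
  g <- small_geometry()
  mat <- small_material()
  probe <- matrix(c(0.3, 0.2, -15), 1)
  u_at <- function(h) {
    mesh <- build_mesh(g, h)
    bot <- surface_nodes(mesh, "well_bottom")
    a <- surface_node_areas(mesh, c("well_wall", "well_bottom"))
    tf <- traction_field(bot, cbind(0, 0, rep(-200, length(bot))),
                         unname(a[as.character(bot)]))
    fw <- solve_forward(mesh, mat, tf)
    displacement_interpolator(mesh, fw$u)(probe) /
      abs(sum(tf$traction[, 3] * tf$area))
  }
  u1 <- u_at(1.6)
  u2 <- u_at(0.8)
  expect_lt(sqrt(sum((u2 - u1)^2)) / sqrt(sum(u2^2)), 0.02)
})
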