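test_that("surface interpolation reproduces constant and affine fields", {
  mesh <- small_mesh()
  grid <- list(dim = c(9L, 9L, 8L), origin = c(-16, -16, -20),
               spacing = c(4, 4, 3))
  pts <- as.matrix(expand.grid(x = seq(-16, 16, 4), y = seq(-16, 16, 4),
                               z = seq(-20, 1, 3)))
  u0 <- c(0.1, -0.2, 0.05)
  f_const <- displacement_field(pts, matrix(u0, nrow(pts), 3, byrow = TRUE),
                                grid = grid)
  m <- interpolate_measured_to_surface(f_const, mesh)
  expect_equal(m$u, matrix(u0, length(m$node), 3, byrow = TRUE),
               tolerance = 1e-12)

  A <- matrix(c(0.01, 0.002, 0, -0.003, 0.005, 0.001, 0, 0.002, -0.004), 3)
  b <- c(0.02, -0.01, 0.03)
  f_aff <- displacement_field(pts, pts %*% t(A) +
                                matrix(b, nrow(pts), 3, byrow = TRUE),
                              grid = grid)
  m2 <- interpolate_measured_to_surface(f_aff, mesh)
  exact <- mesh$nodes[m2$node, ] %*% t(A) +
    matrix(b, length(m2$node), 3, byrow = TRUE)
  expect_equal(m2$u, exact, tolerance = 1e-6)
  expect_false(any(m2$extrapolated))
})

test_that("nodes outside the data hull take nearest values and are flagged", {
  mesh <- small_mesh()
  # grid covering only the lower half of the gel: top nodes are outside
  grid <- list(dim = c(9L, 9L, 4L), origin = c(-16, -16, -20),
               spacing = c(4, 4, 3))
  pts <- as.matrix(expand.grid(x = seq(-16, 16, 4), y = seq(-16, 16, 4),
                               z = seq(-20, -11, 3)))
  f <- displacement_field(pts, cbind(pts[, 3] * 0.01, 0, 0), grid = grid)
  m <- interpolate_measured_to_surface(f, mesh)
  top_nodes <- mesh$nodes[m$node, 3] > -10
  expect_true(all(m$extrapolated[top_nodes]))
  # nearest sample is on the z = -11 plane
  expect_equal(unique(round(m$u[top_nodes, 1], 9)), -0.11)
  expect_error(interpolate_measured_to_surface(
    displacement_field(pts[1:3, ], pts[1:3, ] * 0), mesh), "4 valid")
})

test_that("noiseless ring tractions are recovered within 5% RMS", {
  case <- small_ring_case()
  mesh <- case$mesh
  surf <- small_surface_nodes()
  meas <- list(node = surf, u = case$forward$u[surf, ])
  inv <- solve_inverse(mesh, small_material(), meas, inverse_config(0),
                       operator = small_operator())
  expect_lt(traction_rms_error(inv$tractions, case$truth), 0.05)
  expect_lt(inv$misfit, 1e-10)
})

test_that("zero measurements give zero tractions and zero misfit", {
  mesh <- small_mesh()
  surf <- small_surface_nodes()
  meas <- list(node = surf, u = matrix(0, length(surf), 3))
  inv <- solve_inverse(mesh, small_material(), meas,
                       inverse_config(regularization_lambda = 1e-3),
                       operator = small_operator())
  expect_lt(max(abs(inv$tractions$traction)), 1e-9)
  expect_lt(inv$misfit, 1e-18)
})

test_that("the inverse solution carries no gel-top traction by construction", {
  mesh <- small_mesh()
  top_only <- setdiff(surface_nodes(mesh, "gel_top"),
                      surface_nodes(mesh, c("well_wall", "well_bottom")))
  expect_false(any(top_only %in% small_operator()$t_nodes))
})

test_that("noisy ring recovery with an L-curve lambda stays within 15%", {
  case <- small_ring_case()
  mesh <- case$mesh
  surf <- small_surface_nodes()
  set.seed(71)
  noise <- matrix(rnorm(3 * length(surf), sd = 0.01), ncol = 3) # 10 nm RMS
  meas <- list(node = surf, u = case$forward$u[surf, ] + noise)
  lam <- choose_lambda_lcurve(mesh, small_material(), meas,
                              operator = small_operator(),
                              lambdas = 10^seq(-6, -1, length.out = 11))
  inv <- solve_inverse(mesh, small_material(), meas,
                       inverse_config(lam$lambda), operator = small_operator())
  wall <- surface_nodes(mesh, "well_wall")
  sel <- inv$tractions$node %in% wall
  wc <- decompose_wall(traction_field(inv$tractions$node[sel],
                                      inv$tractions$traction[sel, ],
                                      inv$tractions$area[sel]), mesh)
  amp <- ring_amplitude(wc, z_center = -4, width = 3)
  expect_lt(abs(amp + 500) / 500, 0.15)
})

test_that("misfit is non-increasing as lambda decreases", {
  case <- small_ring_case()
  surf <- small_surface_nodes()
  set.seed(5)
  meas <- list(node = surf,
               u = case$forward$u[surf, ] +
                 matrix(rnorm(3 * length(surf), sd = 0.005), ncol = 3))
  ms <- vapply(c(1e-1, 1e-3, 1e-5), function(l)
    solve_inverse(case$mesh, small_material(), meas, inverse_config(l),
                  operator = small_operator())$misfit, numeric(1))
  expect_true(all(diff(ms) <= 1e-12))
})

test_that("direct Dirichlet reproduces consistent data but amplifies noise on the top", {
  case <- small_ring_case()
  mesh <- case$mesh
  surf <- small_surface_nodes()
  meas <- list(node = surf, u = case$forward$u[surf, ])
  dd <- direct_dirichlet_solve(mesh, small_material(), meas)
  # well-surface tractions match ground truth within discretization error
  wall_bot <- rbind(dd$well_wall$traction, dd$well_bottom$traction)
  expect_lt(traction_rms_error(
    traction_field(c(dd$well_wall$node, dd$well_bottom$node), wall_bot,
                   c(dd$well_wall$area, dd$well_bottom$area)),
    case$truth), 0.35)
  top_clean <- mean(sqrt(rowSums(dd$gel_top$traction^2)))

  set.seed(9)
  noisy <- meas
  idx_top <- meas$node %in% surface_nodes(mesh, "gel_top")
  noisy$u[idx_top, ] <- noisy$u[idx_top, ] +
    matrix(rnorm(3 * sum(idx_top), sd = 0.01), ncol = 3)
  ddn <- direct_dirichlet_solve(mesh, small_material(), noisy)
  top_noisy <- mean(sqrt(rowSums(ddn$gel_top$traction^2)))
  expect_gt(top_noisy, 3 * top_clean)

  zero <- list(node = surf, u = matrix(0, length(surf), 3))
  ddz <- direct_dirichlet_solve(mesh, small_material(), zero)
  expect_lt(max(abs(ddz$well_wall$traction)), 1e-9)
})

test_that("misfit satisfies its definition and the triangle inequality", {
  expect_equal(misfit(matrix(1, 4, 3), matrix(1, 4, 3)), 0)
  u1 <- matrix(0, 1, 3)
  u2 <- matrix(c(0.1, 0, 0), 1, 3)
  expect_equal(misfit(u2, u1), 0.01)
  expect_error(misfit(matrix(0, 3, 3), matrix(0, 4, 3)), "mismatched")
  set.seed(2)
  a <- matrix(rnorm(15), 5, 3)
  b <- matrix(rnorm(15), 5, 3)
  c <- matrix(rnorm(15), 5, 3)
  w <- runif(5)
  d <- function(x, y) sqrt(misfit(x, y, w))
  expect_lte(d(a, c), d(a, b) + d(b, c) + 1e-12)
})

test_that("zero-signal reconstructions scale linearly with noise amplitude", {
  mesh <- small_mesh()
  surf <- small_surface_nodes()
  op <- small_operator()
  sds <- c(0.005, 0.01, 0.02, 0.04)
  mean_mag <- vapply(seq_along(sds), function(i) {
    set.seed(100 + i)
    meas <- list(node = surf,
                 u = matrix(rnorm(3 * length(surf), sd = sds[i]), ncol = 3))
    inv <- solve_inverse(mesh, small_material(), meas, inverse_config(1e-3),
                         operator = op)
    mean(sqrt(rowSums(inv$tractions$traction^2)))
  }, numeric(1))
  fit <- stats::lm(mean_mag ~ 0 + sds)
  expect_gt(summary(fit)$r.squared, 0.98)
  expect_gt(coef(fit)[1], 0)
})
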