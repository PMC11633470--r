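test_that("bead sampling is empty at zero density and reproducible", {
  g <- small_geometry()
  b0 <- sample_beads(g, bulk_density = 0, surface_density = 0, seed = 1)
  expect_equal(nrow(b0$positions), 0L)
  b1 <- sample_beads(g, seed = 5)
  b2 <- sample_beads(g, seed = 5)
  expect_identical(b1$positions, b2$positions)
  b3 <- sample_beads(g, seed = 6)
  expect_false(isTRUE(all.equal(dim(b1$positions), dim(b3$positions))) &&
               isTRUE(all.equal(b1$positions, b3$positions)))
})

test_that("all beads lie inside the gel, outside the cavity", {
  g <- small_geometry()
  b <- sample_beads(g, bulk_density = 0.1, surface_density = 2, seed = 2)
  p <- b$positions
  r <- sqrt((p[, 1] - g$center_xy[1])^2 + (p[, 2] - g$center_xy[2])^2)
  rc <- cavity_radius(g, p[, 3])
  expect_true(all(is.na(rc) | r >= rc - 1e-9))
  expect_true(all(p[, 3] <= g$top_z + 1e-9))
})

test_that("bulk bead count follows the Poisson expectation", {
  # 0.0005 beads/voxel at 0.104 um pixels and 0.2 um steps, counted in a
  # region of 64 x 64 x 16 voxels fully inside the gel: Poisson mean 32.768
  vox <- 0.104^2 * 0.2
  dens <- 0.0005 / vox
  g <- well_geometry(5, 8, gel_height = 40, lateral_extent = 40)
  b <- sample_beads(g, bulk_density = dens, surface_density = 0,
                    bulk_depth = 20, seed = 9)
  p <- b$positions
  lx <- 64 * 0.104; lz <- 16 * 0.2
  inside <- p[, 1] > -18 & p[, 1] < -18 + lx &
    p[, 2] > -18 & p[, 2] < -18 + lx &
    p[, 3] > -20 & p[, 3] < -20 + lz
  mu <- 32.768
  expect_lt(abs(sum(inside) - mu), 3 * sqrt(mu))
})

test_that("bead counts scale linearly with density", {
  g <- small_geometry()
  dens <- c(0.05, 0.1, 0.2)
  counts <- vapply(seq_along(dens), function(i)
    nrow(sample_beads(g, bulk_density = dens[i], surface_density = 0,
                      seed = 20 + i)$positions), numeric(1))
  fit <- stats::lm(counts ~ 0 + dens)
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("rendering reproduces bead positions and is deterministic", {
  b0 <- bead_field(matrix(numeric(0), 0, 3))
  st0 <- render_stack(b0, c(16, 16, 8), noise_sd = 0)
  expect_true(all(st0$data == 0))

  b <- bead_field(matrix(c(10, 10, -5), 1, 3))
  st <- render_stack(b, c(192, 192, 80), origin = c(0, 0, -12), noise_sd = 0)
  w <- st$data / sum(st$data)
  cx <- sum(apply(w, 1, sum) * ((seq_len(192) - 1) * 0.104))
  cy <- sum(apply(w, 2, sum) * ((seq_len(192) - 1) * 0.104))
  cz <- sum(apply(w, 3, sum) * (-12 + (seq_len(80) - 1) * 0.2))
  expect_lt(max(abs(c(cx - 10, cy - 10, cz + 5))), 0.05)

  bn <- bead_field(matrix(runif(30) * 8, 10, 3))
  s1 <- render_stack(bn, c(64, 64, 32), noise_sd = 0.05, seed = 4)
  s2 <- render_stack(bn, c(64, 64, 32), noise_sd = 0.05, seed = 4)
  expect_identical(s1$data, s2$data)
})

test_that("warping displaces beads by the prescribed field", {
  b <- bead_field(matrix(runif(24, 1, 7), 8, 3))
  expect_identical(warp_beads(b, function(p) p * 0)$positions, b$positions)
  sh <- warp_beads(b, function(p) cbind(rep(1, nrow(p)), 0, 0))
  expect_equal(sh$positions[, 1], b$positions[, 1] + 1)
  expect_equal(sh$positions[, 2:3], b$positions[, 2:3])
  expect_error(warp_beads(b, function(p) {
    u <- p * 0; u[3, 1] <- NA; u
  }), "bead")
})

test_that("warping with a forward FEM field matches the interpolated solution", {
  case <- small_ring_case()
  interp <- displacement_interpolator(case$mesh, case$forward$u)
  g <- small_geometry()
  b <- sample_beads(g, bulk_density = 0.02, surface_density = 1, seed = 13)
  w <- warp_beads(b, interp)
  expect_equal(w$positions, b$positions + interp(b$positions))
  # surface beads move with the loaded wall
  wall_band <- abs(sqrt((b$positions[, 1])^2 + (b$positions[, 2])^2) -
                   g$radius) < 0.7 &
    abs(b$positions[, 3] - (g$top_z - g$depth / 2)) < 1.5
  expect_gt(max(sqrt(rowSums((w$positions - b$positions)^2))[wall_band]), 0.02)
})

test_that("zero-deformation closure: PIV of an identical pair is null", {
  st <- piv_test_stack()
  f <- piv3d(st, st)
  expect_true(any(f$valid))
  expect_lt(sqrt(mean(f$vectors[f$valid, ]^2)), 0.02)
})
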