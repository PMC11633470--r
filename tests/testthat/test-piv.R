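test_that("piv_config validates its fields", {
  expect_error(piv_config(c(4, 32, 8)), "8 voxels")
  expect_error(piv_config(c(32, 32, 2)), "z")
  expect_error(piv_config(overlap_fraction = 1), "overlap")
  expect_error(piv_config(max_displacement = 0), "max_displacement")
})

test_that("integer voxel translations are recovered exactly on interior boxes", {
  st <- piv_test_stack()
  sh <- c(2, 3, 1)
  f <- piv3d(st, roll_stack(st, sh))
  expect_gt(mean(f$valid), 0.9)
  # interior: the offset window stays inside the stack
  d <- dim(st$data)
  box <- c(32, 32, 8)
  idx0 <- sweep(sweep(sweep(f$points, 2, st$origin, "-"),
                      2, c(0.104, 0.104, 0.2), "/"),
                2, (box - 1) / 2, "-") + 1
  interior <- idx0[, 1] + sh[1] + box[1] - 1 <= d[1] &
    idx0[, 2] + sh[2] + box[2] - 1 <= d[2] &
    idx0[, 3] + sh[3] + box[3] - 1 <= d[3]
  expect_gt(sum(interior), 50)
  expect_true(all(f$valid[interior]))
  err <- abs(sweep(f$vectors[interior, ], 2, sh * c(0.104, 0.104, 0.2)))
  expect_lt(max(err), 1e-9)
})

test_that("an identical pair yields the zero field", {
  st <- piv_test_stack()
  f <- piv3d(st, st)
  expect_lt(max(abs(f$vectors[f$valid, ])), 1e-9)
})

test_that("subpixel shifts are recovered within a tenth of a pixel", {
  st <- piv_test_stack()
  def <- piv_test_stack(shift = c(0.4 * 0.104, 0, 0))
  f <- piv3d(st, def)
  ex <- f$vectors[f$valid, 1] / 0.104 - 0.4
  expect_gte(mean(abs(ex) <= 0.1), 0.95)
  # y and z stay near zero
  expect_lt(median(abs(f$vectors[f$valid, 2])), 0.02)
})

test_that("axial errors are not smaller than lateral errors", {
  st <- piv_test_stack()
  fx <- piv3d(st, piv_test_stack(shift = c(0.4 * 0.104, 0, 0)))
  fz <- piv3d(st, piv_test_stack(shift = c(0, 0, 0.4 * 0.2)))
  ex <- abs(fx$vectors[fx$valid, 1] / 0.104 - 0.4)
  ez <- abs(fz$vectors[fz$valid, 3] / 0.2 - 0.4)
  expect_gte(median(ez), median(ex))
})

test_that("PIV response is linear in the displacement for small shifts", {
  st <- piv_test_stack()
  f1 <- piv3d(st, piv_test_stack(shift = c(0.2 * 0.104, 0, 0)))
  f2 <- piv3d(st, piv_test_stack(shift = c(0.4 * 0.104, 0, 0)))
  both <- f1$valid & f2$valid
  expect_equal(median(f2$vectors[both, 1]) / median(f1$vectors[both, 1]), 2,
               tolerance = 0.1)
})

test_that("piv3d rejects mismatched inputs", {
  a <- image_stack(array(1, c(32, 32, 8)), 0.1, 0.2)
  b <- image_stack(array(1, c(32, 32, 10)), 0.1, 0.2)
  expect_error(piv3d(a, b), "shape")
  cc <- image_stack(array(1, c(32, 32, 8)), 0.2, 0.2)
  expect_error(piv3d(a, cc), "calibration")
  small <- image_stack(array(1, c(16, 16, 4)), 0.1, 0.2)
  expect_error(piv3d(small, small), "larger than the stack")
})

test_that("three-point peak refinement matches the closed form", {
  # separable Gaussian sampled on a grid: the log-space three-point fit is
  # exact, so a peak at +0.3 voxels refines to 0.3
  x <- 1:7
  g1 <- exp(-(x - 4.3)^2 / (2 * 1.1^2))
  g2 <- exp(-(x - 4.0)^2 / (2 * 1.3^2))
  g3 <- exp(-(x - 4.0)^2 / (2 * 0.9^2))
  vol <- g1 %o% g2 %o% g3
  sp <- subpixel_peak(vol)
  expect_true(sp$valid)
  expect_equal(sp$offset, c(0.3, 0, 0), tolerance = 1e-6)

  # symmetric peak centered on a voxel: zero fractional part
  sym <- exp(-(x - 4)^2) %o% exp(-(x - 4)^2) %o% exp(-(x - 4)^2)
  expect_equal(subpixel_peak(sym)$offset, c(0, 0, 0), tolerance = 1e-12)

  # peak on the volume corner is flagged invalid
  corner <- array(0, c(5, 5, 5)); corner[1, 1, 1] <- 1
  expect_false(subpixel_peak(corner)$valid)
})

test_that("normalized-median filter replaces outliers and is idempotent", {
  grid <- list(dim = c(5L, 5L, 3L), origin = c(0, 0, 0), spacing = c(1, 1, 1))
  n <- prod(grid$dim)
  pts <- as.matrix(expand.grid(x = 0:4, y = 0:4, z = 0:2))
  vec <- matrix(rep(c(0.5, 0.2, 0.1), each = n), n, 3)
  f <- displacement_field(pts, vec, grid = grid)
  expect_equal(filter_outliers(f)$vectors, f$vectors)

  f2 <- f
  f2$vectors[33, ] <- f2$vectors[33, ] + c(3, 0, 0) # 10x the neighbor spread
  g1 <- filter_outliers(f2)
  expect_false(g1$valid[33])
  expect_equal(g1$vectors[33, ], c(0.5, 0.2, 0.1))
  g2 <- filter_outliers(g1)
  expect_equal(g2$vectors, g1$vectors)
  expect_equal(g2$valid, g1$valid)

  f3 <- f
  f3$valid[] <- FALSE
  expect_error(filter_outliers(f3), "invalid")
})

test_that("seeding diagnostics match the printed arithmetic", {
  # 0.0005 particles/voxel in a 32 x 32 x 8 box: about four particles
  expect_equal(diagnose_seeding(config = piv_config(), density = 5e-4), 4.096)
  empty <- image_stack(array(0, c(64, 64, 16)), 0.104, 0.2)
  expect_equal(diagnose_seeding(empty), 0)
})

test_that("detected seeding density matches the rendered bead count", {
  # 12 beads per 32 x 32 x 8 interrogation volume, as typically encountered
  # on the gel surface
  set.seed(31)
  n_boxes <- c(3, 3, 5)
  npart <- 12 * prod(n_boxes)
  lim <- n_boxes * c(32, 32, 8) * c(0.104, 0.104, 0.2)
  pos <- cbind(runif(npart, 0, lim[1]), runif(npart, 0, lim[2]),
               runif(npart, 0, lim[3]))
  st <- render_stack(bead_field(pos), n_boxes * c(32, 32, 8))
  est <- diagnose_seeding(st)
  expect_lt(abs(est - 12) / 12, 0.2)
})
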