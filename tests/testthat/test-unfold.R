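# wall traction field with prescribed values at chosen angles
wall_field_at <- function(mesh, fun) {
  wall <- surface_nodes(mesh, "well_wall")
  p <- mesh$nodes[wall, , drop = FALSE]
  th <- atan2(p[, 2], p[, 1]) %% (2 * pi)
  a <- surface_node_areas(mesh, c("well_wall", "well_bottom"))
  traction_field(wall, fun(th, p[, 3]), unname(a[as.character(wall)]))
}

test_that("wall decomposition matches the aligned and rotated frames", {
  mesh <- small_mesh()
  wc <- decompose_wall(wall_field_at(mesh, function(th, z)
    matrix(c(100, 0, 0), length(th), 3, byrow = TRUE)), mesh)
  d <- wc$data
  near0 <- which.min(abs(d$theta))
  expect_equal(d$T_n[near0], 100 * cos(d$theta[near0]), tolerance = 1e-9)
  expect_equal(d$T_v[near0], 0)
  # at theta = 90 degrees, T = (0, -100, 0) is purely inward
  wc2 <- decompose_wall(wall_field_at(mesh, function(th, z)
    matrix(c(0, -100, 0), length(th), 3, byrow = TRUE)), mesh)
  d2 <- wc2$data
  at90 <- which.min(abs(d2$theta - pi / 2))
  expect_equal(d2$T_n[at90], -100, tolerance = 1e-6)
  expect_lt(abs(d2$T_c[at90]), 1e-6)
})

test_that("cylindrical frames conserve the traction magnitude", {
  mesh <- small_mesh()
  set.seed(4)
  tf <- wall_field_at(mesh, function(th, z)
    matrix(rnorm(3 * length(th), sd = 300), ncol = 3))
  wc <- decompose_wall(tf, mesh)
  d <- wc$data
  mag2 <- rowSums(tf$traction[match(d$node, tf$node), ]^2)
  expect_lt(max(abs(d$T_n^2 + d$T_v^2 + d$T_c^2 - mag2)), 1e-10 * max(mag2))
  # round trip back to Cartesian
  ct <- cos(d$theta); st <- sin(d$theta)
  rec <- cbind(d$T_n * ct - d$T_c * st, d$T_n * st + d$T_c * ct, d$T_v)
  expect_equal(rec, unname(tf$traction[match(d$node, tf$node), ]),
               tolerance = 1e-10)
})

test_that("bottom decomposition handles the axis and signs", {
  mesh <- small_mesh()
  bot <- surface_nodes(mesh, "well_bottom")
  p <- mesh$nodes[bot, , drop = FALSE]
  a <- surface_node_areas(mesh, c("well_wall", "well_bottom"))
  tf <- traction_field(bot, matrix(c(-200, 0, 0), length(bot), 3, byrow = TRUE),
                       unname(a[as.character(bot)]))
  bc <- decompose_bottom(tf, mesh)
  d <- bc$data
  center <- d$r < 1e-9
  expect_true(any(center))
  expect_true(all(d$axis_degenerate[center]))
  expect_equal(d$T_r[center], rep(0, sum(center)))
  # at theta ~ 0, T = (-200, 0, 0) points inward: T_r = -200
  off <- which(!d$axis_degenerate)
  at0 <- off[which.min(abs(d$theta[off]))]
  expect_equal(d$T_r[at0], -200 * cos(d$theta[at0]), tolerance = 1e-9)
  expect_equal(d$T_n[at0], 0)
})

test_that("unfolded wall maps reproduce constants, nodes and the seam", {
  mesh <- small_mesh()
  wc <- decompose_wall(wall_field_at(mesh, function(th, z)
    300 * cbind(cos(th), sin(th), 0)), mesh)
  map <- unfold_wall_map(wc, "T_n", n_theta = 36, n_z = 20)
  expect_equal(range(map$values), c(300, 300), tolerance = 1e-9)
  # z-extent excludes the top band
  g <- mesh$geometry
  expect_equal(max(map$z), g$top_z - 1)
  expect_equal(min(map$z), g$top_z - g$depth)

  # linear-in-z component: columns identical across theta and linear in z
  wc2 <- decompose_wall(wall_field_at(mesh, function(th, z)
    (50 * z) * cbind(cos(th), sin(th), 0)), mesh)
  map2 <- unfold_wall_map(wc2, "T_n", n_theta = 24, n_z = 15)
  expect_lt(max(abs(sweep(map2$values, 1, 50 * map2$z))), 1e-6)
  # seam: values at theta = 0 and 360 agree
  expect_lt(max(abs(map2$values[, 1] - map2$values[, ncol(map2$values)])),
            1e-9)

  empty <- wc
  empty$data <- wc$data[0, ]
  expect_error(unfold_wall_map(empty), "empty")
})

test_that("scattered interpolation reproduces nodal values exactly", {
  set.seed(8)
  p <- cbind(runif(60), runif(60))
  v <- rnorm(60)
  got <- wellTFM:::interp_scattered(p, v, p)
  expect_equal(got, v, tolerance = 1e-9)
  # linear precision inside the hull
  q <- cbind(runif(200, 0.2, 0.8), runif(200, 0.2, 0.8))
  lin <- function(x) 2 + 3 * x[, 1] - 5 * x[, 2]
  expect_equal(wellTFM:::interp_scattered(p, lin(p), q), lin(q),
               tolerance = 1e-8)
})

test_that("circumferential profiles compute circular statistics", {
  mesh <- small_mesh()
  wc <- decompose_wall(wall_field_at(mesh, function(th, z)
    250 * cbind(cos(th), sin(th), 0)), mesh)
  map <- unfold_wall_map(wc, "T_n", n_theta = 48, n_z = 12)
  prof <- circumferential_profile(map)
  expect_equal(prof$profile$mean, rep(250, 12), tolerance = 1e-9)
  expect_equal(prof$profile$std, rep(0, 12), tolerance = 1e-9)

  # T_n = A sin(theta): mean ~ 0, std ~ A/sqrt(2) per row
  A <- 120
  wc2 <- decompose_wall(wall_field_at(mesh, function(th, z)
    (A * sin(th)) * cbind(cos(th), sin(th), 0)), mesh)
  map2 <- unfold_wall_map(wc2, "T_n", n_theta = 72, n_z = 10)
  prof2 <- circumferential_profile(map2)
  expect_lt(max(abs(prof2$profile$mean)), 0.03 * A)
  expect_equal(prof2$profile$std, rep(A / sqrt(2), 10), tolerance = 0.05)

  # single-row map degenerates to a length-1 profile
  one <- map
  one$values <- map$values[1, , drop = FALSE]
  one$z <- map$z[1]
  expect_equal(nrow(circumferential_profile(one)$profile), 1L)
})

test_that("map means agree with node-area-weighted means within 3%", {
  case <- small_ring_case()
  mesh <- case$mesh
  wall <- surface_nodes(mesh, "well_wall")
  sel <- case$truth$node %in% wall
  tf <- traction_field(case$truth$node[sel], case$truth$traction[sel, ],
                       case$truth$area[sel])
  # spread the ring over all wall nodes for a nonzero full-wall mean
  wc <- decompose_wall(wall_field_at(mesh, function(th, z)
    (-300 - 20 * z) * cbind(cos(th), sin(th), 0)), mesh)
  map <- unfold_wall_map(wc, "T_n", n_theta = 72, n_z = 40)
  d <- wc$data
  keep <- d$z <= mesh$geometry$top_z - 1
  node_mean <- sum(d$T_n[keep] * d$area[keep]) / sum(d$area[keep])
  map_mean <- mean(map$values[, -ncol(map$values)])
  expect_equal(map_mean, node_mean, tolerance = 0.03)
})

test_that("bottom maps rasterize the disk", {
  mesh <- small_mesh()
  bot <- surface_nodes(mesh, "well_bottom")
  a <- surface_node_areas(mesh, c("well_wall", "well_bottom"))
  tf <- traction_field(bot, matrix(c(0, 0, 150), length(bot), 3, byrow = TRUE),
                       unname(a[as.character(bot)]))
  bc <- decompose_bottom(tf, mesh)
  map <- unfold_bottom_map(bc, "T_n", n = 40)
  inside <- !is.na(map$values)
  expect_gt(mean(inside), 0.6)
  expect_equal(range(map$values[inside]), c(150, 150), tolerance = 1e-9)
  prof <- circumferential_profile(map)
  expect_equal(prof$profile$mean, rep(150, nrow(prof$profile)),
               tolerance = 1e-9)
})

test_that("profiles align at their lowest point with overhangs flagged", {
  mk <- function(depth, n = 12) {
    structure(list(surface = "wall", component = "T_n",
                   profile = data.frame(abscissa = seq(-depth, -1,
                                                       length.out = n),
                                        mean = rnorm(n), std = abs(rnorm(n)),
                                        n = 24)),
              class = "traction_profiles")
  }
  set.seed(1)
  p11 <- mk(11)
  p12 <- mk(12)
  al <- align_profiles(list(p11, p12))
  expect_equal(min(al[[1]]$profile$abscissa), 0)
  expect_equal(min(al[[2]]$profile$abscissa), 0)
  expect_true(all(al[[1]]$profile$displayed))
  expect_false(all(al[[2]]$profile$displayed)) # top of the deeper well flagged
  expect_equal(sum(!al[[2]]$profile$displayed),
               sum(al[[2]]$profile$abscissa > 10 + 1e-9))
  # identical and single profiles pass through unchanged (up to the shift)
  al2 <- align_profiles(list(p11))
  expect_equal(al2[[1]]$profile$mean, p11$profile$mean)
  expect_true(all(al2[[1]]$profile$displayed))
})
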