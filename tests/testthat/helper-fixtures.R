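# Shared fixtures, memoized so expensive objects (meshes, factorizations,
# operators) are built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

small_geometry <- function() well_geometry(5, 8, gel_height = 25,
                                           lateral_extent = 30)

small_mesh <- function() memo("small_mesh", build_mesh(small_geometry(), 1.6))

small_material <- function() material_model(15000, 0.45)

small_system <- function() memo("small_system",
                                fem_system(small_mesh(), small_material()))

small_operator <- function() memo("small_operator", {
  mesh <- small_mesh()
  surf <- surface_nodes(mesh, c("gel_top", "well_wall", "well_bottom"))
  traction_operator(mesh, small_material(), surf, system = small_system())
})

small_surface_nodes <- function()
  surface_nodes(small_mesh(), c("gel_top", "well_wall", "well_bottom"))

# forward solution of a contractile ring on the small mesh
small_ring_case <- function() memo("small_ring_case", {
  mesh <- small_mesh()
  tf <- ring_traction(mesh, -500, width = 3)
  fw <- solve_forward(mesh, small_material(), tf, system = small_system())
  list(mesh = mesh, truth = tf, forward = fw)
})

# uniformly seeded bead stack pair for PIV resolution tests
piv_test_stack <- function(shift = c(0, 0, 0), seed = 11) {
  key <- paste0("piv_pos_", seed)
  pos <- memo(key, {
    set.seed(seed)
    n <- round(0.0015 * 96 * 96 * 40)
    cbind(runif(n, 0, 96 * 0.104), runif(n, 0, 96 * 0.104),
          runif(n, 0, 40 * 0.2))
  })
  render_stack(bead_field(sweep(pos, 2, shift, "+")), c(96, 96, 40))
}

# circularly roll a stack's array by integer voxels (content moves by +s)
roll_stack <- function(stack, s) {
  d <- dim(stack$data)
  idx <- lapply(1:3, function(k) ((seq_len(d[k]) - 1 - s[k]) %% d[k]) + 1)
  image_stack(stack$data[idx[[1]], idx[[2]], idx[[3]]],
              stack$pixel_size_xy, stack$z_step, stack$origin)
}

# area-weighted relative RMS error between a recovered traction field and a
# ground-truth field defined on a subset of its nodes
traction_rms_error <- function(recovered, truth) {
  full <- matrix(0, length(recovered$node), 3)
  full[match(truth$node, recovered$node), ] <- truth$traction
  err <- recovered$traction - full
  a <- recovered$area
  sqrt(sum(a * rowSums(err^2)) / sum(a)) /
    sqrt(sum(a * rowSums(full^2)) / sum(a))
}
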