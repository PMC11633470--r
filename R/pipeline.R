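#' Read and validate a pipeline run configuration
#'
#' YAML configuration with blocks: `paths` (reference, deformed, output_dir),
#' `imaging` (`pixel_size_xy`, `z_step`), `geometry` (`radius`, `depth`,
#' `gel_height`, `fillet_top`, `fillet_bottom`, optional `lateral_extent`),
#' `optics` (`na`, `n_immersion`, `n_sample`, `z_step`), `piv` (`box`,
#' `overlap`), `material` (`youngs_modulus`, `poisson_ratio`), `inverse`
#' (`lambda`), `mesh` (`target_edge_length`), and `seed`. Units are µm and Pa
#' throughout. All blocks are validated against their type constructors
#' before any computation.
#'
#' @param path YAML file path, or a list already parsed.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  req <- function(block, keys) {
    if (is.null(cfg[[block]]))
      stop(sprintf("config error: missing block '%s'", block))
    miss <- setdiff(keys, names(cfg[[block]]))
    if (length(miss))
      stop(sprintf("config error: block '%s' missing key(s) %s", block,
                   paste(miss, collapse = ", ")))
  }
  req("paths", c("reference", "deformed", "output_dir"))
  req("imaging", c("pixel_size_xy", "z_step"))
  req("geometry", c("radius", "depth", "gel_height"))
  req("material", c("youngs_modulus", "poisson_ratio"))
  for (p in c("reference", "deformed")) {
    f <- cfg$paths[[p]]
    if (!file.exists(f))
      stop(sprintf("config error: %s stack not found: %s", p, f))
  }
  g <- cfg$geometry
  geometry <- well_geometry(
    radius = g$radius, depth = g$depth, gel_height = g$gel_height,
    lateral_extent = g$lateral_extent %||% max(6 * g$radius, 4 * g$radius + 10),
    fillet_bottom = g$fillet_bottom %||% 0.5,
    fillet_top = g$fillet_top %||% 1)
  material <- material_model(cfg$material$youngs_modulus,
                             cfg$material$poisson_ratio,
                             cfg$material$law %||% "linear")
  optics <- if (!is.null(cfg$optics))
    optical_params(cfg$optics$na, cfg$optics$n_immersion, cfg$optics$n_sample,
                   cfg$optics$z_step %||% cfg$imaging$z_step) else NULL
  pivb <- cfg$piv %||% list()
  piv <- piv_config(box_size = pivb$box %||% c(32, 32, 8),
                    overlap_fraction = pivb$overlap %||% 0.5)
  invb <- cfg$inverse %||% list()
  inv <- inverse_config(regularization_lambda = invb$lambda %||% 1e-4)
  structure(list(paths = cfg$paths, imaging = cfg$imaging,
                 geometry = geometry, material = material, optics = optics,
                 piv = piv, inverse = inv,
                 mesh = list(target_edge_length =
                               (cfg$mesh$target_edge_length %||%
                                  (geometry$radius / 5))),
                 calibration = cfg$paths$lensing_calibration,
                 seed = cfg$seed %||% 1L),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full traction-recovery pipeline
#'
#' Executes the fixed stage order: load stacks, Visser axial rescale, surface
#' localization, volumetric PIV, outlier filtering, optional lensing
#' subtraction, meshing, interpolation of measured displacements onto the gel
#' surface, inverse traction solve, cylindrical decomposition/unfolding, and
#' metric reporting. Every written artifact is recorded with an MD5 content
#' hash in a JSON manifest, so re-running a deterministic configuration
#' reproduces identical hashes.
#'
#' @param config A `run_config` (see [read_run_config()]) or a YAML path.
#' @param verbose Print per-stage progress.
#' @return The run manifest (list), invisibly; written to
#'   `output_dir/manifest.json`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  out_dir <- config$paths$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config_seed = config$seed, stages = list())
  t_all <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))
  artifacts <- character(0)
  stage <- local({
    function(name, fun) {
      t0 <- Sys.time()
      res <- tryCatch(fun(), error = function(e) e)
      dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
      if (inherits(res, "error")) {
        manifest$stages[[name]] <<- list(status = "error",
                                         error = conditionMessage(res),
                                         seconds = round(dt, 3))
        manifest$artifacts <<- manifest_hashes(artifacts)
        jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                             auto_unbox = TRUE, pretty = TRUE, digits = NA)
        stop(sprintf("pipeline stage '%s' failed: %s", name,
                     conditionMessage(res)), call. = FALSE)
      }
      manifest$stages[[name]] <<- list(status = "ok", seconds = round(dt, 3))
      say("stage %-12s done in %.1fs", name, dt)
      res
    }
  })

  px <- config$imaging$pixel_size_xy
  dz <- config$imaging$z_step
  stacks <- stage("load", function() {
    list(ref = read_stack_tiff(config$paths$reference, px, dz),
         def = read_stack_tiff(config$paths$deformed, px, dz))
  })
  if (!is.null(config$optics)) {
    stacks <- stage("visser", function() {
      list(ref = apply_visser(stacks$ref, config$optics),
           def = apply_visser(stacks$def, config$optics))
    })
    manifest$stages$visser$z_step_corrected <- stacks$ref$z_step
  }
  geom <- stage("locate", function() {
    top_z <- as.numeric(locate_top_surface(stacks$ref))
    g <- config$geometry
    manual <- config$paths$well_center # optional c(cx, cy, r)
    axis <- locate_well_axis(stacks$ref,
                             z_mid = top_z - g$depth / 2,
                             expected_radius = g$radius,
                             manual = if (!is.null(manual))
                               as.numeric(manual) else NULL)
    well_geometry(radius = axis$radius, depth = g$depth,
                  gel_height = g$gel_height,
                  lateral_extent = g$lateral_extent,
                  fillet_bottom = g$fillet_bottom, fillet_top = g$fillet_top,
                  center_xy = axis$center, top_z = top_z)
  })
  disp <- stage("piv", function() {
    f <- piv3d(stacks$ref, stacks$def, config$piv)
    filter_outliers(f)
  })
  if (!is.null(config$calibration)) {
    disp <- stage("lensing", function() {
      lensing_correction(disp, read_displacement_csv(config$calibration))
    })
  }
  piv_path <- file.path(out_dir, "displacements.csv")
  write_displacement_csv(disp, piv_path)
  artifacts <- c(artifacts, piv_path)

  mesh <- stage("mesh", function()
    build_mesh(geom, config$mesh$target_edge_length))
  meas <- stage("interpolate", function()
    interpolate_measured_to_surface(disp, mesh))
  n_extr <- sum(meas$extrapolated)
  if (n_extr > 0)
    say("note: %d surface node(s) outside the PIV hull (nearest-sample)",
        n_extr)
  inv <- stage("solve", function()
    solve_inverse(mesh, config$material, meas, config$inverse))
  vtu_path <- file.path(out_dir, "tractions.vtu")
  u_full <- matrix(0, nrow(mesh$nodes), 3)
  tr_full <- matrix(0, nrow(mesh$nodes), 3)
  tr_full[inv$tractions$node, ] <- inv$tractions$traction
  u_full[meas$node, ] <- meas$u
  export_vtk(mesh, list(traction_Pa = tr_full, displacement_um = u_full),
             vtu_path)
  artifacts <- c(artifacts, vtu_path)

  unfolded <- stage("unfold", function() {
    wall_nodes <- surface_nodes(mesh, "well_wall")
    bot_nodes <- surface_nodes(mesh, "well_bottom")
    tf <- inv$tractions
    wall_tf <- traction_field(intersect(tf$node, wall_nodes),
                              tf$traction[tf$node %in% wall_nodes, ,
                                          drop = FALSE],
                              tf$area[tf$node %in% wall_nodes])
    bot_tf <- traction_field(intersect(tf$node, bot_nodes),
                             tf$traction[tf$node %in% bot_nodes, ,
                                         drop = FALSE],
                             tf$area[tf$node %in% bot_nodes])
    wall <- decompose_wall(wall_tf, mesh, geom)
    bottom <- decompose_bottom(bot_tf, mesh, geom)
    list(wall = wall, bottom = bottom,
         wall_map = unfold_wall_map(wall),
         profile = circumferential_profile(wall, component = "T_n"))
  })
  prof_path <- file.path(out_dir, "profile_Tn_wall.csv")
  write_profile_csv(unfolded$profile, prof_path)
  artifacts <- c(artifacts, prof_path)

  metrics <- stage("report", function() well_metrics(unfolded$wall, geom))
  metrics_path <- file.path(out_dir, "metrics.json")
  jsonlite::write_json(unclass(metrics), metrics_path, auto_unbox = TRUE,
                       digits = NA)
  artifacts <- c(artifacts, metrics_path)

  manifest$geometry <- list(radius = geom$radius, depth = geom$depth,
                            center_xy = geom$center_xy, top_z = geom$top_z)
  manifest$misfit <- inv$misfit
  manifest$artifacts <- manifest_hashes(artifacts)
  manifest$total_seconds <- round(as.numeric(
    difftime(Sys.time(), t_all, units = "secs")), 3)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, mesh = mesh, inverse = inv,
                 unfolded = unfolded, metrics = metrics,
                 displacements = disp, geometry = geom))
}

manifest_hashes <- function(paths) {
  if (!length(paths)) return(list())
  h <- tools::md5sum(paths)
  stats::setNames(as.list(unname(h)), basename(paths))
}

#' Generate a complete synthetic well experiment
#'
#' Forward-synthesizes everything the pipeline consumes: a ground-truth ring
#' traction on the well wall, its forward FEM displacement field, a seeded
#' bead field (surface-biased, as in the physical gels), and the paired
#' reference/deformed bead stacks. Optionally writes the TIFF pair plus a
#' JSON sidecar with the ground truth.
#'
#' @param geometry A [well_geometry()].
#' @param material A [material_model()].
#' @param ring_magnitude Signed normal traction of the wall ring (Pa);
#'   negative = inward (contractile).
#' @param ring_width Band full width at half maximum (µm).
#' @param ring_taper Raised-cosine edge ramp length (µm); default 2, giving a
#'   band-limited ring the imaging pipeline can resolve.
#' @param ring_z_center Band center; default mid-depth.
#' @param mesh_edge Mesh target edge length (µm).
#' @param stack_margin_xy Lateral margin of the rendered stack around the
#'   well mouth (µm).
#' @param z_range Heights spanned by the stack, `c(below_bottom, above_top)`
#'   offsets (µm).
#' @param pixel_size_xy,z_step Stack calibration (µm).
#' @param bulk_density,surface_density,noise_sd,seed Passed to
#'   [sample_beads()] / [render_stack()].
#' @param out_dir Optional directory: writes `reference.tif`, `deformed.tif`,
#'   `ground_truth.json`.
#' @return List: `reference`, `deformed` ([image_stack()]s), `beads`,
#'   `mesh`, `tractions` (ground truth), `forward` (FEM solution), `paths`
#'   (when written).
#' @export
simulate_well_experiment <- function(geometry,
                                     material = material_model(),
                                     ring_magnitude = -500, ring_width = 4,
                                     ring_taper = 2,
                                     ring_z_center = NULL, mesh_edge = NULL,
                                     stack_margin_xy = 4, z_range = c(3, 1.6),
                                     pixel_size_xy = 0.104, z_step = 0.2,
                                     bulk_density = 0.05, surface_density = 2,
                                     noise_sd = 0.02, seed = 1L,
                                     out_dir = NULL) {
  g <- geometry
  if (is.null(mesh_edge)) mesh_edge <- g$radius / 5
  mesh <- build_mesh(g, mesh_edge)
  truth <- ring_traction(mesh, ring_magnitude, z_center = ring_z_center,
                         width = ring_width, taper = ring_taper)
  fw <- solve_forward(mesh, material, truth)
  interp <- displacement_interpolator(mesh, fw$u)
  beads <- sample_beads(g, bulk_density = bulk_density,
                        surface_density = surface_density,
                        seed = seed, bulk_depth = z_range[1])
  # restrict to the imaged box
  half <- g$radius + g$fillet_top + stack_margin_xy
  keep <- abs(beads$positions[, 1] - g$center_xy[1]) < half &
    abs(beads$positions[, 2] - g$center_xy[2]) < half
  beads$positions <- beads$positions[keep, , drop = FALSE]
  warped <- warp_beads(beads, interp)
  origin <- c(g$center_xy[1] - half, g$center_xy[2] - half,
              g$top_z - g$depth - z_range[1])
  nxy <- as.integer(ceiling(2 * half / pixel_size_xy))
  nz <- as.integer(ceiling((g$depth + z_range[1] + z_range[2]) / z_step)) + 1L
  ref <- render_stack(beads, c(nxy, nxy, nz), pixel_size_xy, z_step,
                      noise_sd = noise_sd, seed = seed, origin = origin)
  def <- render_stack(warped, c(nxy, nxy, nz), pixel_size_xy, z_step,
                      noise_sd = noise_sd, seed = seed + 1L, origin = origin)
  out <- list(reference = ref, deformed = def, beads = beads, mesh = mesh,
              tractions = truth, forward = fw, geometry = g)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    pr <- file.path(out_dir, "reference.tif")
    pd <- file.path(out_dir, "deformed.tif")
    write_stack_tiff(ref, pr)
    write_stack_tiff(def, pd)
    gt <- file.path(out_dir, "ground_truth.json")
    jsonlite::write_json(list(
      seed = seed, ring_magnitude = ring_magnitude, ring_width = ring_width,
      geometry = list(radius = g$radius, depth = g$depth,
                      center_xy = g$center_xy, top_z = g$top_z),
      n_beads = nrow(beads$positions),
      bead_positions = beads$positions), gt, digits = NA)
    out$paths <- list(reference = pr, deformed = pd, ground_truth = gt)
  }
  out
}
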