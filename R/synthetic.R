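#' Sample a synthetic fiducial bead field
#'
#' Draws 200 nm bead positions inside the gel around a microwell, reproducing
#' the seeding regime of the physical gels: a dilute bulk population plus a
#' concentrated layer near the free surfaces (gel top, well wall and well
#' bottom), where beads accumulate during polymerization. Counts in each region
#' are Poisson with mean `density * measure(region)`.
#'
#' @param geometry A [well_geometry()].
#' @param bulk_density Bulk bead density (beads/µm³).
#' @param surface_density Areal density of the surface-bound layer (beads/µm²).
#' @param surface_layer_thickness Support of the surface layer (µm); default
#'   0.6. Within the layer the bead concentration peaks at the free surface
#'   and decays exponentially inward (scale = thickness/3), emulating
#'   accumulation against the mold interface during polymerization.
#' @param seed Integer RNG seed; fixed seed gives identical fields.
#' @param bulk_depth How far below the well bottom the sampled bulk region
#'   extends (µm). The gel is much thicker than the imaged volume; only this
#'   slab is seeded.
#' @param bead_diameter Nominal bead diameter (µm); default 0.2.
#' @param intensity_scale Peak intensity of one rendered bead (a.u.).
#' @return An object of class `bead_field`: `positions` (n x 3 matrix, µm),
#'   `bead_diameter`, `intensity_scale`, `seed`.
#' @export
sample_beads <- function(geometry, bulk_density = 0.05, surface_density = 1,
                         surface_layer_thickness = 0.6, seed = 1L,
                         bulk_depth = 5, bead_diameter = 0.2,
                         intensity_scale = 1) {
  stopifnot(inherits(geometry, "well_geometry"))
  if (bulk_density < 0 || surface_density < 0) stop("densities must be >= 0")
  if (surface_layer_thickness <= 0) stop("surface_layer_thickness must be > 0")
  g <- geometry
  top <- g$top_z
  bottom <- top - g$depth
  zlo <- bottom - bulk_depth
  L <- g$lateral_extent
  cx <- g$center_xy[1]
  cy <- g$center_xy[2]
  R <- g$radius
  th <- surface_layer_thickness

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  inside_gel <- function(p) {
    r <- sqrt((p[, 1] - cx)^2 + (p[, 2] - cy)^2)
    rc <- cavity_radius(g, p[, 3])
    is.na(rc) | r >= rc
  }
  # depth into the gel from a free surface: truncated exponential, peaked at
  # the surface (beads accumulate against the mold interface)
  layer_depth <- function(n) {
    scale <- th / 3
    -scale * log(1 - stats::runif(n) * (1 - exp(-th / scale)))
  }

  pts <- list()
  # bulk: rejection sampling in the slab, discarding the cavity
  vol_box <- L * L * (top - zlo)
  n_bulk <- stats::rpois(1, bulk_density * vol_box)
  if (n_bulk > 0) {
    p <- cbind(cx - L / 2 + stats::runif(n_bulk) * L,
               cy - L / 2 + stats::runif(n_bulk) * L,
               zlo + stats::runif(n_bulk) * (top - zlo))
    pts$bulk <- p[inside_gel(p), , drop = FALSE]
  }
  # gel top surface layer (annulus from well mouth to the block edge)
  area_top <- L * L - pi * (R + g$fillet_top)^2
  n_top <- stats::rpois(1, surface_density * max(area_top, 0))
  if (n_top > 0) {
    p <- cbind(cx - L / 2 + stats::runif(n_top) * L,
               cy - L / 2 + stats::runif(n_top) * L,
               top - layer_depth(n_top))
    pts$top <- p[inside_gel(p), , drop = FALSE]
  }
  # well wall layer: radius in [r_cavity, r_cavity + th]
  area_wall <- 2 * pi * R * g$depth
  n_wall <- stats::rpois(1, surface_density * area_wall)
  if (n_wall > 0) {
    ang <- stats::runif(n_wall) * 2 * pi
    z <- bottom + stats::runif(n_wall) * g$depth
    rc <- cavity_radius(g, z)
    r <- rc + layer_depth(n_wall)
    pts$wall <- cbind(cx + r * cos(ang), cy + r * sin(ang), z)
  }
  # well bottom layer: disk below the cavity floor
  rb <- R - g$fillet_bottom
  n_bot <- stats::rpois(1, surface_density * pi * rb^2)
  if (n_bot > 0) {
    r <- rb * sqrt(stats::runif(n_bot))
    ang <- stats::runif(n_bot) * 2 * pi
    pts$bottom <- cbind(cx + r * cos(ang), cy + r * sin(ang),
                        bottom - layer_depth(n_bot))
  }
  positions <- do.call(rbind, pts)
  if (is.null(positions)) positions <- matrix(numeric(0), 0, 3)
  dimnames(positions) <- NULL
  structure(list(positions = positions, bead_diameter = bead_diameter,
                 intensity_scale = intensity_scale, seed = seed),
            class = "bead_field")
}

#' Construct a bead field from explicit positions
#'
#' Low-level constructor used when bead positions come from elsewhere than
#' [sample_beads()] (e.g. uniform fields for resolution tests).
#'
#' @param positions n x 3 matrix of bead centers (µm).
#' @param bead_diameter Nominal diameter (µm).
#' @param intensity_scale Peak intensity of a rendered bead (a.u.).
#' @param seed Bookkeeping seed tag.
#' @return An object of class `bead_field`.
#' @export
bead_field <- function(positions, bead_diameter = 0.2, intensity_scale = 1,
                       seed = NA_integer_) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  structure(list(positions = positions, bead_diameter = bead_diameter,
                 intensity_scale = intensity_scale, seed = seed),
            class = "bead_field")
}

#' @export
print.bead_field <- function(x, ...) {
  cat(sprintf("bead_field: %d beads, diameter %g um (seed %s)\n",
              nrow(x$positions), x$bead_diameter, format(x$seed)))
  invisible(x)
}

#' Render a bead field into a confocal-like image stack
#'
#' Each bead becomes an anisotropic Gaussian blob (the axial sigma is larger
#' than the lateral one, emulating the elongated confocal point-spread
#' function that makes z displacements noisier than lateral ones), plus
#' additive Gaussian background noise. At the default 0.104 µm pixels a blob
#' of ~0.24 µm FWHM spans about 2.3 pixels, the optimum for PIV peak fitting.
#'
#' @param beads A [sample_beads()] result (or any `bead_field`).
#' @param dim Integer triple: stack size in voxels `(nx, ny, nz)`.
#' @param pixel_size_xy,z_step Voxel calibration (µm); defaults 0.104 and 0.2.
#' @param psf_sigma_xy Lateral Gaussian sigma (µm); default 0.102 so the blob
#'   FWHM is ~0.24 µm.
#' @param psf_sigma_z Axial sigma (µm); default three times the lateral one.
#' @param noise_sd Additive Gaussian noise sd (a.u.).
#' @param seed Integer RNG seed for the noise.
#' @param origin Physical position of voxel `[1,1,1]` (µm).
#' @return An [image_stack()].
#' @export
render_stack <- function(beads, dim, pixel_size_xy = 0.104, z_step = 0.2,
                         psf_sigma_xy = 0.102, psf_sigma_z = 3 * psf_sigma_xy,
                         noise_sd = 0, seed = 1L, origin = c(0, 0, 0)) {
  stopifnot(inherits(beads, "bead_field"), length(dim) == 3L)
  if (psf_sigma_xy <= 0 || psf_sigma_z <= 0) stop("psf sigmas must be > 0")
  dim <- as.integer(dim)
  vol <- array(0, dim)
  p <- beads$positions
  if (nrow(p) > 0) {
    hx <- ceiling(4 * psf_sigma_xy / pixel_size_xy)
    hz <- ceiling(4 * psf_sigma_z / z_step)
    # voxel-center index (1-based, fractional) of each bead
    ix <- (p[, 1] - origin[1]) / pixel_size_xy + 1
    iy <- (p[, 2] - origin[2]) / pixel_size_xy + 1
    iz <- (p[, 3] - origin[3]) / z_step + 1
    amp <- beads$intensity_scale
    lo <- cbind(floor(ix - hx), floor(iy - hx), floor(iz - hz))
    hi <- cbind(ceiling(ix + hx), ceiling(iy + hx), ceiling(iz + hz))
    inside <- lo[, 1] <= dim[1] & lo[, 2] <= dim[2] & lo[, 3] <= dim[3] &
      hi[, 1] >= 1 & hi[, 2] >= 1 & hi[, 3] >= 1
    for (b in which(inside)) {
      xr <- max(1L, lo[b, 1]):min(dim[1], hi[b, 1])
      yr <- max(1L, lo[b, 2]):min(dim[2], hi[b, 2])
      zr <- max(1L, lo[b, 3]):min(dim[3], hi[b, 3])
      gxv <- exp(-((xr - ix[b]) * pixel_size_xy)^2 / (2 * psf_sigma_xy^2))
      gyv <- exp(-((yr - iy[b]) * pixel_size_xy)^2 / (2 * psf_sigma_xy^2))
      gzv <- exp(-((zr - iz[b]) * z_step)^2 / (2 * psf_sigma_z^2))
      blob <- amp * (gxv %o% gyv %o% gzv)
      vol[xr, yr, zr] <- vol[xr, yr, zr, drop = FALSE] + blob
    }
  }
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    vol <- vol + array(stats::rnorm(prod(dim), sd = noise_sd), dim)
  }
  image_stack(vol, pixel_size_xy, z_step, origin)
}

#' Displace beads by a prescribed deformation field
#'
#' Maps every bead position `p` to `p + u(p)`, producing the "deformed gel"
#' bead configuration for forward synthesis of an experiment.
#'
#' @param beads A `bead_field`.
#' @param displacement Function taking an n x 3 position matrix (µm) and
#'   returning an n x 3 displacement matrix (µm).
#' @return A `bead_field` with displaced positions; metadata preserved.
#' @export
warp_beads <- function(beads, displacement) {
  stopifnot(inherits(beads, "bead_field"), is.function(displacement))
  p <- beads$positions
  if (nrow(p) == 0) return(beads)
  u <- displacement(p)
  u <- matrix(as.numeric(u), nrow = nrow(p))
  if (!all(dim(u) == dim(p)))
    stop("displacement function must return an n x 3 matrix")
  bad <- which(!stats::complete.cases(u) | rowSums(!is.finite(u)) > 0)
  if (length(bad))
    stop("displacement undefined at bead(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  out <- beads
  out$positions <- p + u
  out
}
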