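#' Parametric cylindrical microwell geometry
#'
#' Describes a cell-sized cylindrical cavity molded into the top surface of an
#' elastic gel slab. The gel occupies a square prism of side `lateral_extent`
#' and height `gel_height`; the cavity of radius `radius` is sunk to `depth`
#' below the gel's top plane (`top_z`). Cavity edges are rounded: `fillet_bottom`
#' at the concave wall/bottom junction, `fillet_top` at the convex rim where the
#' wall meets the gel top, matching the physical wells replica-molded from PDMS
#' pillars.
#'
#' Coordinates are right-handed with z increasing from the glass coverslip
#' toward the objective; the well axis is vertical through `center_xy`, and the
#' azimuth theta is measured counter-clockwise from +x. All lengths are in
#' micrometres.
#'
#' @param radius Well radius (µm).
#' @param depth Well depth below the gel top surface (µm).
#' @param gel_height Total gel thickness (µm).
#' @param lateral_extent Side of the square gel block modeled around one well
#'   (µm). Defaults to six radii so that the traction-free lateral boundary is
#'   remote (wells are spaced ~100 µm apart in the physical gels).
#' @param fillet_bottom,fillet_top Rounding radii of the bottom and top cavity
#'   edges (µm); defaults 0.5 and 1.
#' @param center_xy Length-2 numeric, well axis position (µm).
#' @param top_z z of the gel top surface plane (µm).
#' @return An object of class `well_geometry`.
#' @examples
#' g <- well_geometry(radius = 5.25, depth = 12)
#' well_contact_area(g)
#' @export
well_geometry <- function(radius, depth, gel_height = 100,
                          lateral_extent = max(6 * radius, 4 * radius + 10),
                          fillet_bottom = 0.5, fillet_top = 1,
                          center_xy = c(0, 0), top_z = 0) {
  stopifnot(is.numeric(radius), length(radius) == 1L)
  if (radius <= 0) stop("well radius must be positive")
  if (!(depth > 0 && depth < gel_height))
    stop("well depth must satisfy 0 < depth < gel_height")
  if (fillet_bottom < 0 || fillet_top < 0) stop("fillet radii must be >= 0")
  if (fillet_bottom + fillet_top >= depth)
    stop("fillet_bottom + fillet_top must be smaller than depth")
  if (fillet_bottom >= radius) stop("fillet_bottom must be smaller than radius")
  if (lateral_extent <= 2 * (radius + fillet_top))
    stop("lateral_extent too small to contain the well mouth")
  structure(list(radius = radius, depth = depth, gel_height = gel_height,
                 lateral_extent = lateral_extent,
                 fillet_bottom = fillet_bottom, fillet_top = fillet_top,
                 center_xy = as.numeric(center_xy), top_z = top_z),
            class = "well_geometry")
}

#' @export
print.well_geometry <- function(x, ...) {
  cat(sprintf(
    "Cylindrical microwell: R = %g um, depth = %g um (fillets %g/%g um)\n",
    x$radius, x$depth, x$fillet_bottom, x$fillet_top))
  cat(sprintf("Gel: %g um thick, %g x %g um block; top surface at z = %g um\n",
              x$gel_height, x$lateral_extent, x$lateral_extent, x$top_z))
  invisible(x)
}

#' Cavity radius profile of a filleted well
#'
#' Radius of the gel--cavity interface at height `z`, tracing the straight wall
#' and the two fillet arcs. Below the cavity bottom the cavity does not exist
#' and `NA` is returned.
#'
#' @param geometry A [well_geometry()].
#' @param z Heights (µm).
#' @return Numeric vector of cavity radii (µm), `NA` outside `[top_z - depth, top_z]`.
#' @keywords internal
cavity_radius <- function(geometry, z) {
  top <- geometry$top_z
  bottom <- top - geometry$depth
  fb <- geometry$fillet_bottom
  ft <- geometry$fillet_top
  R <- geometry$radius
  r <- rep(NA_real_, length(z))
  inside <- z >= bottom - 1e-9 & z <= top + 1e-9
  zc <- pmin(pmax(z[inside], bottom), top)
  ri <- rep(R, length(zc))
  if (fb > 0) {
    sel <- zc < bottom + fb
    ri[sel] <- (R - fb) + sqrt(pmax(fb^2 - (zc[sel] - (bottom + fb))^2, 0))
  }
  if (ft > 0) {
    sel <- zc > top - ft
    ri[sel] <- (R + ft) - sqrt(pmax(ft^2 - (zc[sel] - (top - ft))^2, 0))
  }
  r[inside] <- ri
  r
}

#' 3D fluorescence image stack with voxel calibration
#'
#' A scalar intensity volume with isotropic lateral sampling and a (possibly
#' different) axial step. The array is indexed `[x, y, z]`; voxel `[i, j, k]`
#' has its center at `origin + ((i,j,k) - 1) * (pixel_size_xy, pixel_size_xy,
#' z_step)`.
#'
#' @param data Numeric 3D array `[x, y, z]` of intensities (arbitrary units).
#' @param pixel_size_xy Lateral voxel size (µm), e.g. 0.104 for Airyscan data.
#' @param z_step Axial plane spacing (µm), nominally 0.2.
#' @param origin Physical position (µm) of the center of voxel `[1, 1, 1]`.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, pixel_size_xy, z_step, origin = c(0, 0, 0)) {
  if (!(is.array(data) && length(dim(data)) == 3L))
    stop("`data` must be a 3D array [x, y, z]")
  if (any(dim(data) < 1L)) stop("all stack dimensions must be >= 1")
  if (pixel_size_xy <= 0) stop("pixel_size_xy must be positive")
  if (z_step <= 0) stop("z_step must be positive")
  structure(list(data = data, pixel_size_xy = pixel_size_xy, z_step = z_step,
                 origin = as.numeric(origin)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "image_stack: %d x %d x %d voxels, %g um/px lateral, %g um z-step\n",
    d[1], d[2], d[3], x$pixel_size_xy, x$z_step))
  invisible(x)
}

#' Physical z-coordinates of the planes of a stack
#' @param stack An [image_stack()].
#' @return Numeric vector, one z (µm) per plane.
#' @export
stack_plane_z <- function(stack) {
  stack$origin[3] + (seq_len(dim(stack$data)[3]) - 1) * stack$z_step
}

#' Locate the gel top surface from a bead stack
#'
#' Beads accumulate near the free surfaces of the gel during polymerization, so
#' the mean intensity of each plane peaks at the gel's top surface. Returns the
#' z of the plane with maximal plane-mean intensity.
#'
#' @param stack An [image_stack()] with at least 3 planes.
#' @param tol Relative peak-prominence tolerance: if the range of plane means is
#'   below `tol` times the maximal mean, the profile is considered flat.
#' @param refine Sub-plane refinement of the peak by a three-point parabolic
#'   fit (default `TRUE`); the refined position stays within one z-step of the
#'   peak plane.
#' @return The z-coordinate (µm) of the surface plane, with the plane-mean
#'   profile attached as attribute `"profile"`.
#' @export
locate_top_surface <- function(stack, tol = 1e-6, refine = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  nz <- dim(stack$data)[3]
  if (nz < 3L) stop("stack must have at least 3 planes")
  means <- apply(stack$data, 3, mean)
  rng <- diff(range(means))
  if (!is.finite(rng) || rng <= tol * max(abs(means), .Machine$double.eps))
    stop("ambiguous surface: plane-mean intensity profile has no peak")
  k <- which.max(means)
  z <- stack_plane_z(stack)[k]
  if (refine && k > 1L && k < nz) {
    off <- three_point_offset(means[k - 1], means[k], means[k + 1], "parabolic")
    if (abs(off) < 1) z <- z + off * stack$z_step
  }
  attr(z, "profile") <- means
  z
}

#' Locate the well axis and radius in a central plane
#'
#' Detects the well in the plane nearest `z_mid`, where the cavity appears as
#' a dark disk rimmed by the bright bead layer on the wall. The center is
#' found by maximizing a ring-contrast score (mean intensity in the annulus
#' just outside the expected radius minus mean intensity of the interior
#' disk) over a coarse-to-fine grid of candidate centers; the radius is then
#' refined to the half-rise point of the azimuthal-mean radial intensity
#' profile, which is unbiased for a blurred edge. A user-supplied circle
#' bypasses detection entirely.
#'
#' @param stack An [image_stack()].
#' @param z_mid Height (µm) of a plane strictly inside the well.
#' @param expected_radius Expected well radius (µm).
#' @param radius_band Acceptance band: the detected radius must lie within
#'   `expected_radius * (1 +/- radius_band)`.
#' @param manual Optional numeric `c(cx, cy, r)` (µm) returned unchanged.
#' @param smooth_sigma Gaussian smoothing sigma (µm) applied before the
#'   center search.
#' @return List with `center` (µm pair) and `radius` (µm); `manual` flag.
#' @export
locate_well_axis <- function(stack, z_mid, expected_radius,
                             radius_band = 0.3, manual = NULL,
                             smooth_sigma = 0.5) {
  if (!is.null(manual)) {
    stopifnot(length(manual) == 3L)
    return(list(center = as.numeric(manual[1:2]), radius = as.numeric(manual[3]),
                manual = TRUE))
  }
  stopifnot(inherits(stack, "image_stack"))
  zs <- stack_plane_z(stack)
  if (z_mid < min(zs) || z_mid > max(zs))
    stop("z_mid must lie within the stack")
  k <- which.min(abs(zs - z_mid))
  plane <- stack$data[, , k]
  px <- stack$pixel_size_xy
  rng <- diff(range(plane))
  if (rng <= .Machine$double.eps)
    stop("well detection failed: featureless plane")
  sm <- gaussian_blur_2d(plane, smooth_sigma / px)
  n <- dim(plane)
  xs <- stack$origin[1] + (seq_len(n[1]) - 1) * px
  ys <- stack$origin[2] + (seq_len(n[2]) - 1) * px
  R <- expected_radius
  score <- function(cx, cy) {
    d2 <- outer((xs - cx)^2, (ys - cy)^2, "+")
    ann <- d2 >= R^2 & d2 <= (R + 1.2)^2
    disk <- d2 <= (0.8 * R)^2
    if (sum(ann) < 8 || sum(disk) < 8) return(-Inf)
    mean(sm[ann]) - mean(sm[disk])
  }
  # coarse-to-fine center search
  step <- R / 3
  cand <- expand.grid(cx = seq(min(xs) + R / 2, max(xs) - R / 2, by = step),
                      cy = seq(min(ys) + R / 2, max(ys) - R / 2, by = step))
  if (nrow(cand) == 0)
    stop("well detection failed: image smaller than the expected well")
  sc <- mapply(score, cand$cx, cand$cy)
  best <- c(cand$cx[which.max(sc)], cand$cy[which.max(sc)])
  for (step in c(R / 10, R / 40, px / 2)) {
    dd <- as.matrix(expand.grid(dx = -2:2, dy = -2:2)) * step
    cnd <- sweep(dd, 2, best, "+")
    sc <- mapply(score, cnd[, 1], cnd[, 2])
    best <- cnd[which.max(sc), ]
  }
  if (!is.finite(max(sc)) || max(sc) <= 0)
    stop("well detection failed: no dark cavity with a bright rim found")
  # radius from the half-rise of the raw radial profile around the center
  r_half <- radial_half_rise(plane, stack,
                             list(cx = best[1], cy = best[2], r = R))
  if (!is.finite(r_half) ||
      abs(r_half - expected_radius) > radius_band * expected_radius)
    stop(sprintf(
      "well detection failed: radius %.2f um outside the band around %.2f um",
      if (is.finite(r_half)) r_half else NA_real_, expected_radius))
  list(center = unname(best), radius = unname(r_half), manual = FALSE)
}

radial_half_rise <- function(plane, stack, fit) {
  px <- stack$pixel_size_xy
  n <- dim(plane)
  xs <- stack$origin[1] + (seq_len(n[1]) - 1) * px
  ys <- stack$origin[2] + (seq_len(n[2]) - 1) * px
  rr <- sqrt(outer((xs - fit$cx)^2, (ys - fit$cy)^2, "+"))
  bw <- px
  bin <- pmin(floor(rr / bw) + 1L, 10000L)
  prof <- tapply(as.numeric(plane), bin, mean)
  rmid <- (as.integer(names(prof)) - 0.5) * bw
  inside <- rmid < 0.6 * fit$r
  ring <- rmid >= 0.6 * fit$r & rmid <= 1.5 * fit$r
  if (sum(inside) < 2 || sum(ring) < 2) return(NA_real_)
  lo <- mean(prof[inside])
  hi <- max(prof[ring])
  half <- (lo + hi) / 2
  cand <- which(ring & prof >= half)
  if (!length(cand)) return(NA_real_)
  k <- cand[1]
  if (k == 1) return(rmid[1])
  # linear interpolation between the bracketing bins
  r0 <- rmid[k - 1]; r1 <- rmid[k]
  v0 <- prof[k - 1]; v1 <- prof[k]
  if (v1 == v0) return(r1)
  unname(r0 + (half - v0) / (v1 - v0) * (r1 - r0))
}

# Separable Gaussian blur with reflective borders; sigma in pixels.
gaussian_blur_2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    vp <- c(v[pmin(half:1, n)], v, v[pmax(n - (1:half) + 1, 1)])
    stats::convolve(vp, rev(k), type = "filter")
  }
  m1 <- apply(m, 2, conv1)
  t(apply(m1, 1, conv1))
}

#' Locate the well bottom surface
#'
#' The intensity signal carries no reliable bottom signature, so the bottom is
#' placed at a fixed offset equal to the model depth below the located top
#' surface.
#'
#' @param top_z z of the gel top surface (µm).
#' @param geometry A [well_geometry()]; its `depth` is used.
#' @return z of the well bottom plane (µm), `top_z - depth`.
#' @examples
#' locate_bottom_surface(0, well_geometry(5.5, 11.5))
#' @export
locate_bottom_surface <- function(top_z, geometry) {
  stopifnot(inherits(geometry, "well_geometry"))
  if (geometry$depth <= 0) stop("geometry depth must be positive")
  top_z - geometry$depth
}
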