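#' Decompose wall tractions into cylindrical components
#'
#' At a wall node at azimuth theta the traction vector is resolved in the
#' local orthonormal frame of the cylinder: `T_n = T . (cos t, sin t, 0)`
#' (positive outward, i.e. extensile), `T_v = T . (0, 0, 1)` (positive upward)
#' and `T_c = T . (-sin t, cos t, 0)` (positive counter-clockwise). A negative
#' circumference-average `T_n` therefore means the cell pulls the wall inward
#' (contractile).
#'
#' @param tractions A [traction_field()] whose nodes lie on the well wall.
#' @param mesh A `well_mesh` (for node coordinates).
#' @param geometry A [well_geometry()]; defaults to the mesh's.
#' @param tol Radial tolerance (µm) around the wall profile (fillets included);
#'   nodes further off-cylinder are dropped with a warning.
#' @return A `traction_components` object (`surface = "wall"`): data.frame
#'   with node, theta (rad), z, r, T_n, T_v, T_c.
#' @export
decompose_wall <- function(tractions, mesh, geometry = mesh$geometry,
                           tol = NULL) {
  stopifnot(inherits(tractions, "traction_field"))
  if (is.null(tol))
    tol <- max(geometry$fillet_bottom, geometry$fillet_top, 0.1) + 0.2
  p <- mesh$nodes[tractions$node, , drop = FALSE]
  dx <- p[, 1] - geometry$center_xy[1]
  dy <- p[, 2] - geometry$center_xy[2]
  r <- sqrt(dx^2 + dy^2)
  ok <- abs(r - geometry$radius) <= tol +
    pmax(geometry$fillet_bottom, geometry$fillet_top)
  ok <- ok & r > 1e-9
  if (any(!ok))
    warning(sprintf("%d node(s) off the wall cylinder excluded", sum(!ok)))
  th <- atan2(dy[ok], dx[ok]) %% (2 * pi)
  Tm <- tractions$traction[ok, , drop = FALSE]
  ct <- cos(th); st <- sin(th)
  out <- data.frame(node = tractions$node[ok], theta = th, z = p[ok, 3],
                    r = r[ok], area = tractions$area[ok],
                    T_n = Tm[, 1] * ct + Tm[, 2] * st,
                    T_v = Tm[, 3],
                    T_c = -Tm[, 1] * st + Tm[, 2] * ct)
  structure(list(surface = "wall", data = out, geometry = geometry),
            class = "traction_components")
}

#' Decompose bottom tractions into cylindrical components
#'
#' On the well floor the frame is `T_n = T . (0, 0, 1)` (normal to the
#' bottom), `T_r` positive pointing radially outward (contractile pulling of
#' the bottom edge toward the center shows as negative `T_r`), `T_c` as on
#' the wall. At the axis (r = 0) the in-plane directions are undefined; such
#' nodes get `T_r = T_c = 0` and an `axis_degenerate` flag.
#'
#' @inheritParams decompose_wall
#' @return A `traction_components` object (`surface = "bottom"`): node, r,
#'   theta, T_n, T_r, T_c, axis_degenerate.
#' @export
decompose_bottom <- function(tractions, mesh, geometry = mesh$geometry,
                             tol = 0.5) {
  stopifnot(inherits(tractions, "traction_field"))
  p <- mesh$nodes[tractions$node, , drop = FALSE]
  bottom_z <- geometry$top_z - geometry$depth
  ok <- abs(p[, 3] - bottom_z) <= tol
  if (any(!ok))
    warning(sprintf("%d node(s) off the bottom plane excluded", sum(!ok)))
  dx <- p[ok, 1] - geometry$center_xy[1]
  dy <- p[ok, 2] - geometry$center_xy[2]
  r <- sqrt(dx^2 + dy^2)
  degen <- r < 1e-9
  th <- ifelse(degen, 0, atan2(dy, dx) %% (2 * pi))
  ct <- cos(th); st <- sin(th)
  Tm <- tractions$traction[ok, , drop = FALSE]
  Tr <- ifelse(degen, 0, Tm[, 1] * ct + Tm[, 2] * st)
  Tc <- ifelse(degen, 0, -Tm[, 1] * st + Tm[, 2] * ct)
  out <- data.frame(node = tractions$node[ok], r = r, theta = th,
                    z = p[ok, 3], area = tractions$area[ok],
                    T_n = Tm[, 3], T_r = Tr, T_c = Tc,
                    axis_degenerate = degen)
  structure(list(surface = "bottom", data = out, geometry = geometry),
            class = "traction_components")
}

#' @export
print.traction_components <- function(x, ...) {
  cat(sprintf("traction_components (%s): %d nodes, components %s\n",
              x$surface, nrow(x$data),
              paste(intersect(c("T_n", "T_v", "T_r", "T_c"), names(x$data)),
                    collapse = ", ")))
  invisible(x)
}

#' Unfold wall tractions into a theta-z rectangle
#'
#' Interpolates the scattered wall-node values of one cylindrical component
#' onto a regular (theta, z) grid, honoring the 0/360 degree seam by
#' replicating the data across it. The top band of the wall (default 1 µm),
#' where the fillet makes discretization errors largest, is excluded from the
#' map. Interpolation is piecewise-linear on a triangulation of the scattered
#' nodes, so nodal values are reproduced exactly.
#'
#' @param components A wall `traction_components`.
#' @param component One of `"T_n"`, `"T_v"`, `"T_c"`.
#' @param n_theta,n_z Grid resolution (theta cells, z rows).
#' @param excluded_band Height (µm) removed below the wall top; default 1.
#' @return An `unfolded_map`: `theta` (degrees, 0..360 inclusive), `z` (µm),
#'   `values` (length(z) x length(theta) matrix, Pa).
#' @export
unfold_wall_map <- function(components, component = "T_n", n_theta = 72,
                            n_z = 40, excluded_band = 1) {
  stopifnot(inherits(components, "traction_components"),
            components$surface == "wall")
  d <- components$data
  if (nrow(d) == 0) stop("empty component set")
  if (!component %in% names(d)) stop("unknown component: ", component)
  g <- components$geometry
  z_lo <- g$top_z - g$depth
  z_hi <- g$top_z - excluded_band
  keep <- d$z <= z_hi + 1e-9
  d <- d[keep, , drop = FALSE]
  if (nrow(d) < 3) stop("empty component set after excluding the top band")
  th_deg <- d$theta * 180 / pi
  # replicate across the seam so the interpolant is periodic
  p <- cbind(c(th_deg - 360, th_deg, th_deg + 360), rep(d$z, 3))
  v <- rep(d[[component]], 3)
  # triangulate in seam-replicated arc-length coordinates for quality
  arc <- g$radius * pi / 180
  gz <- seq(z_lo, z_hi, length.out = n_z)
  gt <- seq(0, 360, length.out = n_theta + 1)
  q <- cbind(rep(gt, each = n_z) * arc, rep(gz, n_theta + 1))
  vals <- interp_scattered(cbind(p[, 1] * arc, p[, 2]), v, q)
  structure(list(surface = "wall", component = component, theta = gt, z = gz,
                 values = matrix(vals, n_z, n_theta + 1),
                 excluded_band = excluded_band, geometry = g),
            class = "unfolded_map")
}

#' Rasterize bottom tractions as a disk
#'
#' Interpolates one component of the bottom tractions onto a Cartesian grid
#' masked to the well floor disk.
#'
#' @param components A bottom `traction_components`.
#' @param component One of `"T_n"`, `"T_r"`, `"T_c"`.
#' @param n Grid cells per axis.
#' @return An `unfolded_map` with `x`, `y` (µm), `values` (n x n, NA outside
#'   the disk).
#' @export
unfold_bottom_map <- function(components, component = "T_n", n = 64) {
  stopifnot(inherits(components, "traction_components"),
            components$surface == "bottom")
  d <- components$data
  if (nrow(d) == 0) stop("empty component set")
  if (!component %in% names(d)) stop("unknown component: ", component)
  g <- components$geometry
  Rb <- g$radius - g$fillet_bottom
  gx <- seq(-Rb, Rb, length.out = n)
  q <- cbind(rep(gx, each = n), rep(gx, n)) # (y fast, x slow) -> matrix [y, x]
  mask <- sqrt(q[, 1]^2 + q[, 2]^2) <= Rb + 1e-9
  px <- g$center_xy[1] + d$r * cos(d$theta)
  py <- g$center_xy[2] + d$r * sin(d$theta)
  vals <- rep(NA_real_, nrow(q))
  vals[mask] <- interp_scattered(
    cbind(px - g$center_xy[1], py - g$center_xy[2]), d[[component]],
    q[mask, , drop = FALSE])
  structure(list(surface = "bottom", component = component, x = gx, y = gx,
                 values = matrix(vals, n, n), geometry = g),
            class = "unfolded_map")
}

#' @export
print.unfolded_map <- function(x, ...) {
  cat(sprintf("unfolded_map (%s, %s): %s grid, range [%.1f, %.1f] Pa\n",
              x$surface, x$component,
              paste(dim(x$values), collapse = " x "),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Circumference-averaged traction profiles
#'
#' Averages a traction component along the well circumference: per z row for
#' the wall (profile against distance from the well top), per annular radial
#' bin for the bottom (profile against radial distance from the center).
#' Means and standard deviations are across theta within the well.
#'
#' @param x An `unfolded_map` or a `traction_components` object.
#' @param ... Passed on; for bottom components, `bin_width` (µm) sets the
#'   annulus width (default: one mesh edge, approximated by Rb/8).
#' @return A `traction_profiles` object: `abscissa` (µm), `mean`, `std` (Pa),
#'   `n` (samples per row).
#' @export
circumferential_profile <- function(x, ...) UseMethod("circumferential_profile")

#' @rdname circumferential_profile
#' @export
circumferential_profile.unfolded_map <- function(x, ...) {
  if (x$surface == "wall") {
    vals <- x$values[, -ncol(x$values), drop = FALSE] # drop duplicated seam
    prof <- data.frame(abscissa = x$z,
                       mean = rowMeans(vals),
                       std = apply(vals, 1, stats::sd),
                       n = ncol(vals))
  } else {
    r <- sqrt(outer(x$y^2, rep(1, length(x$x))) +
              outer(rep(1, length(x$y)), x$x^2))
    Rb <- max(x$x)
    bw <- Rb / 12
    bins <- seq(0, Rb + bw, by = bw)
    idx <- findInterval(r, bins)
    ok <- !is.na(x$values)
    agg <- tapply(x$values[ok], idx[ok], function(v) c(mean(v), stats::sd(v),
                                                       length(v)))
    ab <- (bins[as.integer(names(agg))] + bw / 2)
    m <- do.call(rbind, agg)
    prof <- data.frame(abscissa = ab, mean = m[, 1],
                       std = ifelse(is.na(m[, 2]), 0, m[, 2]), n = m[, 3])
  }
  structure(list(surface = x$surface, component = x$component,
                 profile = prof), class = "traction_profiles")
}

#' @rdname circumferential_profile
#' @export
circumferential_profile.traction_components <- function(x, component = NULL,
                                                        bin_width = NULL,
                                                        ...) {
  d <- x$data
  if (is.null(component))
    component <- if (x$surface == "wall") "T_n" else "T_n"
  v <- d[[component]]
  if (x$surface == "wall") {
    key <- round(d$z, 6)
    ab <- sort(unique(key))
    agg <- t(vapply(ab, function(z) {
      s <- v[key == z]
      c(mean(s), if (length(s) > 1) stats::sd(s) else 0, length(s))
    }, numeric(3)))
    prof <- data.frame(abscissa = ab, mean = agg[, 1], std = agg[, 2],
                       n = agg[, 3])
  } else {
    Rb <- x$geometry$radius - x$geometry$fillet_bottom
    if (is.null(bin_width)) bin_width <- Rb / 8
    bins <- seq(0, Rb + bin_width, by = bin_width)
    idx <- findInterval(d$r, bins)
    agg <- tapply(v, idx, function(s) c(mean(s),
                                        if (length(s) > 1) stats::sd(s) else 0,
                                        length(s)))
    ab <- bins[as.integer(names(agg))] + bin_width / 2
    m <- do.call(rbind, agg)
    prof <- data.frame(abscissa = ab, mean = m[, 1], std = m[, 2], n = m[, 3])
  }
  structure(list(surface = x$surface, component = component, profile = prof),
            class = "traction_profiles")
}

#' @export
print.traction_profiles <- function(x, ...) {
  cat(sprintf("traction_profiles (%s, %s): %d rows, mean range [%.1f, %.1f] Pa\n",
              x$surface, x$component, nrow(x$profile),
              min(x$profile$mean), max(x$profile$mean)))
  invisible(x)
}

#' Align traction profiles at their lowest point
#'
#' Wells of slightly different depths yield profiles of different lengths
#' (e.g. 12 µm vs 11 µm deep wells). For group display all profiles are
#' aligned to the same lowest point; samples beyond the shortest common
#' support are retained but flagged `displayed = FALSE` so they are excluded
#' from group means and standard deviations.
#'
#' @param profiles A list of `traction_profiles`.
#' @return The list with shifted abscissae (0 at each profile's lowest point)
#'   and a `displayed` column.
#' @export
align_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, logical(1), "traction_profiles")))
  spans <- vapply(profiles, function(p) diff(range(p$profile$abscissa)),
                  numeric(1))
  common <- min(spans)
  lapply(profiles, function(p) {
    p$profile$abscissa <- p$profile$abscissa - min(p$profile$abscissa)
    p$profile$displayed <- p$profile$abscissa <= common + 1e-9
    p
  })
}
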