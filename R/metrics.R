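#' Measure-weighted mean traction of a profile
#'
#' Mean of the signed component values of a circumferential profile, weighted
#' by the measure each row represents (arc-band area for wall rows, annulus
#' area for bottom rows, or user-supplied weights). The sign is meaningful:
#' for `T_n`-wall, negative is contractile (inward), positive extensile.
#'
#' @param profile A `traction_profiles` object.
#' @param weights Optional row weights; default equal weights (the unweighted
#'   profile-sample average is also reported by [well_metrics()]).
#' @return Mean traction (Pa).
#' @export
mean_traction <- function(profile, weights = NULL) {
  stopifnot(inherits(profile, "traction_profiles"))
  p <- profile$profile
  if (nrow(p) == 0) stop("empty profile")
  if (is.null(weights)) weights <- rep(1, nrow(p))
  stopifnot(length(weights) == nrow(p))
  sum(p$mean * weights) / sum(weights)
}

#' Coefficient of variation of a traction profile
#'
#' Sample standard deviation of the profile values divided by their mean
#' (absolute value reported) — a measure of how inhomogeneous the traction
#' pattern is along the well axis or radius.
#'
#' @param profile A `traction_profiles` object.
#' @param tol Means with `|mean| < tol` (Pa) make the ratio meaningless and
#'   raise an error.
#' @return Unitless CoV (>= 0).
#' @export
coefficient_of_variation <- function(profile, tol = 1e-9) {
  stopifnot(inherits(profile, "traction_profiles"))
  v <- profile$profile$mean
  m <- mean(v)
  if (abs(m) < tol)
    stop("undefined CoV: profile mean is zero within tolerance")
  abs(stats::sd(v) / m)
}

#' Signal-to-noise ratio of traction profiles
#'
#' Ratio of the mean absolute value of a signal profile (e.g. from a cell) to
#' that of a noise profile (e.g. from an empty or trypsinized well), after
#' alignment on a common abscissa support.
#'
#' @param signal_profile,noise_profile `traction_profiles` on matched
#'   abscissae (see [align_profiles()]).
#' @return Unitless SNR; `Inf` for identically zero noise.
#' @export
snr <- function(signal_profile, noise_profile) {
  stopifnot(inherits(signal_profile, "traction_profiles"),
            inherits(noise_profile, "traction_profiles"))
  s <- signal_profile$profile
  n <- noise_profile$profile
  ns <- if ("displayed" %in% names(s)) s[s$displayed, ] else s
  nn <- if ("displayed" %in% names(n)) n[n$displayed, ] else n
  sig <- mean(abs(ns$mean))
  noi <- mean(abs(nn$mean))
  if (noi == 0) return(Inf)
  sig / noi
}

#' Net force over a surface selection
#'
#' Integrates tractions over the selected nodes, `sum(T * area)`, and converts
#' to nanonewtons (1 Pa µm² = 1 pN = 1e-3 nN). With a component and sign
#' filter this yields, e.g., the total outward push of the extensile mid-plane
#' ring.
#'
#' @param tractions A [traction_field()].
#' @param nodes Optional node-index subset; default all nodes of the field.
#' @param component `"magnitude"` for `||T||`, `"x"`, `"y"`, `"z"`, or an
#'   n x 3 matrix of unit direction vectors per node (e.g. outward normals)
#'   for a projected component.
#' @param sign_filter `"all"`, `"positive"` or `"negative"` applied to the
#'   selected component before integration.
#' @return Net force (nN).
#' @export
net_force <- function(tractions, nodes = NULL,
                      component = "magnitude",
                      sign_filter = c("all", "positive", "negative")) {
  stopifnot(inherits(tractions, "traction_field"))
  sign_filter <- match.arg(sign_filter)
  sel <- if (is.null(nodes)) seq_along(tractions$node) else
    match(nodes, tractions$node)
  if (length(sel) == 0 || any(is.na(sel)))
    stop("empty or unknown node selection")
  Tm <- tractions$traction[sel, , drop = FALSE]
  a <- tractions$area[sel]
  val <- if (is.matrix(component)) {
    rowSums(Tm * component)
  } else switch(component,
    magnitude = sqrt(rowSums(Tm^2)),
    x = Tm[, 1], y = Tm[, 2], z = Tm[, 3],
    stop("unknown component: ", component))
  keep <- switch(sign_filter, all = rep(TRUE, length(val)),
                 positive = val > 0, negative = val < 0)
  sum(val[keep] * a[keep]) * 1e-3
}

#' Cell-gel contact area of a well
#'
#' Area of the cavity surface a well-filling cell touches: the lateral wall
#' plus the bottom disk, with exact corrections for the fillet bands when
#' fillets are present. For the printed small-well dimensions (R = 5.5 µm,
#' depth = 11.5 µm, sharp edges) this is ~492 µm².
#'
#' @param geometry A [well_geometry()].
#' @return Contact area (µm²).
#' @export
contact_area <- function(geometry) {
  stopifnot(inherits(geometry, "well_geometry"))
  R <- geometry$radius; d <- geometry$depth
  fb <- geometry$fillet_bottom; ft <- geometry$fillet_top
  wall <- 2 * pi * R * (d - fb - ft)
  # surfaces of revolution of the quarter-circle fillet arcs
  top_f <- if (ft > 0) 2 * pi * ft * ((R + ft) * pi / 2 - ft) else 0
  bot_f <- if (fb > 0) 2 * pi * fb * ((R - fb) * pi / 2 + fb) else 0
  bottom <- pi * (R - fb)^2
  wall + top_f + bot_f + bottom
}

#' Approximate cell volume in a well
#'
#' Volume of the well cavity, approximating the cell as a cylinder of the
#' well's radius and depth; optionally corrected for the filleted edges
#' (Pappus' theorem on the corner regions).
#'
#' @param geometry A [well_geometry()].
#' @param fillet_correct Apply the fillet corrections; default `FALSE`
#'   (plain cylinder, as used for reported cell volumes).
#' @return Volume (µm³).
#' @export
cell_volume <- function(geometry, fillet_correct = FALSE) {
  stopifnot(inherits(geometry, "well_geometry"))
  R <- geometry$radius; d <- geometry$depth
  v <- pi * R^2 * d
  if (!fillet_correct) return(v)
  fb <- geometry$fillet_bottom; ft <- geometry$fillet_top
  vb <- if (fb > 0)
    2 * pi * (fb^2 * ((R - fb) + fb / 2) -
              (pi * fb^2 / 4 * (R - fb) + fb^3 / 3)) else 0
  vt <- if (ft > 0)
    2 * pi * (ft^2 * (R + ft / 2) -
              (pi * ft^2 / 4 * (R + ft) - ft^3 / 3)) else 0
  v - vb + vt
}

#' Summary metrics for one well
#'
#' Convenience bundle of the per-well scalar metrics computed from the
#' reconstructed tractions: mean and CoV of the `T_n`-wall profile (both
#' measure-weighted and plain sample averages), net outward/inward normal
#' force on the wall, contact area and approximate cell volume.
#'
#' @param wall_components A wall `traction_components` (see
#'   [decompose_wall()]).
#' @param geometry A [well_geometry()].
#' @return A list of class `well_metrics`.
#' @export
well_metrics <- function(wall_components, geometry) {
  stopifnot(inherits(wall_components, "traction_components"),
            wall_components$surface == "wall")
  prof <- circumferential_profile(wall_components, component = "T_n")
  d <- wall_components$data
  nrm <- cbind(cos(d$theta), sin(d$theta), 0)
  tf <- traction_field(d$node, cbind(d$T_n * cos(d$theta),
                                     d$T_n * sin(d$theta), d$T_v), d$area)
  mean_w <- sum(d$T_n * d$area) / sum(d$area)
  cov_val <- tryCatch(coefficient_of_variation(prof), error = function(e) NA_real_)
  structure(list(
    mean_Tn_wall = mean_traction(prof),
    mean_Tn_wall_area_weighted = mean_w,
    cov_Tn_wall = cov_val,
    net_extensile_force_nN = net_force(tf, component = nrm,
                                       sign_filter = "positive"),
    net_contractile_force_nN = net_force(tf, component = nrm,
                                         sign_filter = "negative"),
    contact_area_um2 = contact_area(geometry),
    cell_volume_um3 = cell_volume(geometry)), class = "well_metrics")
}

#' @export
print.well_metrics <- function(x, ...) {
  cat(sprintf("well metrics: mean T_n-wall %.1f Pa (CoV %.2f)\n",
              x$mean_Tn_wall, x$cov_Tn_wall))
  cat(sprintf("  net extensile %.2f nN / contractile %.2f nN\n",
              x$net_extensile_force_nN, x$net_contractile_force_nN))
  cat(sprintf("  contact area %.0f um2, cell volume %.0f um3\n",
              x$contact_area_um2, x$cell_volume_um3))
  invisible(x)
}
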