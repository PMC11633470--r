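#' Surface traction field on mesh nodes
#'
#' Tractions (Pa) carried by surface nodes, together with the lumped nodal
#' areas (µm²) that convert them to nodal forces (1 Pa µm² = 1 pN).
#'
#' @param node Integer node indices.
#' @param traction n x 3 matrix of traction vectors (Pa).
#' @param area Numeric nodal areas (µm²), all positive.
#' @return An object of class `traction_field`.
#' @export
traction_field <- function(node, traction, area) {
  node <- as.integer(node)
  traction <- matrix(as.numeric(traction), nrow = length(node))
  area <- as.numeric(area)
  if (nrow(traction) != length(node) || length(area) != length(node))
    stop("node, traction and area lengths must match")
  if (any(!is.finite(traction))) stop("tractions must be finite")
  if (any(area <= 0)) stop("nodal areas must be positive")
  structure(list(node = node, traction = traction, area = area),
            class = "traction_field")
}

#' @export
print.traction_field <- function(x, ...) {
  mag <- sqrt(rowSums(x$traction^2))
  cat(sprintf(
    "traction_field: %d surface nodes, |T| mean %.1f Pa (max %.1f), area %.1f um2\n",
    length(x$node), mean(mag), max(mag), sum(x$area)))
  invisible(x)
}

#' Convert nodal forces to surface tractions
#'
#' Divides each nodal force by the lumped nodal area (one third of the areas
#' of the adjacent boundary facets in the given groups). Total force is
#' conserved exactly: `sum(traction * area) == sum(force)` node by node.
#'
#' @param mesh A `well_mesh`.
#' @param node Integer node indices carrying forces.
#' @param force n x 3 matrix of nodal forces (pN).
#' @param groups Surface groups defining the lumped areas; default the well
#'   surfaces.
#' @return A [traction_field()] (Pa).
#' @export
nodal_force_to_traction <- function(mesh, node, force,
                                    groups = c("well_wall", "well_bottom")) {
  areas <- surface_node_areas(mesh, groups)
  a <- areas[as.character(node)]
  if (any(is.na(a)))
    stop("node(s) not on the requested surface group(s): ",
         paste(utils::head(node[is.na(a)], 10), collapse = ", "))
  force <- matrix(as.numeric(force), nrow = length(node))
  traction_field(node, force / a, unname(a))
}

#' Prescribe an axisymmetric traction ring on the well wall
#'
#' Builds a traction field applying a constant normal traction over a band of
#' the cavity wall — the canonical synthetic load case (e.g. a contractile
#' ring pulling the wall inward). Positive `magnitude` is extensile (outward
#' normal traction), negative contractile.
#'
#' @param mesh A `well_mesh` with geometry.
#' @param magnitude Signed normal traction (Pa); e.g. -500 for a 500 Pa inward
#'   ring.
#' @param z_center Band center height (µm); default mid-depth.
#' @param width Band full width at half maximum (µm).
#' @param taper Length (µm) of a raised-cosine ramp at each band edge; 0 for
#'   a sharp-edged band. Tapered rings are band-limited and therefore better
#'   resolved by the finite PIV interrogation volume.
#' @return A [traction_field()] on the wall nodes where the band weight is
#'   positive.
#' @export
ring_traction <- function(mesh, magnitude, z_center = NULL, width = 4,
                          taper = 0) {
  g <- mesh$geometry
  stopifnot(!is.null(g))
  if (is.null(z_center)) z_center <- g$top_z - g$depth / 2
  wall <- surface_nodes(mesh, "well_wall")
  z <- mesh$nodes[wall, 3]
  w <- ring_weight(z, z_center, width, taper)
  sel <- which(w > 1e-9)
  if (length(sel) == 0) stop("no wall nodes inside the requested band")
  nodes <- wall[sel]
  dx <- mesh$nodes[nodes, 1] - g$center_xy[1]
  dy <- mesh$nodes[nodes, 2] - g$center_xy[2]
  r <- sqrt(dx^2 + dy^2)
  tr <- magnitude * w[sel] * cbind(dx / r, dy / r, 0)
  areas <- surface_node_areas(mesh, c("well_wall", "well_bottom"))
  traction_field(nodes, tr, unname(areas[as.character(nodes)]))
}

#' Axial weight profile of a traction ring
#'
#' Plateau of 1 with raised-cosine ramps: full width at half maximum `width`,
#' ramp length `taper` per edge (sharp-edged band for `taper = 0`).
#'
#' @param z Heights (µm).
#' @param z_center Band center (µm).
#' @param width Full width at half maximum (µm).
#' @param taper Ramp length (µm).
#' @return Weights in `[0, 1]`.
#' @export
ring_weight <- function(z, z_center, width, taper = 0) {
  dz <- abs(z - z_center)
  if (taper <= 0) return(as.numeric(dz <= width / 2 + 1e-9))
  p <- width / 2 - taper / 2 # plateau half-width
  if (p < 0) stop("taper too long for the requested width")
  w <- numeric(length(dz))
  w[dz <= p] <- 1
  ramp <- dz > p & dz < p + taper
  w[ramp] <- 0.5 * (1 + cos(pi * (dz[ramp] - p) / taper))
  w
}

#' Matched-filter amplitude of a recovered traction ring
#'
#' Estimates the amplitude of a prescribed ring pattern from reconstructed
#' wall tractions: `sum(w T_n A) / sum(w^2 A)` over wall nodes, where `w` is
#' the ring's axial weight profile. For a reconstruction equal to
#' `amplitude * w` this returns the amplitude exactly; for the sharp-edged
#' band it reduces to the area-weighted band mean.
#'
#' @param components A wall `traction_components` (see [decompose_wall()]).
#' @param z_center,width,taper Ring parameters as in [ring_traction()].
#' @return Estimated signed ring amplitude (Pa).
#' @export
ring_amplitude <- function(components, z_center, width, taper = 0) {
  stopifnot(inherits(components, "traction_components"),
            components$surface == "wall")
  d <- components$data
  w <- ring_weight(d$z, z_center, width, taper)
  if (sum(w^2 * d$area) == 0) stop("no wall nodes under the ring weight")
  sum(w * d$T_n * d$area) / sum(w^2 * d$area)
}

#' Evaluate FEM displacements at arbitrary points
#'
#' Linear interpolation of a nodal displacement solution inside the tet mesh
#' (barycentric within the containing element); used to move synthetic beads
#' with a forward solution. Points outside the mesh get the nearest node's
#' value.
#'
#' @param mesh A `well_mesh`.
#' @param u n x 3 nodal displacement matrix (µm).
#' @return A function mapping an m x 3 point matrix to an m x 3 displacement
#'   matrix.
#' @export
displacement_interpolator <- function(mesh, u) {
  nodes <- mesh$nodes
  tets <- mesh$tets
  eg <- element_gradients(nodes, tets)
  p1 <- nodes[tets[, 1], , drop = FALSE]
  # centroid-based search acceleration
  cent <- (nodes[tets[, 1], ] + nodes[tets[, 2], ] + nodes[tets[, 3], ] +
           nodes[tets[, 4], ]) / 4
  rad <- sqrt(pmax(
    rowSums((nodes[tets[, 1], ] - cent)^2),
    rowSums((nodes[tets[, 2], ] - cent)^2),
    rowSums((nodes[tets[, 3], ] - cent)^2),
    rowSums((nodes[tets[, 4], ] - cent)^2)))
  function(p) {
    p <- matrix(as.numeric(p), ncol = 3)
    out <- matrix(NA_real_, nrow(p), 3)
    for (q in seq_len(nrow(p))) {
      d2 <- (cent[, 1] - p[q, 1])^2 + (cent[, 2] - p[q, 2])^2 +
        (cent[, 3] - p[q, 3])^2
      cand <- which(d2 <= (1.0001 * rad)^2)
      cand <- cand[order(d2[cand])]
      hit <- FALSE
      for (e in cand) {
        d <- p[q, ] - p1[e, ]
        # barycentric via shape gradients: N_a(p) for a = 2..4
        b2 <- sum(eg$G[e, 2, ] * d)
        b3 <- sum(eg$G[e, 3, ] * d)
        b4 <- sum(eg$G[e, 4, ] * d)
        b1 <- 1 - b2 - b3 - b4
        if (min(b1, b2, b3, b4) >= -1e-9) {
          out[q, ] <- b1 * u[tets[e, 1], ] + b2 * u[tets[e, 2], ] +
            b3 * u[tets[e, 3], ] + b4 * u[tets[e, 4], ]
          hit <- TRUE
          break
        }
      }
      if (!hit) {
        nn <- which.min((nodes[, 1] - p[q, 1])^2 + (nodes[, 2] - p[q, 2])^2 +
                        (nodes[, 3] - p[q, 3])^2)
        out[q, ] <- u[nn, ]
      }
    }
    out
  }
}
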