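#' Tetrahedral mesh of the gel block with a filleted cylindrical cavity
#'
#' Meshes the square gel prism with the well cavity sunk into its top surface
#' using 4-node linear tetrahedra. The mesh is a structured extrusion: each
#' horizontal cross-section is a fixed triangulated layout (a polar disk under
#' the cavity plus a circle-to-square blended ring around it), levels are
#' stacked along z following the cavity profile (straight wall plus fillet
#' arcs), and every triangular prism between consecutive levels is split into
#' three tetrahedra using the lowest-global-index diagonal rule, which yields a
#' conforming mesh. Element size is ~`target_edge_length` near the cavity and
#' grows geometrically toward the remote base and lateral boundaries.
#'
#' Boundary facets are labeled into disjoint surface groups covering the whole
#' boundary: `well_wall` (cavity wall including both fillet bands), `well_bottom`
#' (flat cavity floor), `gel_top` (free top surface), `base` (glass-bonded
#' bottom) and `lateral` (remote vertical faces).
#'
#' @param geometry A [well_geometry()].
#' @param target_edge_length Desired edge length near the cavity (µm); must be
#'   below `radius / 2`.
#' @return An object of class `well_mesh` with `nodes` (n x 3 µm), `tets`
#'   (m x 4 node indices, positively oriented), `surface` (named list of facet
#'   index matrices) and the generating `geometry`.
#' @export
build_mesh <- function(geometry, target_edge_length) {
  stopifnot(inherits(geometry, "well_geometry"))
  h <- target_edge_length
  if (!(h > 0 && h < geometry$radius / 2))
    stop("target_edge_length must be positive and below radius/2 ",
         sprintf("(geometry: R = %g, depth = %g)", geometry$radius,
                 geometry$depth))
  g <- geometry
  R <- g$radius; fb <- g$fillet_bottom; ft <- g$fillet_top
  top <- g$top_z; bottom <- top - g$depth; base <- top - g$gel_height
  L <- g$lateral_extent; C <- g$center_xy
  Rb <- R - fb

  # multiple of 8 so the square-corner directions (45 deg etc.) carry nodes
  ntheta <- max(16L, 8L * as.integer(ceiling(2 * pi * R / h / 8)))
  theta <- 2 * pi * (seq_len(ntheta) - 1) / ntheta

  zlv <- mesh_z_levels(g, h)
  tolz <- 1e-9 * g$gel_height

  # radial stations
  m <- max(2L, as.integer(round(Rb / h)))          # disk rings (incl. shared)
  disk_r <- Rb * seq_len(m - 1) / m                # interior disk rings
  sq <- square_boundary(theta, L, C)               # outer square points
  D <- mean(sqrt((sq[, 1] - (C[1] + R * cos(theta)))^2 +
                 (sq[, 2] - (C[2] + R * sin(theta)))^2))
  nr <- max(4L, as.integer(ceiling(log(1 + 0.6 * D / h) / log(1.6))))
  gam <- min(3, max(1, log(h / D) / log(1 / nr)))
  tj <- (seq(0, nr) / nr)^gam

  # local cross-section indexing: ring nodes first, then disk nodes
  rl <- function(i, j) ((i - 1L) %% ntheta) + 1L + ntheta * j  # i 1..ntheta, j 0..nr
  n_ring <- ntheta * (nr + 1L)
  dl <- function(i, k) n_ring + 1L + ((i - 1L) %% ntheta) + ntheta * (k - 1L) + 1L
  id_center <- n_ring + 1L
  n_full <- n_ring + 1L + ntheta * (m - 1L)

  tri_ring <- matrix(0L, 2L * ntheta * nr, 3L)
  r <- 0L
  for (j in 0:(nr - 1L)) for (i in seq_len(ntheta)) {
    A <- rl(i, j); B <- rl(i + 1L, j); Cc <- rl(i + 1L, j + 1L); Dd <- rl(i, j + 1L)
    tri_ring[r + 1L, ] <- c(A, B, Cc)
    tri_ring[r + 2L, ] <- c(A, Cc, Dd)
    r <- r + 2L
  }
  tri_disk <- list()
  if (m == 1L) {
    tri_disk <- lapply(seq_len(ntheta), function(i)
      c(id_center, rl(i, 0L), rl(i + 1L, 0L)))
  } else {
    tri_disk <- lapply(seq_len(ntheta), function(i)
      c(id_center, dl(i, 1L), dl(i + 1L, 1L)))
    ann <- function(inner, outer) {
      out <- vector("list", 2L * ntheta)
      for (i in seq_len(ntheta)) {
        A <- inner(i); B <- inner(i + 1L); Cc <- outer(i + 1L); Dd <- outer(i)
        out[[2L * i - 1L]] <- c(A, B, Cc)
        out[[2L * i]] <- c(A, Cc, Dd)
      }
      out
    }
    if (m > 2L)
      for (k in seq_len(m - 2L))
        tri_disk <- c(tri_disk, ann(function(i) dl(i, k),
                                    function(i) dl(i, k + 1L)))
    tri_disk <- c(tri_disk, ann(function(i) dl(i, m - 1L),
                                function(i) rl(i, 0L)))
  }
  tri_disk <- do.call(rbind, tri_disk)

  # instantiate nodes level by level
  nlev <- length(zlv)
  full_lvl <- zlv <= bottom + tolz
  id_maps <- vector("list", nlev)
  nodes <- vector("list", nlev)
  nxt <- 0L
  for (l in seq_len(nlev)) {
    z <- zlv[l]
    rin <- if (full_lvl[l]) Rb else cavity_radius(g, z)
    ringp <- matrix(0, n_ring, 3)
    for (j in 0:nr) {
      inner <- cbind(C[1] + rin * cos(theta), C[2] + rin * sin(theta))
      p <- (1 - tj[j + 1]) * inner + tj[j + 1] * sq
      ringp[rl(seq_len(ntheta), j), 1:2] <- p
    }
    ringp[, 3] <- z
    if (full_lvl[l]) {
      diskp <- matrix(0, 1L + ntheta * (m - 1L), 3)
      diskp[1, ] <- c(C, z)
      if (m > 1L) for (k in seq_len(m - 1L))
        diskp[dl(seq_len(ntheta), k) - n_ring, ] <-
          cbind(C[1] + disk_r[k] * cos(theta), C[2] + disk_r[k] * sin(theta), z)
      lev <- rbind(ringp, diskp)
    } else lev <- ringp
    ids <- nxt + seq_len(nrow(lev))
    nxt <- nxt + nrow(lev)
    id_maps[[l]] <- ids
    nodes[[l]] <- lev
  }
  nodes <- do.call(rbind, nodes)

  # prisms per slab -> tets
  tets <- vector("list", nlev - 1L)
  for (l in seq_len(nlev - 1L)) {
    tris <- if (full_lvl[l + 1L]) rbind(tri_ring, tri_disk) else tri_ring
    lo <- id_maps[[l]]
    hi <- id_maps[[l + 1L]]
    tets[[l]] <- split_prisms(cbind(lo[tris[, 1]], lo[tris[, 2]], lo[tris[, 3]],
                                    hi[tris[, 1]], hi[tris[, 2]], hi[tris[, 3]]))
  }
  tets <- do.call(rbind, tets)
  tets <- orient_tets(nodes, tets)

  surface <- classify_boundary(nodes, tets, g, tolz)
  structure(list(nodes = nodes, tets = tets, surface = surface,
                 geometry = g, target_edge_length = h),
            class = "well_mesh")
}

#' @export
print.well_mesh <- function(x, ...) {
  cat(sprintf("well_mesh: %d nodes, %d tets; surface groups: %s\n",
              nrow(x$nodes), nrow(x$tets),
              paste(sprintf("%s(%d)", names(x$surface),
                            vapply(x$surface, nrow, 1L)), collapse = ", ")))
  invisible(x)
}

# z-levels: fillet arcs resolved by angle, straight wall uniform, geometric
# coarsening below the cavity down to the base.
mesh_z_levels <- function(g, h) {
  top <- g$top_z; bottom <- top - g$depth; base <- top - g$gel_height
  fb <- g$fillet_bottom; ft <- g$fillet_top
  z <- c(bottom, top)
  if (fb > 0) {
    nseg <- max(2L, ceiling(fb * pi / 2 / h))
    beta <- seq(0, pi / 2, length.out = nseg + 1L)
    z <- c(z, bottom + fb * (1 - cos(beta)))
  }
  if (ft > 0) {
    nseg <- max(2L, ceiling(ft * pi / 2 / h))
    gamma <- seq(0, pi / 2, length.out = nseg + 1L)
    z <- c(z, top - ft + ft * sin(gamma))
  }
  lo <- bottom + fb; hi <- top - ft
  nmid <- max(1L, ceiling((hi - lo) / h))
  z <- c(z, seq(lo, hi, length.out = nmid + 1L))
  z <- sort(unique(round(z, 9)))
  # below the cavity: geometric growth from ~h to the base
  dz <- h
  off <- c()
  acc <- 0
  while (acc < (bottom - base) - 1e-9) {
    acc <- acc + dz
    off <- c(off, acc)
    dz <- dz * 1.7
  }
  if (length(off)) off <- off * (bottom - base) / max(off)
  sort(unique(round(c(base, bottom - off, z), 9)))
}

square_boundary <- function(theta, L, C) {
  s <- (L / 2) / pmax(abs(cos(theta)), abs(sin(theta)))
  cbind(C[1] + s * cos(theta), C[2] + s * sin(theta))
}

# Split prisms (rows: bottom a,b,c then top a',b',c' with vertical edges
# i -- i+3) into 3 tets each, choosing face diagonals through the smallest
# global node index; this is guaranteed to produce a conforming
# tetrahedralization of an extruded prism mesh.
split_prisms <- function(pr) {
  perms <- list(c(1, 2, 3, 4, 5, 6), c(2, 3, 1, 5, 6, 4), c(3, 1, 2, 6, 4, 5),
                c(4, 6, 5, 1, 3, 2), c(5, 4, 6, 2, 1, 3), c(6, 5, 4, 3, 2, 1))
  n <- nrow(pr)
  out <- matrix(0L, 3L * n, 4L)
  for (e in seq_len(n)) {
    v <- pr[e, ]
    k <- which.min(v)
    v <- v[perms[[which(vapply(perms, function(p) p[1] == k, logical(1)))]]]
    if (min(v[2], v[6]) < min(v[3], v[5])) {
      t3 <- rbind(c(v[1], v[2], v[3], v[6]),
                  c(v[1], v[2], v[6], v[5]),
                  c(v[1], v[5], v[6], v[4]))
    } else {
      t3 <- rbind(c(v[1], v[2], v[3], v[5]),
                  c(v[1], v[5], v[3], v[6]),
                  c(v[1], v[5], v[6], v[4]))
    }
    out[(3L * e - 2L):(3L * e), ] <- t3
  }
  out
}

tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 2], ] - nodes[tets[, 1], ]
  b <- nodes[tets[, 3], ] - nodes[tets[, 1], ]
  c <- nodes[tets[, 4], ] - nodes[tets[, 1], ]
  (a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) +
   a[, 2] * (b[, 3] * c[, 1] - b[, 1] * c[, 3]) +
   a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

orient_tets <- function(nodes, tets) {
  v <- tet_volumes(nodes, tets)
  if (any(abs(v) < 1e-12))
    stop("meshing failure: degenerate tetrahedra produced")
  neg <- v < 0
  if (any(neg)) tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
  tets
}

# faces of each tet, outward ordering not guaranteed
tet_faces <- function(tets) {
  rbind(tets[, c(1, 2, 3)], tets[, c(1, 2, 4)],
        tets[, c(1, 3, 4)], tets[, c(2, 3, 4)])
}

boundary_faces <- function(tets) {
  f <- tet_faces(tets)
  key <- apply(f, 1, function(r) paste(sort(r), collapse = "-"))
  tab <- table(key)
  if (any(tab > 2)) stop("meshing failure: non-manifold face detected")
  f[key %in% names(tab)[tab == 1L], , drop = FALSE]
}

classify_boundary <- function(nodes, tets, g, tolz) {
  bf <- boundary_faces(tets)
  cx <- (nodes[bf[, 1], 1] + nodes[bf[, 2], 1] + nodes[bf[, 3], 1]) / 3
  cy <- (nodes[bf[, 1], 2] + nodes[bf[, 2], 2] + nodes[bf[, 3], 2]) / 3
  cz <- (nodes[bf[, 1], 3] + nodes[bf[, 2], 3] + nodes[bf[, 3], 3]) / 3
  top <- g$top_z; bottom <- top - g$depth; base <- top - g$gel_height
  L <- g$lateral_extent; C <- g$center_xy
  tol <- max(tolz, 1e-7 * g$gel_height)
  rc <- sqrt((cx - C[1])^2 + (cy - C[2])^2)
  grp <- rep("well_wall", nrow(bf))
  grp[abs(cz - base) < tol] <- "base"
  grp[pmax(abs(cx - C[1]), abs(cy - C[2])) > L / 2 - max(1e-7 * L, tol)] <-
    "lateral"
  is_top <- abs(cz - top) < tol & grp == "well_wall"
  grp[is_top] <- "gel_top"
  is_bot <- abs(cz - bottom) < tol & rc <= (g$radius - g$fillet_bottom) + tol &
    grp == "well_wall"
  grp[is_bot] <- "well_bottom"
  out <- lapply(c(base = "base", lateral = "lateral", gel_top = "gel_top",
                  well_wall = "well_wall", well_bottom = "well_bottom"),
                function(k) bf[grp == k, , drop = FALSE])
  out
}

#' Facet areas of a surface group
#' @param mesh A `well_mesh` (or any mesh-like list with `nodes`).
#' @param facets k x 3 matrix of node indices.
#' @return Numeric vector of triangle areas (µm²).
#' @keywords internal
facet_areas <- function(mesh, facets) {
  a <- mesh$nodes[facets[, 2], , drop = FALSE] -
    mesh$nodes[facets[, 1], , drop = FALSE]
  b <- mesh$nodes[facets[, 3], , drop = FALSE] -
    mesh$nodes[facets[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sqrt(rowSums(cr^2)) / 2
}

#' Lumped nodal areas on surface groups
#'
#' Assigns each surface node one third of the area of every adjacent boundary
#' facet in the requested groups, so nodal areas sum exactly to the facet area
#' of the groups.
#'
#' @param mesh A `well_mesh`.
#' @param groups Character vector of surface group names.
#' @return Named numeric vector: area (µm²) per node id (names are node ids).
#' @export
surface_node_areas <- function(mesh, groups) {
  stopifnot(all(groups %in% names(mesh$surface)))
  f <- do.call(rbind, mesh$surface[groups])
  if (is.null(f) || nrow(f) == 0) return(numeric(0))
  ar <- facet_areas(mesh, f)
  acc <- tapply(rep(ar / 3, 3), c(f[, 1], f[, 2], f[, 3]), sum)
  out <- as.numeric(acc)
  names(out) <- names(acc)
  out
}

#' Node indices of one or more surface groups
#' @param mesh A `well_mesh`.
#' @param groups Character vector of group names.
#' @return Sorted integer vector of node indices.
#' @export
surface_nodes <- function(mesh, groups) {
  stopifnot(all(groups %in% names(mesh$surface)))
  sort(unique(as.integer(do.call(rbind, mesh$surface[groups]))))
}

#' Structured tetrahedral mesh of a rectangular block
#'
#' Simple box mesh used for solver verification against closed-form elasticity
#' solutions. Surface groups: `base` (z min), `top` (z max), `xmin`, `xmax`,
#' `ymin`, `ymax`.
#'
#' @param lx,ly,lz Block dimensions (µm).
#' @param n Integer triple of cells per axis.
#' @param origin Corner position (µm).
#' @return A `well_mesh`-like list (class `well_mesh`, `geometry = NULL`).
#' @export
build_box_mesh <- function(lx, ly, lz, n = c(4, 4, 4), origin = c(0, 0, 0)) {
  n <- as.integer(n)
  xs <- origin[1] + seq(0, lx, length.out = n[1] + 1L)
  ys <- origin[2] + seq(0, ly, length.out = n[2] + 1L)
  zs <- origin[3] + seq(0, lz, length.out = n[3] + 1L)
  nid <- function(i, j, k)
    (k - 1L) * (n[1] + 1L) * (n[2] + 1L) + (j - 1L) * (n[1] + 1L) + i
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  dimnames(nodes) <- NULL
  tris <- list()
  for (j in seq_len(n[2])) for (i in seq_len(n[1])) {
    A <- nid(i, j, 1L); B <- nid(i + 1L, j, 1L)
    Cc <- nid(i + 1L, j + 1L, 1L); Dd <- nid(i, j + 1L, 1L)
    tris <- c(tris, list(c(A, B, Cc), c(A, Cc, Dd)))
  }
  tris <- do.call(rbind, tris)
  lay <- (n[1] + 1L) * (n[2] + 1L)
  tets <- vector("list", n[3])
  for (k in seq_len(n[3])) {
    lo <- tris + (k - 1L) * lay
    tets[[k]] <- split_prisms(cbind(lo, lo + lay))
  }
  tets <- orient_tets(nodes, do.call(rbind, tets))
  bf <- boundary_faces(tets)
  cxyz <- (nodes[bf[, 1], ] + nodes[bf[, 2], ] + nodes[bf[, 3], ]) / 3
  tol <- 1e-9 * max(lx, ly, lz)
  grp <- rep(NA_character_, nrow(bf))
  grp[abs(cxyz[, 3] - origin[3]) < tol] <- "base"
  grp[abs(cxyz[, 3] - (origin[3] + lz)) < tol] <- "top"
  grp[abs(cxyz[, 1] - origin[1]) < tol] <- "xmin"
  grp[abs(cxyz[, 1] - (origin[1] + lx)) < tol] <- "xmax"
  grp[abs(cxyz[, 2] - origin[2]) < tol] <- "ymin"
  grp[abs(cxyz[, 2] - (origin[2] + ly)) < tol] <- "ymax"
  surface <- lapply(stats::setNames(nm = c("base", "top", "xmin", "xmax",
                                           "ymin", "ymax")),
                    function(k) bf[grp == k & !is.na(grp), , drop = FALSE])
  structure(list(nodes = nodes, tets = tets, surface = surface,
                 geometry = NULL, target_edge_length = min(lx / n[1],
                                                           ly / n[2],
                                                           lz / n[3])),
            class = "well_mesh")
}
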