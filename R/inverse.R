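#' Inverse solver configuration
#'
#' @param regularization_lambda Unitless Tikhonov weight scaling the traction
#'   penalty relative to the data misfit; 0 for pure least squares.
#' @param solver_tol Relative tolerance used when factorizing the normal
#'   equations.
#' @param max_basis Optional cap on the number of traction degrees of freedom
#'   (a guard for very fine meshes).
#' @return An object of class `inverse_config`.
#' @export
inverse_config <- function(regularization_lambda = 0, solver_tol = 1e-10,
                           max_basis = Inf) {
  if (regularization_lambda < 0) stop("regularization_lambda must be >= 0")
  if (solver_tol <= 0) stop("solver_tol must be positive")
  structure(list(regularization_lambda = regularization_lambda,
                 solver_tol = solver_tol, max_basis = max_basis),
            class = "inverse_config")
}

#' Interpolate a measured displacement field onto mesh surface nodes
#'
#' Carries the PIV displacement field onto the nodes of the gel surface (top
#' surface, well wall and well bottom) by componentwise linear interpolation:
#' trilinear on the PIV sample grid when the field is grid-laid-out, otherwise
#' a local moving least-squares affine fit (both reproduce affine fields
#' exactly). Nodes outside the data hull take nearest-sample values and are
#' flagged as extrapolated.
#'
#' @param field A [displacement_field()] with at least 4 valid samples.
#' @param mesh A `well_mesh`.
#' @param groups Surface groups to cover; default gel top, wall and bottom.
#' @return List: `node` (indices), `u` (n x 3 µm), `extrapolated` (logical).
#' @export
interpolate_measured_to_surface <- function(field, mesh,
                                            groups = c("gel_top", "well_wall",
                                                       "well_bottom")) {
  stopifnot(inherits(field, "displacement_field"))
  if (sum(field$valid) < 4) stop("need at least 4 valid displacement samples")
  nodes_idx <- surface_nodes(mesh, groups)
  q <- mesh$nodes[nodes_idx, , drop = FALSE]
  if (!is.null(field$grid)) {
    u <- grid_interp3(field, q, extrapolate = TRUE)
    extr <- attr(u, "extrapolated")
    # cells poisoned by invalid samples: fall back to nearest valid sample
    bad <- !stats::complete.cases(u)
    if (any(bad)) {
      u[bad, ] <- nearest_valid(field, q[bad, , drop = FALSE])
      extr[bad] <- TRUE
    }
  } else {
    fit <- mls_affine(field, q)
    u <- fit$u
    extr <- fit$extrapolated
  }
  attributes(u) <- list(dim = dim(u))
  list(node = nodes_idx, u = u, extrapolated = extr)
}

nearest_valid <- function(field, q) {
  p <- field$points[field$valid, , drop = FALSE]
  v <- field$vectors[field$valid, , drop = FALSE]
  out <- matrix(NA_real_, nrow(q), 3)
  for (i in seq_len(nrow(q))) {
    d2 <- (p[, 1] - q[i, 1])^2 + (p[, 2] - q[i, 2])^2 + (p[, 3] - q[i, 3])^2
    out[i, ] <- v[which.min(d2), ]
  }
  out
}

# local affine least squares from the k nearest valid samples
mls_affine <- function(field, q, k = 10L) {
  p <- field$points[field$valid, , drop = FALSE]
  v <- field$vectors[field$valid, , drop = FALSE]
  k <- min(k, nrow(p))
  out <- matrix(NA_real_, nrow(q), 3)
  extr <- logical(nrow(q))
  for (i in seq_len(nrow(q))) {
    d2 <- (p[, 1] - q[i, 1])^2 + (p[, 2] - q[i, 2])^2 + (p[, 3] - q[i, 3])^2
    sel <- order(d2)[seq_len(k)]
    A <- cbind(1, sweep(p[sel, , drop = FALSE], 2, q[i, ], "-"))
    ok <- qr(A)$rank >= 4
    if (ok) {
      coef <- qr.solve(A, v[sel, , drop = FALSE])
      out[i, ] <- coef[1, ]
    } else {
      out[i, ] <- v[sel[1], ]
      extr[i] <- TRUE
    }
    # outside the neighborhood's bounding box counts as extrapolation
    bb_lo <- apply(p[sel, , drop = FALSE], 2, min)
    bb_hi <- apply(p[sel, , drop = FALSE], 2, max)
    if (any(q[i, ] < bb_lo - 1e-9) || any(q[i, ] > bb_hi + 1e-9))
      extr[i] <- TRUE
  }
  list(u = out, extrapolated = extr)
}

#' Linear operator from well-surface tractions to measured displacements
#'
#' Builds the sensitivity matrix G whose column k is the displacement at the
#' measured surface dofs produced by a unit traction on the k-th traction
#' degree of freedom (nodal traction vectors on the well wall and bottom,
#' converted to forces by the lumped nodal areas). One sparse factorization is
#' reused for all columns; the operator can then serve many inverse solves
#' (e.g. a regularization sweep).
#'
#' @param mesh A `well_mesh`.
#' @param material A [material_model()] (the linear law is used).
#' @param measured_nodes Integer node indices where data are available.
#' @param traction_groups Surface groups carrying unknown tractions.
#' @param system Optional precomputed [fem_system()].
#' @return An object of class `traction_operator`.
#' @export
traction_operator <- function(mesh, material, measured_nodes,
                              traction_groups = c("well_wall", "well_bottom"),
                              system = NULL) {
  if (is.null(system)) system <- fem_system(mesh, material)
  t_nodes <- surface_nodes(mesh, traction_groups)
  t_areas <- surface_node_areas(mesh, traction_groups)
  t_areas <- unname(t_areas[as.character(t_nodes)])
  nt <- 3L * length(t_nodes)
  meas_dofs <- as.integer(t(outer(3L * (measured_nodes - 1L), 1:3, "+")))
  free <- system$free
  pos_in_free <- match(meas_dofs, free)
  if (any(is.na(pos_in_free)))
    stop("measured nodes overlap the clamped base")
  nd <- 3L * nrow(mesh$nodes)
  t_dofs <- as.integer(t(outer(3L * (t_nodes - 1L), 1:3, "+")))
  # unit traction on dof k -> force area_k at that dof
  B <- Matrix::sparseMatrix(i = match(t_dofs, free), j = seq_len(nt),
                            x = rep(t_areas, each = 3L),
                            dims = c(length(free), nt))
  G <- matrix(0, length(meas_dofs), nt)
  blk <- 200L
  for (s in seq(1L, nt, by = blk)) {
    cols <- s:min(s + blk - 1L, nt)
    X <- Matrix::solve(system$factor, B[, cols, drop = FALSE])
    G[, cols] <- as.matrix(X[pos_in_free, , drop = FALSE])
  }
  structure(list(G = G, t_nodes = t_nodes, t_areas = t_areas,
                 measured_nodes = measured_nodes, system = system,
                 traction_groups = traction_groups, mesh = mesh,
                 material = material),
            class = "traction_operator")
}

#' Reconstruct well-surface tractions from measured surface displacements
#'
#' Solves the inverse problem
#' `min_T sum_i w_i ||u_model_i - u_meas_i||^2 + lambda ||T||^2_w` subject to
#' `u_model = Forward(T)`, where the unknowns are nodal traction vectors on
#' the well wall and bottom, the gel top surface is constrained traction-free
#' by construction (its dofs are simply not unknowns), and the weights are
#' lumped nodal areas so both terms approximate surface integrals. Mechanical
#' equilibrium is satisfied exactly because the result is a forward solution.
#' Displacement data measured on the gel top still enter the misfit — this is
#' precisely what distinguishes the inverse method from imposing the data as
#' boundary conditions.
#'
#' @param mesh A `well_mesh`.
#' @param material A [material_model()].
#' @param measured List with `node` (indices) and `u` (n x 3 µm), e.g. from
#'   [interpolate_measured_to_surface()].
#' @param config An [inverse_config()]; `regularization_lambda` is unitless
#'   (scaled internally against the data term).
#' @param operator Optional precomputed [traction_operator()] for the same
#'   measured node set.
#' @return An object of class `inverse_solution`: `tractions` (a
#'   [traction_field()], Pa), `u_model` (matched to the measured nodes),
#'   `misfit` (µm²-weighted residual), `lambda`, `operator`.
#' @export
solve_inverse <- function(mesh, material, measured,
                          config = inverse_config(), operator = NULL) {
  stopifnot(inherits(config, "inverse_config"))
  if (is.null(operator))
    operator <- traction_operator(mesh, material, measured$node)
  if (!identical(operator$measured_nodes, measured$node))
    stop("operator was built for a different measured node set")
  G <- operator$G
  if (ncol(G) > 3 * config$max_basis)
    stop("traction basis exceeds max_basis; coarsen the mesh")
  w_nodes <- surface_node_areas(mesh, c("gel_top", "well_wall", "well_bottom"))
  w <- unname(w_nodes[as.character(measured$node)])
  if (any(is.na(w))) w[is.na(w)] <- 0
  W <- rep(w, each = 3L)
  b <- as.numeric(t(measured$u))
  GtW <- t(G * W)
  A <- GtW %*% G
  rhs <- as.numeric(GtW %*% b)
  lam <- config$regularization_lambda
  if (lam > 0) {
    Reg <- rep(operator$t_areas, each = 3L)
    scale <- mean(diag(A)) / mean(Reg)
    A <- A + diag(lam * scale * Reg, nrow(A))
  }
  A <- A + diag(config$solver_tol * mean(diag(A)), nrow(A))
  tvec <- solve(A, rhs)
  u_model <- as.numeric(G %*% tvec)
  r <- b - u_model
  msf <- sum(W * r^2)
  tr <- matrix(tvec, ncol = 3, byrow = TRUE)
  structure(list(
    tractions = traction_field(operator$t_nodes, tr, operator$t_areas),
    u_model = matrix(u_model, ncol = 3, byrow = TRUE),
    measured_nodes = measured$node,
    misfit = msf, lambda = lam, operator = operator),
    class = "inverse_solution")
}

#' @export
print.inverse_solution <- function(x, ...) {
  cat(sprintf(
    "inverse_solution: %d traction nodes, lambda = %g, misfit = %.4g um2*um2\n",
    length(x$tractions$node), x$lambda, x$misfit))
  invisible(x)
}

#' Area-weighted displacement misfit
#'
#' `sum_i w_i ||u_model_i - u_meas_i||^2` over a matched node set; zero iff
#' the fields coincide on nodes with positive weight.
#'
#' @param u_model,u_measured n x 3 matrices (µm) on the same node set.
#' @param weights Nodal weights (µm²); default 1.
#' @return Scalar weighted residual.
#' @export
misfit <- function(u_model, u_measured, weights = NULL) {
  u_model <- as.matrix(u_model)
  u_measured <- as.matrix(u_measured)
  if (!all(dim(u_model) == dim(u_measured)))
    stop("mismatched node sets: model and measured displacements differ in size")
  if (is.null(weights)) weights <- rep(1, nrow(u_model))
  if (length(weights) != nrow(u_model))
    stop("mismatched node sets: weights length differs")
  sum(weights * rowSums((u_model - u_measured)^2))
}

#' Direct Dirichlet traction computation (diagnostic)
#'
#' The first-attempt approach: impose the measured displacements directly as
#' essential boundary conditions on all measured surfaces (gel top, well wall,
#' well bottom), solve, and convert the boundary reactions to tractions. With
#' noisy data this produces spurious nonzero tractions on the gel top — the
#' surface no cell touches — which is why the inverse formulation is
#' preferred. Kept as a diagnostic for comparison.
#'
#' @inheritParams solve_inverse
#' @return List of [traction_field()]s per surface group (`gel_top`,
#'   `well_wall`, `well_bottom`) plus the full displacement solution `u`.
#' @export
direct_dirichlet_solve <- function(mesh, material, measured) {
  base_nodes <- surface_nodes(mesh, "base")
  dir_meas <- data.frame(node = rep(measured$node, each = 3L),
                         dof = rep(1:3, length(measured$node)),
                         value = as.numeric(t(measured$u)))
  dir_base <- data.frame(node = rep(base_nodes, each = 3L),
                         dof = rep(1:3, length(base_nodes)), value = 0)
  dir <- rbind(dir_meas, dir_base[!(dir_base$node %in% measured$node), ])
  sol <- solve_forward(mesh, material, tractions = NULL, dirichlet = dir)
  out <- list(u = sol$u)
  for (grp in c("gel_top", "well_wall", "well_bottom")) {
    nds <- intersect(surface_nodes(mesh, grp), measured$node)
    if (length(nds) == 0) next
    areas <- surface_node_areas(mesh, grp)
    a <- unname(areas[as.character(nds)])
    out[[grp]] <- traction_field(nds, sol$reactions[nds, , drop = FALSE] / a, a)
  }
  out
}

#' Pick a regularization weight from an L-curve sweep
#'
#' Computes the misfit/penalty trade-off for a grid of lambda values on a
#' shared [traction_operator()] and returns the corner (maximum curvature of
#' the log-log L-curve).
#'
#' @param mesh,material,measured,operator As in [solve_inverse()].
#' @param lambdas Candidate unitless regularization weights.
#' @return List: `lambda` (corner value), `sweep` (data.frame of lambda,
#'   misfit, penalty).
#' @export
choose_lambda_lcurve <- function(mesh, material, measured, operator = NULL,
                                 lambdas = 10^seq(-8, 0, length.out = 17)) {
  if (is.null(operator))
    operator <- traction_operator(mesh, material, measured$node)
  res <- lapply(lambdas, function(l) {
    s <- solve_inverse(mesh, material, measured,
                       inverse_config(regularization_lambda = l),
                       operator = operator)
    c(misfit = s$misfit,
      penalty = sum(rep(operator$t_areas, each = 3) *
                    as.numeric(t(s$tractions$traction))^2))
  })
  sweep <- data.frame(lambda = lambdas, do.call(rbind, res))
  # corner by the triangle method: the point of the normalized log-log curve
  # farthest from the chord joining its endpoints
  lr <- log10(pmax(sweep$misfit, 1e-300))
  lp <- log10(pmax(sweep$penalty, 1e-300))
  sc <- function(v) (v - min(v)) / max(diff(range(v)), 1e-12)
  x <- sc(lr)
  y <- sc(lp)
  n <- length(lambdas)
  ex <- x[n] - x[1]
  ey <- y[n] - y[1]
  dist <- abs(ex * (y[1] - y) - ey * (x[1] - x)) / sqrt(ex^2 + ey^2)
  list(lambda = lambdas[which.max(dist)], sweep = sweep)
}
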