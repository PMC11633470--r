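#' Gel material model
#'
#' Isotropic elastic law of the polyacrylamide gel. The tested core is linear
#' (small-strain) elasticity, appropriate for the ~15 kPa gels and the small
#' measured strains; a compressible Neo-Hookean law (parameters derived from E
#' and nu) is available to account for geometric/material nonlinearity.
#'
#' Units throughout the solver are µm, Pa and pN (1 Pa µm² = 1 pN), which keeps
#' stiffness and load magnitudes well scaled.
#'
#' @param youngs_modulus Young's modulus E (Pa); default 15000.
#' @param poisson_ratio Poisson ratio nu; default 0.45 (the gel is nearly
#'   incompressible but linear tetrahedra lock as nu -> 0.5).
#' @param law `"linear"` or `"neo_hookean"`.
#' @return An object of class `material_model`.
#' @export
material_model <- function(youngs_modulus = 15000, poisson_ratio = 0.45,
                           law = c("linear", "neo_hookean")) {
  if (youngs_modulus <= 0) stop("Young's modulus must be positive")
  if (poisson_ratio <= -1 || poisson_ratio >= 0.5)
    stop("Poisson ratio must lie in (-1, 0.5)")
  structure(list(youngs_modulus = youngs_modulus,
                 poisson_ratio = poisson_ratio, law = match.arg(law)),
            class = "material_model")
}

lame_parameters <- function(material) {
  E <- material$youngs_modulus
  nu <- material$poisson_ratio
  list(mu = E / (2 * (1 + nu)), lambda = E * nu / ((1 + nu) * (1 - 2 * nu)))
}

# shape-function gradients (per element, 4 x 3) and volumes
element_gradients <- function(nodes, tets) {
  m <- nrow(tets)
  p1 <- nodes[tets[, 1], , drop = FALSE]
  e1 <- nodes[tets[, 2], , drop = FALSE] - p1
  e2 <- nodes[tets[, 3], , drop = FALSE] - p1
  e3 <- nodes[tets[, 4], , drop = FALSE] - p1
  det <- e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) +
    e1[, 2] * (e2[, 3] * e3[, 1] - e2[, 1] * e3[, 3]) +
    e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])
  # rows of inv(J) where J = [e1; e2; e3]: gradients of N2, N3, N4
  inv <- array(0, c(m, 3, 3))
  inv[, 1, 1] <- (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) / det
  inv[, 1, 2] <- (e1[, 3] * e3[, 2] - e1[, 2] * e3[, 3]) / det
  inv[, 1, 3] <- (e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]) / det
  inv[, 2, 1] <- (e2[, 3] * e3[, 1] - e2[, 1] * e3[, 3]) / det
  inv[, 2, 2] <- (e1[, 1] * e3[, 3] - e1[, 3] * e3[, 1]) / det
  inv[, 2, 3] <- (e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]) / det
  inv[, 3, 1] <- (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1]) / det
  inv[, 3, 2] <- (e1[, 2] * e3[, 1] - e1[, 1] * e3[, 2]) / det
  inv[, 3, 3] <- (e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) / det
  # dN_{a+1}/dx_j = (dxi_a/dx_j) = ((J^-1)^T)_{aj} = inv[j, a]
  G <- array(0, c(m, 4, 3))
  for (j in 1:3) {
    G[, 2, j] <- inv[, j, 1]
    G[, 3, j] <- inv[, j, 2]
    G[, 4, j] <- inv[, j, 3]
    G[, 1, j] <- -(G[, 2, j] + G[, 3, j] + G[, 4, j])
  }
  list(G = G, V = det / 6)
}

#' Assemble the global linear-elastic stiffness matrix
#'
#' Linear 4-node tetrahedra; for node pair (a, b) of an element with volume V
#' and shape gradients g, the 3x3 block is
#' `V * (lambda ga gb' + mu gb ga' + mu (ga . gb) I)`.
#'
#' @param mesh A `well_mesh`.
#' @param material A [material_model()] (Lame parameters from E, nu).
#' @return Sparse symmetric stiffness matrix (pN/µm), 3 dofs per node.
#' @export
assemble_stiffness <- function(mesh, material) {
  lam <- lame_parameters(material)
  eg <- element_gradients(mesh$nodes, mesh$tets)
  G <- eg$G
  V <- eg$V
  m <- nrow(mesh$tets)
  nd <- 3L * nrow(mesh$nodes)
  ii <- vector("list", 144)
  jj <- vector("list", 144)
  xx <- vector("list", 144)
  q <- 0L
  gdot <- array(0, c(m, 4, 4))
  for (a in 1:4) for (b in 1:4)
    gdot[, a, b] <- G[, a, 1] * G[, b, 1] + G[, a, 2] * G[, b, 2] +
      G[, a, 3] * G[, b, 3]
  for (a in 1:4) for (b in 1:4) for (i in 1:3) for (j in 1:3) {
    val <- V * (lam$lambda * G[, a, i] * G[, b, j] +
                lam$mu * G[, a, j] * G[, b, i] +
                (if (i == j) lam$mu * gdot[, a, b] else 0))
    q <- q + 1L
    ii[[q]] <- 3L * (mesh$tets[, a] - 1L) + i
    jj[[q]] <- 3L * (mesh$tets[, b] - 1L) + j
    xx[[q]] <- val
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(nd, nd))
  Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
}

#' Precompute the FEM system for repeated solves
#'
#' Assembles the stiffness matrix, applies the Dirichlet constraint set and
#' factorizes the free-free block once (sparse Cholesky), so that many load
#' cases — e.g. the sensitivity columns of the inverse problem — reuse the
#' factorization.
#'
#' @param mesh A `well_mesh`.
#' @param material A [material_model()].
#' @param fixed_nodes Integer node indices fully clamped (all 3 dofs). Default:
#'   the `base` surface group (glass-bonded gel bottom).
#' @return An object of class `fem_system`.
#' @export
fem_system <- function(mesh, material, fixed_nodes = NULL) {
  if (is.null(fixed_nodes)) {
    if (is.null(mesh$surface$base) || nrow(mesh$surface$base) == 0)
      stop("no Dirichlet constraints: mesh has no base group and no fixed_nodes")
    fixed_nodes <- surface_nodes(mesh, "base")
  }
  if (length(fixed_nodes) == 0)
    stop("singular system: no Dirichlet constraints supplied")
  K <- assemble_stiffness(mesh, material)
  nd <- nrow(K)
  fixed_dofs <- sort(as.integer(outer(3L * (fixed_nodes - 1L), 1:3, "+")))
  free <- setdiff(seq_len(nd), fixed_dofs)
  Kff <- K[free, free]
  fac <- Matrix::Cholesky(Kff, LDL = FALSE, perm = TRUE)
  structure(list(K = K, factor = fac, free = free, fixed = fixed_dofs,
                 mesh = mesh, material = material), class = "fem_system")
}

# lumped consistent load (pN) from a traction field (Pa over µm² areas)
traction_load <- function(ndof, tf) {
  f <- numeric(ndof)
  if (is.null(tf)) return(f)
  idx <- rep(3L * (tf$node - 1L), each = 3L) + rep(1:3, length(tf$node))
  f[idx] <- as.numeric(t(tf$traction * tf$area))
  f
}

#' Solve the forward elastic problem (tractions to displacements)
#'
#' Solves static equilibrium for the gel under prescribed surface tractions
#' with the base clamped and all other boundaries traction-free. The linear
#' law is solved directly (sparse Cholesky); the Neo-Hookean law by a modified
#' Newton iteration preconditioned with the elastic stiffness.
#'
#' @param mesh A `well_mesh`.
#' @param material A [material_model()].
#' @param tractions A [traction_field()] (Pa) of applied surface tractions, or
#'   `NULL` for no load.
#' @param dirichlet Optional data.frame `(node, dof, value)` of prescribed
#'   displacement components (µm) in addition to / instead of the clamped
#'   base. When supplied together with `system`, the system's constraint set
#'   must match.
#' @param system Optional precomputed [fem_system()] (must match mesh,
#'   material and the homogeneous constraint pattern).
#' @param tol Relative residual tolerance on free dofs.
#' @param max_iter Newton iteration cap (Neo-Hookean only).
#' @return List: `u` (n x 3 µm), `reactions` (n x 3 pN, nonzero on constrained
#'   nodes), `residual` (relative), `system`.
#' @export
solve_forward <- function(mesh, material, tractions = NULL, dirichlet = NULL,
                          system = NULL, tol = 1e-10, max_iter = 60L) {
  nd <- 3L * nrow(mesh$nodes)
  if (is.null(system)) {
    if (is.null(dirichlet)) {
      system <- fem_system(mesh, material)
    } else {
      fixed_dofs <- sort(unique(3L * (dirichlet$node - 1L) + dirichlet$dof))
      K <- assemble_stiffness(mesh, material)
      free <- setdiff(seq_len(nd), fixed_dofs)
      if (length(fixed_dofs) == 0)
        stop("singular system: no Dirichlet constraints supplied")
      fac <- Matrix::Cholesky(K[free, free], LDL = FALSE, perm = TRUE)
      system <- structure(list(K = K, factor = fac, free = free,
                               fixed = fixed_dofs, mesh = mesh,
                               material = material), class = "fem_system")
    }
  }
  free <- system$free
  fixed <- system$fixed
  K <- system$K
  f <- traction_load(nd, tractions)
  u <- numeric(nd)
  if (!is.null(dirichlet) && nrow(dirichlet) > 0)
    u[3L * (dirichlet$node - 1L) + dirichlet$dof] <- dirichlet$value

  rhs <- f[free] - as.numeric(K[free, fixed, drop = FALSE] %*% u[fixed])
  u[free] <- as.numeric(Matrix::solve(system$factor, rhs))

  fnorm <- sqrt(sum(f[free]^2)) + sqrt(sum(u[fixed]^2)) * 1 # scale guard
  if (material$law == "neo_hookean") {
    eg <- element_gradients(mesh$nodes, mesh$tets)
    ref <- max(sqrt(sum(f^2)), 1e-12)
    for (it in seq_len(max_iter)) {
      fint <- internal_forces_neo_hookean(mesh, eg, material, u)
      res <- f[free] - fint[free]
      if (sqrt(sum(res^2)) <= max(tol, 1e-12) * ref) break
      u[free] <- u[free] + as.numeric(Matrix::solve(system$factor, res))
    }
    fint <- internal_forces_neo_hookean(mesh, eg, material, u)
    resid <- sqrt(sum((f[free] - fint[free])^2)) / ref
    reactions <- fint - f
  } else {
    Ku <- as.numeric(K %*% u)
    resid <- sqrt(sum((Ku[free] - f[free])^2)) / max(sqrt(sum(f[free]^2)), 1e-12)
    reactions <- Ku - f
  }
  reactions[free] <- 0
  list(u = matrix(u, ncol = 3, byrow = TRUE),
       reactions = matrix(reactions, ncol = 3, byrow = TRUE),
       residual = resid, system = system)
}

# internal nodal forces for compressible Neo-Hookean:
# P = mu (F - F^-T) + lambda ln(J) F^-T
internal_forces_neo_hookean <- function(mesh, eg, material, u) {
  lam <- lame_parameters(material)
  G <- eg$G
  V <- eg$V
  tets <- mesh$tets
  m <- nrow(tets)
  U <- matrix(u, ncol = 3, byrow = TRUE)
  Fm <- array(0, c(m, 3, 3))
  for (i in 1:3) for (j in 1:3) {
    s <- 0
    for (a in 1:4) s <- s + U[tets[, a], i] * G[, a, j]
    Fm[, i, j] <- s + (i == j)
  }
  J <- Fm[, 1, 1] * (Fm[, 2, 2] * Fm[, 3, 3] - Fm[, 2, 3] * Fm[, 3, 2]) -
    Fm[, 1, 2] * (Fm[, 2, 1] * Fm[, 3, 3] - Fm[, 2, 3] * Fm[, 3, 1]) +
    Fm[, 1, 3] * (Fm[, 2, 1] * Fm[, 3, 2] - Fm[, 2, 2] * Fm[, 3, 1])
  if (any(J <= 0)) stop("element inversion during Neo-Hookean iteration")
  Fit <- array(0, c(m, 3, 3)) # inverse transpose of F
  cof <- function(i1, i2, j1, j2)
    Fm[, i1, j1] * Fm[, i2, j2] - Fm[, i1, j2] * Fm[, i2, j1]
  Fit[, 1, 1] <- cof(2, 3, 2, 3) / J
  Fit[, 1, 2] <- -cof(2, 3, 1, 3) / J
  Fit[, 1, 3] <- cof(2, 3, 1, 2) / J
  Fit[, 2, 1] <- -cof(1, 3, 2, 3) / J
  Fit[, 2, 2] <- cof(1, 3, 1, 3) / J
  Fit[, 2, 3] <- -cof(1, 3, 1, 2) / J
  Fit[, 3, 1] <- cof(1, 2, 2, 3) / J
  Fit[, 3, 2] <- -cof(1, 2, 1, 3) / J
  Fit[, 3, 3] <- cof(1, 2, 1, 2) / J
  lnJ <- log(J)
  fint <- numeric(3L * nrow(mesh$nodes))
  for (a in 1:4) for (i in 1:3) {
    val <- 0
    for (j in 1:3) {
      Pij <- lam$mu * (Fm[, i, j] - Fit[, i, j]) + lam$lambda * lnJ * Fit[, i, j]
      val <- val + Pij * G[, a, j]
    }
    idx <- 3L * (tets[, a] - 1L) + i
    acc <- rowsum(V * val, idx)
    fint[as.integer(rownames(acc))] <- fint[as.integer(rownames(acc))] + acc
  }
  fint
}
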