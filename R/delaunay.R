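# 2D Delaunay triangulation (Bowyer-Watson) and piecewise-linear scattered
# interpolation. Small-n incremental implementation used to resample nodal
# traction values onto regular unfolded grids; it reproduces nodal values
# exactly and is linear-precise inside the convex hull.

delaunay2d <- function(p) {
  p <- as.matrix(p)
  n <- nrow(p)
  if (n < 3) stop("need at least 3 points for triangulation")
  ctr <- colMeans(p)
  scale <- max(max(abs(sweep(p, 2, ctr))), 1e-12)
  q <- sweep(p, 2, ctr) / scale
  # tiny deterministic jitter breaks cocircular grid degeneracies
  set_jit <- function(i) ((i * 2654435761) %% 97L - 48L) * 1e-11
  q[, 1] <- q[, 1] + set_jit(seq_len(n))
  q[, 2] <- q[, 2] + set_jit(seq_len(n) + 7L)
  big <- 64
  sv <- rbind(c(-big, -big), c(big, -big), c(0, big))
  pts <- rbind(q, sv)
  tris <- list(c(n + 1L, n + 2L, n + 3L))
  cc <- list(circumcircle(pts, tris[[1]]))
  for (i in seq_len(n)) {
    bad <- which(vapply(cc, function(c)
      (pts[i, 1] - c[1])^2 + (pts[i, 2] - c[2])^2 < c[3], logical(1)))
    if (length(bad) == 0) next # degenerate; should not happen with jitter
    edges <- do.call(rbind, lapply(bad, function(t) {
      tr <- tris[[t]]
      rbind(sort(tr[c(1, 2)]), sort(tr[c(2, 3)]), sort(tr[c(1, 3)]))
    }))
    key <- paste(edges[, 1], edges[, 2])
    keep <- names(which(table(key) == 1L))
    poly <- edges[key %in% keep & !duplicated(key), , drop = FALSE]
    tris[bad] <- NULL
    cc[bad] <- NULL
    for (e in seq_len(nrow(poly))) {
      tr <- c(poly[e, 1], poly[e, 2], i)
      tris[[length(tris) + 1L]] <- tr
      cc[[length(cc) + 1L]] <- circumcircle(pts, tr)
    }
  }
  tm <- do.call(rbind, tris)
  tm <- tm[apply(tm <= n, 1, all), , drop = FALSE]
  tm
}

circumcircle <- function(pts, tr) {
  a <- pts[tr[1], ]; b <- pts[tr[2], ]; c <- pts[tr[3], ]
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-300) return(c(Inf, Inf, Inf))
  a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
  ux <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / d
  uy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / d
  c(ux, uy, (a[1] - ux)^2 + (a[2] - uy)^2)
}

# Piecewise-linear interpolation of scattered (x, y, v); queries outside the
# hull take the nearest data value. Returns a numeric vector.
interp_scattered <- function(p, v, q, tri = NULL) {
  p <- as.matrix(p)
  q <- as.matrix(q)
  if (is.null(tri)) tri <- delaunay2d(p)
  out <- rep(NA_real_, nrow(q))
  remaining <- seq_len(nrow(q))
  for (t in seq_len(nrow(tri))) {
    if (!length(remaining)) break
    a <- p[tri[t, 1], ]; b <- p[tri[t, 2], ]; c <- p[tri[t, 3], ]
    det <- (b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])
    if (abs(det) < 1e-300) next
    dx <- q[remaining, 1] - a[1]
    dy <- q[remaining, 2] - a[2]
    l2 <- (dx * (c[2] - a[2]) - dy * (c[1] - a[1])) / det
    l3 <- (dy * (b[1] - a[1]) - dx * (b[2] - a[2])) / det
    l1 <- 1 - l2 - l3
    tolr <- 1e-9
    inside <- l1 >= -tolr & l2 >= -tolr & l3 >= -tolr
    if (any(inside)) {
      sel <- remaining[inside]
      out[sel] <- l1[inside] * v[tri[t, 1]] + l2[inside] * v[tri[t, 2]] +
        l3[inside] * v[tri[t, 3]]
      remaining <- remaining[!inside]
    }
  }
  if (length(remaining)) {
    for (i in remaining) {
      d2 <- (p[, 1] - q[i, 1])^2 + (p[, 2] - q[i, 2])^2
      out[i] <- v[which.min(d2)]
    }
  }
  out
}
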