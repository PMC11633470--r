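#' PIV configuration
#'
#' Settings for the block-wise volumetric cross-correlation. The default
#' 32 x 32 x 8 voxel interrogation volume matches the acquisition regime the
#' method was designed for (0.104 µm pixels, 0.2 µm z-steps), giving boxes of
#' roughly 3.3 x 3.3 x 1.6 µm.
#'
#' @param box_size Integer triple, interrogation box size in voxels (x, y, z).
#' @param overlap_fraction Fractional overlap between neighboring boxes in
#'   every axis; default 0.5.
#' @param max_displacement Integer triple (or scalar), largest voxel shift
#'   searched per axis; defaults to a quarter of the box.
#' @param subpixel_method `"gaussian"` (three-point Gaussian, falling back to
#'   parabolic where log-weights are undefined) or `"parabolic"`.
#' @param min_quality Minimum normalized correlation peak for a vector to be
#'   considered valid.
#' @return An object of class `piv_config`.
#' @export
piv_config <- function(box_size = c(32L, 32L, 8L), overlap_fraction = 0.5,
                       max_displacement = NULL,
                       subpixel_method = c("gaussian", "parabolic"),
                       min_quality = 0.05) {
  box_size <- as.integer(box_size)
  stopifnot(length(box_size) == 3L)
  if (box_size[1] < 8L || box_size[2] < 8L)
    stop("interrogation box must be at least 8 voxels in x and y")
  if (box_size[3] < 4L) stop("interrogation box must be at least 4 voxels in z")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)")
  if (is.null(max_displacement)) max_displacement <- pmax(box_size %/% 4L, 2L)
  max_displacement <- rep_len(as.integer(max_displacement), 3L)
  if (any(max_displacement < 1L) || any(max_displacement >= box_size %/% 2L))
    stop("max_displacement must be >= 1 and < box_size/2 per axis")
  structure(list(box_size = box_size, overlap_fraction = overlap_fraction,
                 max_displacement = max_displacement,
                 subpixel_method = match.arg(subpixel_method),
                 min_quality = min_quality),
            class = "piv_config")
}

#' Sampled 3D displacement field
#'
#' Container for PIV output: one displacement vector (µm) per sample point,
#' with a validity mask and a per-point correlation quality. When the samples
#' form a regular grid, its layout is stored so neighborhood operations
#' (outlier filtering, grid interpolation) can use it.
#'
#' @param points n x 3 matrix of sample positions (µm).
#' @param vectors n x 3 matrix of displacements (µm).
#' @param valid Logical vector of length n.
#' @param quality Numeric vector of length n (unitless correlation metric).
#' @param grid Optional list `(dim, origin, spacing)` describing a regular
#'   grid in x-fastest order.
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(points, vectors, valid = NULL, quality = NULL,
                               grid = NULL) {
  points <- unname(as.matrix(points))
  vectors <- unname(as.matrix(vectors))
  n <- nrow(points)
  if (is.null(valid)) valid <- rep(TRUE, n)
  if (is.null(quality)) quality <- rep(NA_real_, n)
  if (nrow(vectors) != n || length(valid) != n || length(quality) != n)
    stop("points, vectors, valid and quality must have equal lengths")
  if (any(!is.finite(vectors[valid, ])))
    stop("displacement vectors must be finite where valid")
  structure(list(points = points, vectors = vectors, valid = as.logical(valid),
                 quality = as.numeric(quality), grid = grid),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("displacement_field: %d samples (%d valid)%s\n",
              nrow(x$points), sum(x$valid),
              if (!is.null(x$grid))
                sprintf(", grid %s", paste(x$grid$dim, collapse = "x"))
              else ""))
  invisible(x)
}

#' Volumetric PIV between a reference and a deformed stack
#'
#' Discretizes the stacks into interrogation boxes and measures the relative
#' displacement of each box between the deformed and reference configurations
#' by zero-mean FFT cross-correlation with subpixel peak refinement. Vectors
#' are reported in µm at the box centers using the voxel calibration.
#'
#' @param reference,deformed [image_stack()]s of identical shape and
#'   calibration (reference = relaxed gel).
#' @param config A [piv_config()].
#' @return A [displacement_field()] on the regular box-center grid. Boxes whose
#'   correlation peak sits on the search boundary, or whose content is flat,
#'   are flagged invalid.
#' @export
piv3d <- function(reference, deformed, config = piv_config()) {
  stopifnot(inherits(reference, "image_stack"), inherits(deformed, "image_stack"),
            inherits(config, "piv_config"))
  d <- dim(reference$data)
  if (!all(d == dim(deformed$data)))
    stop("reference and deformed stacks must share the same shape")
  if (abs(reference$pixel_size_xy - deformed$pixel_size_xy) > 1e-9 ||
      abs(reference$z_step - deformed$z_step) > 1e-9)
    stop("reference and deformed stacks must share the same calibration")
  box <- config$box_size
  if (any(box > d)) stop("interrogation box larger than the stack")
  step <- pmax(1L, as.integer(round(box * (1 - config$overlap_fraction))))
  starts <- lapply(1:3, function(a) seq(1L, d[a] - box[a] + 1L, by = step[a]))
  nb <- vapply(starts, length, integer(1))
  spacing_vox <- c(1, 1, 1)
  cal <- c(reference$pixel_size_xy, reference$pixel_size_xy, reference$z_step)
  maxd <- config$max_displacement

  n <- prod(nb)
  vecs <- matrix(NA_real_, n, 3)
  qual <- numeric(n)
  valid <- logical(n)
  pts <- matrix(0, n, 3)
  ctr <- (box - 1) / 2
  crop <- function(arr, s)
    arr[s[1]:(s[1] + box[1] - 1L), s[2]:(s[2] + box[2] - 1L),
        s[3]:(s[3] + box[3] - 1L), drop = FALSE]
  # zero-padded linear cross-correlation, normalized by the overlap volume of
  # each shift so the peak shape is unbiased (no circular wraparound of the
  # broad axial peak in the short z boxes)
  pad <- box + 2L * maxd
  ovl <- lapply(1:3, function(k) {
    s <- seq_len(pad[k]) - 1L
    s <- ifelse(s > pad[k] / 2, s - pad[k], s)
    pmax(box[k] - abs(s), 0L)
  })
  ovl_norm <- prod(box) / pmax(ovl[[1]] %o% ovl[[2]] %o% ovl[[3]], 1)
  xcorr <- function(a, b) {
    A <- array(0, pad); A[seq_len(box[1]), seq_len(box[2]), seq_len(box[3])] <- a
    B <- array(0, pad); B[seq_len(box[1]), seq_len(box[2]), seq_len(box[3])] <- b
    cc <- Re(stats::fft(Conj(stats::fft(A)) * stats::fft(B), inverse = TRUE)) /
      prod(pad)
    cc * ovl_norm
  }
  i <- 0L
  for (kz in starts[[3]]) for (ky in starts[[2]]) for (kx in starts[[1]]) {
    i <- i + 1L
    s0 <- c(kx, ky, kz)
    pts[i, ] <- reference$origin + (s0 - 1 + ctr) * cal
    a <- crop(reference$data, s0)
    a <- a - mean(a)
    na2 <- sum(a * a)
    if (na2 <= 1e-14) next
    # iterated discrete window offset: re-crop the deformed window at the
    # accumulated integer shift until the residual peak is zero, so the
    # final correlation compares fully overlapping content and the
    # three-point fit is unbiased (integer translations are then recovered
    # exactly on boxes whose offset window stays inside the stack)
    clamp_off <- function(o) pmin(pmax(o, 1L - s0), d - (s0 + box - 1L))
    matched_q <- function(o) {
      b <- crop(deformed$data, s0 + o)
      b <- b - mean(b)
      nb <- sum(b * b)
      if (nb <= 1e-14) return(-Inf)
      sum(a * b) / sqrt(na2 * nb)
    }
    off <- c(0L, 0L, 0L)
    pk2 <- NULL
    for (it in 1:3) {
      b <- crop(deformed$data, s0 + off)
      b <- b - mean(b)
      if (sum(b * b) <= 1e-14) break
      pk2 <- correlation_peak(xcorr(a, b), maxd)
      if (is.null(pk2) || all(pk2$shift == 0L)) break
      off_new <- clamp_off(off + pk2$shift)
      if (all(off_new == off)) break # clamped at the stack edge
      off <- off_new
      pk2 <- NULL
    }
    # polish the integer offset where the broad (axial) peak makes discrete
    # samples ambiguous: hill-climb on the matched normalized correlation
    qbest <- matched_q(off)
    if (!is.finite(qbest)) next
    for (it in 1:6) {
      cand <- rbind(off + c(1, 0, 0), off - c(1, 0, 0), off + c(0, 1, 0),
                    off - c(0, 1, 0), off + c(0, 0, 1), off - c(0, 0, 1))
      qs <- apply(cand, 1, function(o) {
        o <- as.integer(o)
        if (any(clamp_off(o) != o) || any(abs(o) > maxd)) -Inf
        else matched_q(o)
      })
      if (max(qs) <= qbest + 1e-12) break
      off <- as.integer(cand[which.max(qs), ])
      qbest <- max(qs)
    }
    b <- crop(deformed$data, s0 + off)
    b <- b - mean(b)
    nb2 <- sum(b * b)
    if (nb2 <= 1e-14) next
    cc <- xcorr(a, b)
    pk2 <- correlation_peak(cc, maxd)
    if (is.null(pk2)) next
    sp <- subpixel_peak(cc, peak = pk2$index, method = config$subpixel_method,
                        periodic = TRUE)
    q <- pk2$value / sqrt(na2 * nb2)
    qual[i] <- q
    if (!sp$valid || q < config$min_quality) next
    if (any(abs(off + pk2$shift) > maxd)) next # beyond the search range
    vecs[i, ] <- (off + pk2$shift + sp$offset) * cal
    valid[i] <- TRUE
  }
  # x-fastest ordering matches the loop nesting above
  grid <- list(dim = nb,
               origin = reference$origin + (c(starts[[1]][1], starts[[2]][1],
                                              starts[[3]][1]) - 1 + ctr) * cal,
               spacing = step * cal)
  displacement_field(pts, vecs, valid, qual, grid)
}

# Locate the maximum of a circular correlation volume within +/- maxd voxels.
# Returns integer shift, its array index, and the peak value; NULL if the
# peak lies on the search boundary.
correlation_peak <- function(cc, maxd) {
  d <- dim(cc)
  idx <- lapply(1:3, function(a) {
    sh <- c(0:maxd[a], (d[a] - maxd[a]):(d[a] - 1)) # allowed wrapped indices
    sort(unique(sh %% d[a])) + 1L
  })
  sub <- cc[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  w <- which.max(sub)
  aw <- arrayInd(w, dim(sub))
  pos <- c(idx[[1]][aw[1]], idx[[2]][aw[2]], idx[[3]][aw[3]])
  shift <- ifelse(pos - 1 > d / 2, pos - 1 - d, pos - 1)
  if (any(abs(shift) >= maxd)) return(NULL)
  list(shift = shift, index = pos, value = cc[pos[1], pos[2], pos[3]])
}

#' Subpixel refinement of a correlation peak
#'
#' Refines an integer peak location by a separable three-point fit per axis: a
#' Gaussian fit on log-values when the three samples are positive (exact for
#' Gaussian-shaped peaks), otherwise a parabolic fit. The refinement magnitude
#' is below one voxel per axis by construction.
#'
#' @param cc 3D numeric array (a correlation volume).
#' @param peak Optional integer triple, the peak location (1-based); found by
#'   `which.max` when omitted.
#' @param method `"gaussian"` or `"parabolic"`.
#' @param periodic Treat the volume as circular when picking neighbors.
#' @return List with `offset` (numeric triple, fractional voxels) and `valid`
#'   (`FALSE` when the peak touches a non-periodic boundary).
#' @export
subpixel_peak <- function(cc, peak = NULL,
                          method = c("gaussian", "parabolic"),
                          periodic = FALSE) {
  method <- match.arg(method)
  d <- dim(cc)
  if (is.null(peak)) {
    peak <- arrayInd(which.max(cc), d)[1, ]
  }
  peak <- as.integer(peak)
  if (!periodic && (any(peak == 1L) || any(peak == d)))
    return(list(offset = c(0, 0, 0), valid = FALSE))
  off <- numeric(3)
  for (a in 1:3) {
    im <- peak
    ip <- peak
    im[a] <- if (peak[a] == 1L) d[a] else peak[a] - 1L
    ip[a] <- if (peak[a] == d[a]) 1L else peak[a] + 1L
    c0 <- cc[peak[1], peak[2], peak[3]]
    cm <- cc[im[1], im[2], im[3]]
    cp <- cc[ip[1], ip[2], ip[3]]
    off[a] <- three_point_offset(cm, c0, cp, method)
  }
  list(offset = off, valid = all(abs(off) < 1))
}

three_point_offset <- function(cm, c0, cp, method) {
  if (method == "gaussian" && cm > 0 && c0 > 0 && cp > 0) {
    den <- 2 * (log(cm) + log(cp) - 2 * log(c0))
    if (abs(den) > .Machine$double.eps)
      return((log(cm) - log(cp)) / den)
  }
  den <- 2 * (cm - 2 * c0 + cp)
  if (abs(den) <= .Machine$double.eps) return(0)
  (cm - cp) / den
}

#' Normalized-median outlier validation of a PIV field
#'
#' Applies the universal normalized-median test: each vector is compared
#' component-wise with the median of its grid neighbors; vectors whose
#' normalized residual exceeds `threshold` are flagged invalid and their value
#' replaced by the neighborhood median. Applying the filter to an already
#' clean field changes nothing.
#'
#' @param field A [displacement_field()] with grid layout.
#' @param window Neighborhood radius in grid units (1 = up to 26 neighbors).
#' @param threshold Normalized residual limit; 2 is the conventional choice.
#' @param eps Noise floor (µm) added to the residual normalization.
#' @return The filtered [displacement_field()]; replaced vectors have
#'   `valid = FALSE` but carry the median value.
#' @export
filter_outliers <- function(field, window = 1L, threshold = 2, eps = 0.02) {
  stopifnot(inherits(field, "displacement_field"))
  if (is.null(field$grid)) stop("filter_outliers requires a grid-layout field")
  if (!any(field$valid)) stop("all vectors are invalid")
  dims <- field$grid$dim
  n <- prod(dims)
  stopifnot(n == nrow(field$points))
  arr_id <- arrayInd(seq_len(n), dims)
  offs <- as.matrix(expand.grid(dx = -window:window, dy = -window:window,
                                dz = -window:window))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  neigh_vals <- array(NA_real_, c(n, nrow(offs), 3))
  for (k in seq_len(nrow(offs))) {
    tgt <- sweep(arr_id, 2, offs[k, ], "+")
    ok <- tgt[, 1] >= 1 & tgt[, 1] <= dims[1] &
      tgt[, 2] >= 1 & tgt[, 2] <= dims[2] &
      tgt[, 3] >= 1 & tgt[, 3] <= dims[3]
    lin <- rep(NA_integer_, n)
    lin[ok] <- (tgt[ok, 3] - 1L) * dims[1] * dims[2] +
      (tgt[ok, 2] - 1L) * dims[1] + tgt[ok, 1]
    use <- !is.na(lin) & field$valid[ifelse(is.na(lin), 1L, lin)]
    for (c in 1:3)
      neigh_vals[use, k, c] <- field$vectors[lin[use], c]
  }
  med <- apply(neigh_vals, c(1, 3), stats::median, na.rm = TRUE)
  resid_norm <- matrix(0, n, 3)
  for (c in 1:3) {
    spread <- apply(abs(neigh_vals[, , c] - med[, c]), 1, stats::median,
                    na.rm = TRUE)
    resid_norm[, c] <- abs(field$vectors[, c] - med[, c]) / (spread + eps)
  }
  r <- apply(resid_norm, 1, max)
  out <- field$valid & is.finite(r) & r > threshold & rowSums(is.na(med)) == 0
  res <- field
  res$vectors[out, ] <- med[out, , drop = FALSE]
  res$valid[out] <- FALSE
  res
}

#' Seeding-density diagnostic
#'
#' Estimates the number of tracer particles per interrogation volume. In
#' arithmetic mode (`density` given) it is simply `density * prod(box_size)`:
#' at the saturation density of 0.0005 particles/voxel a 32 x 32 x 8 box holds
#' about four particles. In detection mode, beads are counted as local
#' intensity maxima above background and divided by the number of
#' non-overlapping boxes in the stack.
#'
#' @param stack An [image_stack()]; ignored in arithmetic mode.
#' @param config A [piv_config()].
#' @param density Optional particle density (particles/voxel) for arithmetic
#'   mode.
#' @param threshold_k Detection threshold in robust sds above the median
#'   intensity.
#' @return Estimated particles per interrogation volume (unitless).
#' @export
diagnose_seeding <- function(stack = NULL, config = piv_config(),
                             density = NULL, threshold_k = 8) {
  if (!is.null(density)) return(density * prod(config$box_size))
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$data
  if (length(v) == 0 || all(v == v[1])) return(0)
  thr <- stats::median(v) + threshold_k * max(stats::mad(v), 1e-12)
  n_peaks <- count_local_maxima(v, thr)
  n_boxes <- prod(pmax(dim(v) %/% config$box_size, 1L))
  n_peaks / n_boxes
}

# strict 26-neighborhood local maxima above `thr`
count_local_maxima <- function(v, thr) {
  d <- dim(v)
  if (any(d < 3)) return(sum(v > thr))
  core <- v[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)]
  is_max <- core > thr
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    nb <- v[(2 + dx):(d[1] - 1 + dx), (2 + dy):(d[2] - 1 + dy),
            (2 + dz):(d[3] - 1 + dz)]
    is_max <- is_max & (core >= nb)
    if (!any(is_max)) break
  }
  sum(is_max)
}
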