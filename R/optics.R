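#' Optical parameters of the acquisition
#'
#' Parameters governing the apparent axial compression of confocal stacks when
#' the immersion medium (index `n1`) and the sample (index `n2`) differ: the
#' objective moves by a nominal step `z_step_nominal` but the focal plane moves
#' by a different amount inside the sample.
#'
#' @param na Numerical aperture of the objective; must satisfy
#'   `0 < na < min(n1, n2)`.
#' @param n1 Refractive index of the immersion medium (e.g. 1.47 for glycerin).
#' @param n2 Refractive index of the sample (e.g. 1.34 for hydrogel/medium).
#' @param z_step_nominal Nominal objective z-step (µm), e.g. 0.2.
#' @return An object of class `optical_params`.
#' @export
optical_params <- function(na, n1, n2, z_step_nominal = 0.2) {
  if (!(n1 > 1 && n2 > 1)) stop("refractive indices must exceed 1")
  if (!(na > 0 && na < min(n1, n2)))
    stop("numerical aperture must satisfy 0 < NA < min(n1, n2)")
  if (z_step_nominal <= 0) stop("z_step_nominal must be positive")
  structure(list(na = na, n1 = n1, n2 = n2, z_step_nominal = z_step_nominal),
            class = "optical_params")
}

#' Focal-shift corrected axial step (Visser correction)
#'
#' The true focal-plane step inside the sample for a nominal objective step
#' `Δs` is `Δf = tan(asin(NA/n1)) / tan(asin(NA/n2)) * Δs`. For matched
#' indices `Δf = Δs`; in the paraxial limit (`NA -> 0`) it tends to
#' `(n2/n1) Δs`.
#'
#' @param params An [optical_params()].
#' @return The corrected axial step `Δf` (µm).
#' @examples
#' visser_focal_shift(optical_params(1.2, 1.47, 1.34, 0.2))
#' @export
visser_focal_shift <- function(params) {
  stopifnot(inherits(params, "optical_params"))
  with(params, tan(asin(na / n1)) / tan(asin(na / n2)) * z_step_nominal)
}

#' Rescale a stack's axial coordinates by the Visser correction
#'
#' Applies the focal-shift correction by replacing the nominal z-step (and the
#' z origin measured from the first plane) with the corrected value, so that
#' all downstream geometry and PIV operate in physical µm. This is done before
#' any surface localization or displacement measurement.
#'
#' @param stack An [image_stack()] whose `z_step` equals the nominal step.
#' @param params An [optical_params()].
#' @return The stack with corrected `z_step` (intensities untouched).
#' @export
apply_visser <- function(stack, params) {
  stopifnot(inherits(stack, "image_stack"))
  ratio <- visser_focal_shift(params) / params$z_step_nominal
  stack$origin[3] <- stack$origin[3] * ratio
  stack$z_step <- stack$z_step * ratio
  stack
}

#' Subtract a lensing calibration field from measured displacements
#'
#' Light refracting through the cell body produces apparent bead displacements
#' (hundreds of nm, mostly axial) that are not gel deformation. Given a
#' calibration displacement field quantifying this artifact (e.g. PIV of a
#' control pair, or a model field), the corrected displacement is the measured
#' vector minus the calibration vector at the same point. The validity mask is
#' propagated.
#'
#' @param field Measured [displacement_field()].
#' @param calibration Calibration [displacement_field()]; either point-matched
#'   to `field` or on a regular grid covering all valid points of `field`.
#' @return The corrected [displacement_field()].
#' @export
lensing_correction <- function(field, calibration) {
  stopifnot(inherits(field, "displacement_field"),
            inherits(calibration, "displacement_field"))
  n <- nrow(field$points)
  cal <- matrix(NA_real_, n, 3)
  if (nrow(calibration$points) == n &&
      max(abs(calibration$points - field$points)) < 1e-9) {
    cal <- calibration$vectors
    cal[!calibration$valid, ] <- NA_real_
  } else if (!is.null(calibration$grid)) {
    cal <- grid_interp3(calibration, field$points, extrapolate = FALSE)
  } else {
    stop("calibration must be point-matched to the field or carry a grid")
  }
  need <- field$valid
  uncovered <- need & !stats::complete.cases(cal)
  if (any(uncovered))
    stop("calibration does not cover valid sample point(s): ",
         paste(utils::head(which(uncovered), 10), collapse = ", "))
  out <- field
  out$vectors[need, ] <- field$vectors[need, ] - cal[need, ]
  out
}

# Trilinear interpolation of a grid-layout displacement field at query points.
# Invalid samples poison the cells they touch (result NA there; callers fall
# back to the nearest valid sample, which near masked regions is less biased
# than renormalizing over the remaining corners). Points outside the grid
# hull get NA unless `extrapolate`, in which case nearest-sample values are
# used and attribute "extrapolated" marks them.
grid_interp3 <- function(field, query, extrapolate = TRUE) {
  g <- field$grid
  stopifnot(!is.null(g))
  dims <- g$dim
  vec <- field$vectors
  vec[!field$valid, ] <- NA_real_
  q <- sweep(sweep(as.matrix(query), 2, g$origin, "-"), 2, g$spacing, "/") + 1
  n <- nrow(q)
  out <- matrix(NA_real_, n, 3)
  inb <- q[, 1] >= 1 & q[, 1] <= dims[1] & q[, 2] >= 1 & q[, 2] <= dims[2] &
    q[, 3] >= 1 & q[, 3] <= dims[3]
  lin <- function(i, j, k) (k - 1L) * dims[1] * dims[2] + (j - 1L) * dims[1] + i
  if (any(inb)) {
    qi <- q[inb, , drop = FALSE]
    i0 <- pmin(pmax(floor(qi[, 1]), 1), dims[1] - ifelse(dims[1] > 1, 1, 0))
    j0 <- pmin(pmax(floor(qi[, 2]), 1), dims[2] - ifelse(dims[2] > 1, 1, 0))
    k0 <- pmin(pmax(floor(qi[, 3]), 1), dims[3] - ifelse(dims[3] > 1, 1, 0))
    fx <- qi[, 1] - i0
    fy <- qi[, 2] - j0
    fz <- qi[, 3] - k0
    acc <- matrix(0, sum(inb), 3)
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx == 1) fx else 1 - fx) * (if (dy == 1) fy else 1 - fy) *
        (if (dz == 1) fz else 1 - fz)
      ii <- pmin(i0 + dx, dims[1]); jj <- pmin(j0 + dy, dims[2])
      kk <- pmin(k0 + dz, dims[3])
      acc <- acc + w * vec[lin(ii, jj, kk), , drop = FALSE]
    }
    out[inb, ] <- acc
  }
  extr <- logical(n)
  if (extrapolate && any(!inb)) {
    qc <- q
    qc[, 1] <- pmin(pmax(round(qc[, 1]), 1), dims[1])
    qc[, 2] <- pmin(pmax(round(qc[, 2]), 1), dims[2])
    qc[, 3] <- pmin(pmax(round(qc[, 3]), 1), dims[3])
    out[!inb, ] <- vec[lin(qc[!inb, 1], qc[!inb, 2], qc[!inb, 3]), ,
                       drop = FALSE]
    extr[!inb] <- TRUE
  }
  attr(out, "extrapolated") <- extr
  out
}
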