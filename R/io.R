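#' Read a multi-page TIFF as an image stack
#'
#' Reads a grayscale 8/16-bit (or float) multi-page TIFF into an
#' [image_stack()]. Pages are z-planes; each page's rows are y and columns x,
#' transposed into the package's `[x, y, z]` array convention.
#'
#' @param path TIFF file path.
#' @param pixel_size_xy,z_step Voxel calibration (µm); TIFF rarely carries
#'   trustworthy 3D calibration, so these are explicit.
#' @param origin Physical position of voxel `[1,1,1]` (µm).
#' @return An [image_stack()].
#' @export
read_stack_tiff <- function(path, pixel_size_xy, z_step, origin = c(0, 0, 0)) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1] # drop extra channels
    t(p) # rows = y, cols = x -> [x, y]
  })
  d <- dim(pages[[1]])
  arr <- array(0, c(d[1], d[2], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  image_stack(arr, pixel_size_xy, z_step, origin)
}

#' Write an image stack as a multi-page TIFF
#'
#' Intensities are rescaled to `[0, 1]` (the range stored in the file) unless
#' already within it; 16-bit output.
#'
#' @param stack An [image_stack()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$data
  lo <- min(v); hi <- max(v)
  if (lo < 0 || hi > 1) v <- (v - lo) / max(hi - lo, .Machine$double.eps)
  pages <- lapply(seq_len(dim(v)[3]), function(k) t(v[, , k]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a displacement field as a columnar text file
#'
#' Plain CSV with columns x, y, z (µm), ux, uy, uz (µm), valid (0/1),
#' quality.
#'
#' @param field A [displacement_field()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_displacement_csv <- function(field, path) {
  stopifnot(inherits(field, "displacement_field"))
  df <- data.frame(x = field$points[, 1], y = field$points[, 2],
                   z = field$points[, 3], ux = field$vectors[, 1],
                   uy = field$vectors[, 2], uz = field$vectors[, 3],
                   valid = as.integer(field$valid), quality = field$quality)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a columnar displacement file
#'
#' Inverse of [write_displacement_csv()]. If the points form a regular grid
#' (as PIV output does) the grid layout is reconstructed.
#'
#' @param path CSV path with columns x, y, z, ux, uy, uz and optionally
#'   valid, quality.
#' @return A [displacement_field()].
#' @export
read_displacement_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x", "y", "z", "ux", "uy", "uz")
  if (!all(need %in% names(df)))
    stop("displacement file must have columns ", paste(need, collapse = ", "))
  valid <- if ("valid" %in% names(df)) df$valid > 0 else
    stats::complete.cases(df[, c("ux", "uy", "uz")])
  quality <- if ("quality" %in% names(df)) df$quality else rep(NA_real_, nrow(df))
  pts <- unname(as.matrix(df[, c("x", "y", "z")]))
  vec <- unname(as.matrix(df[, c("ux", "uy", "uz")]))
  displacement_field(pts, vec, valid, quality, detect_grid(pts))
}

# recognize an x-fastest regular grid layout in a point list
detect_grid <- function(p, tol = 1e-6) {
  ax <- lapply(1:3, function(a) sort(unique(round(p[, a], 9))))
  dims <- vapply(ax, length, integer(1))
  if (prod(dims) != nrow(p)) return(NULL)
  sp <- vapply(ax, function(v) if (length(v) > 1) v[2] - v[1] else 1, numeric(1))
  for (a in 1:3) {
    if (length(ax[[a]]) > 2 && max(abs(diff(ax[[a]]) - sp[a])) > tol)
      return(NULL)
  }
  expect <- cbind(rep(ax[[1]], times = dims[2] * dims[3]),
                  rep(rep(ax[[2]], each = dims[1]), times = dims[3]),
                  rep(ax[[3]], each = dims[1] * dims[2]))
  if (max(abs(expect - p)) > tol) return(NULL)
  list(dim = dims, origin = vapply(ax, min, numeric(1)), spacing = sp)
}

#' Export mesh fields as a VTK unstructured grid (VTU)
#'
#' Writes an ASCII VTU file (tetrahedral cells) with any number of per-node
#' vector or scalar fields, readable by Paraview. Units are recorded in the
#' array names (e.g. `traction_Pa`, `displacement_um`).
#'
#' @param mesh A `well_mesh`.
#' @param fields Named list of per-node data: n x 3 matrices (vectors) or
#'   length-n numerics (scalars). Names should carry units.
#' @param path Output path (conventionally `.vtu`).
#' @return The path, invisibly.
#' @export
export_vtk <- function(mesh, fields = list(), path) {
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$tets)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    len <- if (is.matrix(f)) nrow(f) else length(f)
    if (len != n)
      stop(sprintf("field '%s' has %d entries for %d nodes", nm, len, n))
  }
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  num <- function(x) paste(formatC(x, format = "g", digits = 9), collapse = " ")
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid>')
  w(sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m))
  w('<Points>')
  w('<DataArray type="Float32" NumberOfComponents="3" format="ascii">')
  w(num(as.numeric(t(mesh$nodes))))
  w('</DataArray>')
  w('</Points>')
  w('<Cells>')
  w('<DataArray type="Int32" Name="connectivity" format="ascii">')
  w(paste(as.integer(t(mesh$tets)) - 1L, collapse = " "))
  w('</DataArray>')
  w('<DataArray type="Int32" Name="offsets" format="ascii">')
  w(paste(4L * seq_len(m), collapse = " "))
  w('</DataArray>')
  w('<DataArray type="UInt8" Name="types" format="ascii">')
  w(paste(rep(10L, m), collapse = " "))
  w('</DataArray>')
  w('</Cells>')
  w('<PointData>')
  for (nm in names(fields)) {
    f <- fields[[nm]]
    nc <- if (is.matrix(f)) ncol(f) else 1L
    w(sprintf(
      '<DataArray type="Float32" Name="%s" NumberOfComponents="%d" format="ascii">',
      nm, nc))
    w(num(if (is.matrix(f)) as.numeric(t(f)) else as.numeric(f)))
    w('</DataArray>')
  }
  w('</PointData>')
  w('</Piece>')
  w('</UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}

#' Read back a VTU file written by [export_vtk()]
#'
#' Minimal reader for round-trip checks: returns node coordinates,
#' connectivity and the named point-data arrays.
#'
#' @param path VTU path.
#' @return List with `nodes`, `tets`, `fields`.
#' @export
read_vtk <- function(path) {
  if (!requireNamespace("xml2", quietly = TRUE))
    stop("read_vtk requires the xml2 package")
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  getnum <- function(node) as.numeric(strsplit(trimws(xml2::xml_text(node)),
                                               "\\s+")[[1]])
  pts <- getnum(xml2::xml_find_first(piece, ".//Points/DataArray"))
  conn <- getnum(xml2::xml_find_first(
    piece, ".//Cells/DataArray[@Name='connectivity']"))
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  tets <- matrix(as.integer(conn), ncol = 4, byrow = TRUE) + 1L
  fields <- list()
  for (da in xml2::xml_find_all(piece, ".//PointData/DataArray")) {
    nm <- xml2::xml_attr(da, "Name")
    nc <- as.integer(xml2::xml_attr(da, "NumberOfComponents"))
    v <- getnum(da)
    fields[[nm]] <- if (!is.na(nc) && nc > 1)
      matrix(v, ncol = nc, byrow = TRUE) else v
  }
  list(nodes = nodes, tets = tets, fields = fields)
}

#' Write a traction profile as CSV
#' @param profile A `traction_profiles` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "traction_profiles"))
  utils::write.csv(profile$profile, path, row.names = FALSE)
  invisible(path)
}
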