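#' Scan geometry of a 3D OCT volume
#'
#' Describes the sampling grid and physical calibration of a raster-scanned
#' OCT volume. Axis convention throughout the package is `[z, x, y]`:
#' `z` is depth along the A-scan (increasing from the vitreous toward the
#' sclera), `x` the fast axis (A-scans within a B-scan), `y` the slow axis
#' (B-scans). Depth indices are 0-based and depth intervals are half-open
#' `[start, stop)` at every module boundary.
#'
#' @param n_depth Voxels per A-scan (z).
#' @param n_fast A-scans per B-scan (x).
#' @param n_slow Number of B-scans (y).
#' @param field_deg_x,field_deg_y Angular field of view in degrees.
#' @param axial_sampling_um Optical path length per depth voxel in
#'   micrometres. The depth sampling calibration of the instrument is a
#'   run-time input, never hard-coded; the default 3.5 um gives a ~1.8 mm
#'   optical depth range over 512 voxels.
#' @param refractive_index Group refractive index used to convert optical to
#'   anatomical distance (anatomical = optical / refractive_index).
#' @param mm_per_degree Transverse scale in mm per degree of visual angle
#'   (0.289 mm/deg for the emmetropic schematic eye).
#' @param laterality `"right"` or `"left"` eye; controls nasal/temporal
#'   assignment in ETDRS grids.
#'
#' @return An object of class `scan_geometry`.
#' @export
#' @examples
#' g <- scan_geometry()  # 512 x 512 x 512 over a 36 x 36 degree field
#' g$n_slow / g$field_deg_y  # ~14 B-scans per degree
scan_geometry <- function(n_depth = 512L, n_fast = 512L, n_slow = 512L,
                          field_deg_x = 36, field_deg_y = 36,
                          axial_sampling_um = 3.5,
                          refractive_index = 1.4,
                          mm_per_degree = 0.289,
                          laterality = c("right", "left")) {
  laterality <- match.arg(laterality)
  counts <- c(n_depth = n_depth, n_fast = n_fast, n_slow = n_slow)
  if (any(!is.finite(counts)) || any(counts < 8))
    stop("all voxel counts must be finite and >= 8")
  scales <- c(field_deg_x = field_deg_x, field_deg_y = field_deg_y,
              axial_sampling_um = axial_sampling_um,
              mm_per_degree = mm_per_degree)
  if (any(!is.finite(scales)) || any(scales <= 0))
    stop("all physical scales must be finite and > 0")
  if (!is.finite(refractive_index) || refractive_index < 1)
    stop("refractive_index must be >= 1")
  structure(list(n_depth = as.integer(n_depth), n_fast = as.integer(n_fast),
                 n_slow = as.integer(n_slow),
                 field_deg_x = field_deg_x, field_deg_y = field_deg_y,
                 axial_sampling_um = axial_sampling_um,
                 refractive_index = refractive_index,
                 mm_per_degree = mm_per_degree,
                 laterality = laterality),
            class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("scan_geometry: %d x %d x %d voxels [z,x,y], %g x %g deg\n",
              x$n_depth, x$n_fast, x$n_slow, x$field_deg_x, x$field_deg_y))
  cat(sprintf("  axial sampling %g um (optical), n = %g, %g mm/deg, %s eye\n",
              x$axial_sampling_um, x$refractive_index, x$mm_per_degree,
              x$laterality))
  invisible(x)
}

## anatomical depth per voxel, um
axial_um_per_voxel <- function(geometry) {
  geometry$axial_sampling_um / geometry$refractive_index
}

## transverse cell size, mm per A-scan along x / y
transverse_mm_per_voxel <- function(geometry) {
  c(x = geometry$mm_per_degree * geometry$field_deg_x / geometry$n_fast,
    y = geometry$mm_per_degree * geometry$field_deg_y / geometry$n_slow)
}

#' OCT intensity volume
#'
#' Wraps a non-negative 3D intensity array (axis order `[z, x, y]`) with its
#' [scan_geometry()].
#'
#' @param intensity Numeric 3D array of shape `(n_depth, n_fast, n_slow)`.
#' @param geometry A [scan_geometry()].
#' @return An object of class `oct_volume`.
#' @export
oct_volume <- function(intensity, geometry) {
  stopifnot(inherits(geometry, "scan_geometry"))
  d <- dim(intensity)
  want <- c(geometry$n_depth, geometry$n_fast, geometry$n_slow)
  if (length(d) != 3L || any(d != want))
    stop(sprintf("volume shape (%s) does not match geometry (%s)",
                 paste(d, collapse = "x"), paste(want, collapse = "x")))
  if (!is.numeric(intensity)) stop("intensity must be numeric")
  if (any(!is.finite(intensity))) stop("intensity must be finite")
  storage.mode(intensity) <- "double"
  structure(list(intensity = intensity, geometry = geometry),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("oct_volume: %d x %d x %d [z,x,y], intensity range [%.4g, %.4g]\n",
              d[1], d[2], d[3], min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' En-face thickness map
#'
#' A 2D grid of thickness values in micrometres, indexed `[x, y]` (or a tile
#' grid at coarser resolution). Undefined cells are `NA`.
#'
#' @param values Numeric matrix, um; `NA` marks undefined cells.
#' @param mm_per_cell_x,mm_per_cell_y Physical cell size, mm.
#' @param unit Unit label (always micrometres here).
#' @return An object of class `thickness_map`.
#' @export
thickness_map <- function(values, mm_per_cell_x, mm_per_cell_y, unit = "um") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(values < 0, na.rm = TRUE)) stop("defined thickness values must be >= 0")
  stopifnot(mm_per_cell_x > 0, mm_per_cell_y > 0)
  structure(list(values = values, mm_per_cell_x = mm_per_cell_x,
                 mm_per_cell_y = mm_per_cell_y, unit = unit),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  v <- x$values
  cat(sprintf("thickness_map: %d x %d cells (%.4g x %.4g mm), %d defined\n",
              nrow(v), ncol(v), x$mm_per_cell_x, x$mm_per_cell_y,
              sum(is.finite(v))))
  if (any(is.finite(v)))
    cat(sprintf("  mean %.1f %s, range [%.1f, %.1f]\n",
                mean(v, na.rm = TRUE), x$unit, min(v, na.rm = TRUE),
                max(v, na.rm = TRUE)))
  invisible(x)
}

#' Bilinearly upsample a tile-resolution map to a finer grid
#'
#' Used to render per-tile sublayer thickness at A-scan resolution for
#' display and for grid averaging. Tile centres are interpolation nodes;
#' cells outside the convex hull of tile centres take the nearest node value.
#' `NA` tiles propagate to the cells nearest them.
#'
#' @param map A [thickness_map()] at tile resolution.
#' @param nx,ny Target grid size.
#' @return A [thickness_map()] of size `nx` x `ny`.
#' @export
upsample_map <- function(map, nx, ny) {
  v <- map$values
  tx <- nrow(v); ty <- ncol(v)
  ## node coordinates of tile centres on the target grid, in cell units
  sx <- nrow(v) * map$mm_per_cell_x / nx
  sy <- ncol(v) * map$mm_per_cell_y / ny
  cx <- ((seq_len(tx) - 0.5) * map$mm_per_cell_x)
  cy <- ((seq_len(ty) - 0.5) * map$mm_per_cell_y)
  px <- (seq_len(nx) - 0.5) * sx
  py <- (seq_len(ny) - 0.5) * sy
  ix <- findInterval(px, cx, all.inside = TRUE)  # left node
  iy <- findInterval(py, cy, all.inside = TRUE)
  fx <- pmin(1, pmax(0, (px - cx[ix]) / (cx[pmin(ix + 1, tx)] - cx[ix] + 1e-12)))
  fy <- pmin(1, pmax(0, (py - cy[iy]) / (cy[pmin(iy + 1, ty)] - cy[iy] + 1e-12)))
  ix2 <- pmin(ix + 1L, tx); iy2 <- pmin(iy + 1L, ty)
  out <- matrix(NA_real_, nx, ny)
  FX <- matrix(fx, nx, ny); FY <- matrix(fy, nx, ny, byrow = TRUE)
  V11 <- v[cbind(rep(ix, ny), rep(iy, each = nx))]
  V21 <- v[cbind(rep(ix2, ny), rep(iy, each = nx))]
  V12 <- v[cbind(rep(ix, ny), rep(iy2, each = nx))]
  V22 <- v[cbind(rep(ix2, ny), rep(iy2, each = nx))]
  out[] <- (1 - FX) * (1 - FY) * V11 + FX * (1 - FY) * V21 +
    (1 - FX) * FY * V12 + FX * FY * V22
  thickness_map(out, sx, sy, unit = map$unit)
}
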