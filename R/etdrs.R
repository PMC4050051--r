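## ETDRS-style macular grid averaging. The grid is a central disc, an inner
## and an outer annulus, the rings split into four quadrants by the +/-45
## degree diagonals. The central disc here is 1.5 mm in diameter (the
## central submacular field, CSM) and the outer disc 6 mm (the total macular
## field); the 3 mm inner-ring diameter follows the standard ETDRS layout.

etdrs_fields <- c("central",
                  "inner_superior", "inner_nasal", "inner_inferior",
                  "inner_temporal",
                  "outer_superior", "outer_nasal", "outer_inferior",
                  "outer_temporal")

#' Build an ETDRS grid for a thickness map
#'
#' Cell (1, 1) is the superior-temporal corner for a right eye; the x axis
#' (rows of the map) is horizontal with nasal at increasing x for a right
#' eye, flipped for a left eye. Quadrants are bounded by the +/-45 degree
#' diagonals (cells exactly on a diagonal join the horizontal quadrants).
#'
#' @param nx,ny Map size in cells.
#' @param mm_per_cell_x,mm_per_cell_y Cell size, mm.
#' @param center Grid centre in cell units (`c(x, y)`, 1-based, fractional
#'   allowed); defaults to the map centre.
#' @param laterality `"right"` or `"left"`.
#' @param diameters_mm Central disc, inner-ring and outer-ring diameters,
#'   strictly increasing.
#' @return An `etdrs_grid`: a named list of nine disjoint logical masks
#'   whose union is the outer disc, plus the geometry metadata.
#' @export
etdrs_grid <- function(nx, ny, mm_per_cell_x, mm_per_cell_y, center = NULL,
                       laterality = c("right", "left"),
                       diameters_mm = c(1.5, 3, 6)) {
  laterality <- match.arg(laterality)
  if (length(diameters_mm) != 3 || any(diff(diameters_mm) <= 0))
    stop("diameters must be strictly increasing (central < inner < outer)")
  if (is.null(center)) center <- c((nx + 1) / 2, (ny + 1) / 2)
  r <- diameters_mm / 2
  ## distance of the disc rim from the field edges
  cx_mm <- (center[1] - 0.5) * mm_per_cell_x
  cy_mm <- (center[2] - 0.5) * mm_per_cell_y
  ext_x <- nx * mm_per_cell_x; ext_y <- ny * mm_per_cell_y
  if (cx_mm - r[3] < -mm_per_cell_x / 2 || cx_mm + r[3] > ext_x + mm_per_cell_x / 2 ||
      cy_mm - r[3] < -mm_per_cell_y / 2 || cy_mm + r[3] > ext_y + mm_per_cell_y / 2)
    stop(sprintf("outer disc (%g mm) exceeds the mapped field (%.2f x %.2f mm)",
                 diameters_mm[3], ext_x, ext_y))
  dx <- ((seq_len(nx) - center[1]) * mm_per_cell_x)
  dy <- ((seq_len(ny) - center[2]) * mm_per_cell_y)
  DX <- matrix(dx, nx, ny)
  DY <- matrix(dy, nx, ny, byrow = TRUE)
  RR <- sqrt(DX^2 + DY^2)
  horizontal <- abs(DX) >= abs(DY)
  nasal_side <- if (laterality == "right") DX > 0 else DX < 0
  superior <- DY < 0
  masks <- list()
  masks$central <- RR <= r[1]
  for (ring in c("inner", "outer")) {
    ann <- if (ring == "inner") RR > r[1] & RR <= r[2] else RR > r[2] & RR <= r[3]
    masks[[paste0(ring, "_superior")]] <- ann & !horizontal & superior
    masks[[paste0(ring, "_inferior")]] <- ann & !horizontal & !superior
    masks[[paste0(ring, "_nasal")]] <- ann & horizontal & nasal_side
    masks[[paste0(ring, "_temporal")]] <- ann & horizontal & !nasal_side
  }
  structure(list(masks = masks[etdrs_fields], center = center,
                 laterality = laterality, diameters_mm = diameters_mm,
                 mm_per_cell_x = mm_per_cell_x, mm_per_cell_y = mm_per_cell_y),
            class = "etdrs_grid")
}

#' @export
print.etdrs_grid <- function(x, ...) {
  cat(sprintf("etdrs_grid: diameters %s mm, %s eye, %d cells in outer disc\n",
              paste(x$diameters_mm, collapse = "/"), x$laterality,
              sum(Reduce(`|`, x$masks))))
  invisible(x)
}

#' Build an ETDRS grid matching a thickness map
#'
#' @param map A [thickness_map()].
#' @param ... Passed to [etdrs_grid()].
#' @return An `etdrs_grid`.
#' @export
etdrs_grid_for_map <- function(map, ...) {
  etdrs_grid(nrow(map$values), ncol(map$values),
             map$mm_per_cell_x, map$mm_per_cell_y, ...)
}

#' Average a thickness map over the ETDRS subfields
#'
#' Per-subfield mean and SD over defined cells; a subfield with more than
#' 50% missing cells is reported missing. The central submacular field (CSM)
#' equals the central-subfield entry; the total macular field is the mean
#' over the whole outer disc.
#'
#' @param map A [thickness_map()] co-registered with the grid.
#' @param grid An `etdrs_grid`.
#' @return An `etdrs_summary` data frame with columns `field`, `mean`, `sd`,
#'   `n_defined`, `n_cells`, including rows `csm` (alias of `central`) and
#'   `total` (whole disc).
#' @export
subfield_means <- function(map, grid) {
  stopifnot(inherits(map, "thickness_map"), inherits(grid, "etdrs_grid"))
  if (!all(dim(map$values) == dim(grid$masks$central)))
    stop("map and grid are not co-registered")
  one <- function(mask) {
    v <- map$values[mask]
    n <- length(v); nd <- sum(is.finite(v))
    if (n == 0 || nd <= n / 2) return(c(NA_real_, NA_real_, nd, n))
    c(mean(v, na.rm = TRUE), sd(v, na.rm = TRUE), nd, n)
  }
  rows <- lapply(grid$masks, one)
  disc <- Reduce(`|`, grid$masks)
  rows$csm <- rows$central
  rows$total <- one(disc)
  out <- data.frame(field = names(rows),
                    mean = vapply(rows, `[`, 0, 1),
                    sd = vapply(rows, `[`, 0, 2),
                    n_defined = as.integer(vapply(rows, `[`, 0, 3)),
                    n_cells = as.integer(vapply(rows, `[`, 0, 4)),
                    row.names = NULL)
  class(out) <- c("etdrs_summary", "data.frame")
  out
}

#' @export
print.etdrs_summary <- function(x, digits = 1, ...) {
  cat("ETDRS subfield thickness (um):\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-15s %s\n", x$field[i],
                if (is.na(x$mean[i])) "missing"
                else sprintf("%.*f +/- %.*f (n=%d)", digits, x$mean[i],
                             digits, x$sd[i], x$n_defined[i])))
  invisible(x)
}
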