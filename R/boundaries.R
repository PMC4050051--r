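## Detection of the RBC complex and the choroidal-scleral interface (CSI),
## and derivation of the choroid region and total choroidal thickness.
##
## Interface evidence is built on a transversely smoothed copy of the volume
## (wide boxcar): individual vessel walls are local in x/y and average away,
## while the two interfaces extend across the whole field and survive. The
## per-B-scan dynamic program then extracts a path maximizing evidence minus
## a per-column jump penalty.

## mean box blur of a matrix with radius r (edge windows renormalized)
boxblur_mat <- function(m, r) {
  if (r <= 0) return(m)
  n <- nrow(m)
  p <- ncol(m)
  blur1 <- function(mm, r) {      # along rows (dim 1)
    cs <- apply(mm, 2, cumsum)
    idx <- seq_len(nrow(mm))
    hi <- pmin(idx + r, nrow(mm))
    lo <- pmax(idx - r, 1L)
    tot <- cs[hi, , drop = FALSE] -
      rbind(0, cs)[lo, , drop = FALSE]
    tot / (hi - lo + 1L)
  }
  t(blur1(t(blur1(m, r)), r))
}

## axial window means via cumulative sums: for each z, mean over
## [z + lo, z + hi] (clipped to the volume)
axial_window_mean <- function(M, lo, hi) {
  nz <- nrow(M)
  cs <- apply(M, 2, cumsum)
  cs <- rbind(0, cs)
  zlo <- pmax(seq_len(nz) + lo, 1L)
  zhi <- pmin(seq_len(nz) + hi, nz)
  bad <- zhi < zlo
  zhi2 <- pmax(zhi, zlo)
  out <- (cs[zhi2 + 1L, , drop = FALSE] - cs[zlo, , drop = FALSE]) /
    (zhi2 - zlo + 1L)
  if (any(bad)) out[bad, ] <- NA_real_
  out
}

#' Detect a choroidal boundary surface
#'
#' Per B-scan, a dynamic-programming shortest path maximizes interface
#' evidence minus `lambda` per voxel of depth jump between adjacent A-scans.
#' Evidence is a signed axial contrast on a transversely smoothed volume:
#' dark-above-bright for the RBC complex (transition into the hyperintense
#' choroidal band), bright-above-dark with a long dark tail below for the
#' CSI. A volume with no axial contrast yields an all-zero-confidence result
#' (flagged in the log), not an error.
#'
#' @param vol An [oct_volume()] (ideally denoised; see [denoise()]).
#' @param which `"rbc"` or `"csi"`.
#' @param lambda Smoothness penalty per voxel of depth jump between adjacent
#'   A-scans, in units of normalized evidence (evidence is scaled to max 1
#'   per B-scan). `Inf` forces a flat surface per B-scan.
#' @param smooth_xy Transverse boxcar radius (voxels) for evidence
#'   construction.
#' @return A `surface_map`: 0-based integer depth per A-scan (`[x, y]`),
#'   per-A-scan confidence in `[0, 1]`, and the surface name.
#' @export
detect_surface <- function(vol, which = c("rbc", "csi"), lambda = 2,
                           smooth_xy = 7L) {
  which <- match.arg(which)
  g <- vol$geometry
  nz <- g$n_depth; nx <- g$n_fast; ny <- g$n_slow
  depth <- matrix(0L, nx, ny)
  conf <- matrix(0, nx, ny)
  ## log intensity: depth attenuation is multiplicative, so interface
  ## contrast is depth-invariant in the log domain, and residual vessel
  ## ridges compress relative to the full tissue/background contrast
  L <- log(vol$intensity + 1e-3 * max(vol$intensity))
  wide <- 14L  # transverse radius of the brightness-envelope max
  for (j in seq_len(ny)) {
    ## narrow transverse smoothing localizes the interface
    jlo <- max(1L, j - smooth_xy); jhi <- min(ny, j + smooth_xy)
    plane <- rowMeans(L[, , jlo:jhi, drop = FALSE], dims = 2)
    plane <- t(boxblur_mat(t(plane), smooth_xy))
    ## transverse brightness envelope: the per-depth maximum over a wide
    ## neighbourhood of B-scans. Below a vessel - even a large tube lying
    ## along the B-scan - bright stroma persists somewhere in the
    ## neighbourhood; below the true interface (into the sclera, or above
    ## the RBC complex in the vitreous/retina band of this contrast model)
    ## nothing is bright anywhere.
    ## keep the full window span at the volume edges (slide inward)
    jlo_w <- max(1L, min(j - wide, ny - 2L * wide))
    jhi_w <- min(ny, max(j + wide, 1L + 2L * wide))
    env <- L[, , jlo_w]
    if (jhi_w > jlo_w)
      for (jj in (jlo_w + 1L):jhi_w) env <- pmax(env, L[, , jj])
    env <- t(boxblur_mat(t(env), 1L))
    ## two-term evidence: short-window edge contrast plus sustained
    ## far-side darkness of the brightness envelope
    if (which == "rbc") {
      below <- axial_window_mean(plane, 0L, 3L)
      ev <- (below - axial_window_mean(plane, -8L, -1L)) +
        (axial_window_mean(env, 0L, 3L) -
         axial_window_mean(env, -48L, -1L))
    } else {
      above <- axial_window_mean(plane, -4L, -1L)
      ev <- (above - axial_window_mean(plane, 0L, 7L)) +
        (axial_window_mean(env, -4L, -1L) -
         axial_window_mean(env, 0L, 47L))
    }
    ev[is.na(ev)] <- 0
    emax <- max(ev)
    if (emax <= 0) {
      depth[, j] <- nz %/% 2L
      conf[, j] <- 0
      next
    }
    ev <- ev / emax
    if (is.infinite(lambda)) {
      z <- which.max(rowSums(ev))
      depth[, j] <- z - 1L
      conf[, j] <- pmax(0, pmin(1, ev[z, ]))
      next
    }
    ## DP: cost-to-come C[z, x]; |dz| transition via two cummin passes
    C <- matrix(0, nz, nx)
    C[, 1] <- -ev[, 1]
    lam_z <- lambda * seq_len(nz)
    for (x in 2:nx) {
      prev <- C[, x - 1L]
      m1 <- cummin(prev - lam_z) + lam_z
      m2 <- rev(cummin(rev(prev + lam_z))) - lam_z
      C[, x] <- pmin(m1, m2) - ev[, x]
    }
    ## backtrack
    path <- integer(nx)
    path[nx] <- which.min(C[, nx])
    for (x in (nx - 1L):1L) {
      trans <- C[, x] + lambda * abs(seq_len(nz) - path[x + 1L])
      path[x] <- which.min(trans)
    }
    ## per-column refinement: snap to the strongest local edge within +/-3
    ## voxels of the DP path, measured without transverse smoothing (the
    ## wide boxcar smears the interface by a voxel or two on curved
    ## surfaces)
    jl <- max(1L, j - 1L); jh <- min(ny, j + 1L)
    raw <- rowMeans(L[, , jl:jh, drop = FALSE], dims = 2)
    eloc <- if (which == "rbc") {
      axial_window_mean(raw, 0L, 2L) - axial_window_mean(raw, -3L, -1L)
    } else {
      axial_window_mean(raw, -3L, -1L) - axial_window_mean(raw, 0L, 2L)
    }
    eloc[is.na(eloc)] <- 0
    for (x in seq_len(nx)) {
      zwin <- max(1L, path[x] - 3L):min(nz, path[x] + 3L)
      path[x] <- zwin[which.max(eloc[zwin, x])]
    }
    depth[, j] <- path - 1L
    conf[, j] <- pmax(0, pmin(1, ev[cbind(path, seq_len(nx))]))
  }
  if (all(conf == 0))
    cl_log("detect_surface(%s): no axial contrast, all-zero confidence", which)
  structure(list(depth = depth, name = which, confidence = conf),
            class = "surface_map")
}

#' Construct a surface map directly
#'
#' @param depth Integer matrix `[x, y]` of 0-based depth indices.
#' @param name `"rbc"` or `"csi"`.
#' @param confidence Per-A-scan confidence in `[0, 1]`.
#' @return A `surface_map`.
#' @export
surface_map <- function(depth, name = c("rbc", "csi"),
                        confidence = matrix(1, nrow(depth), ncol(depth))) {
  name <- match.arg(name)
  depth <- as.matrix(depth)
  structure(list(depth = depth, name = name, confidence = confidence),
            class = "surface_map")
}

#' @export
print.surface_map <- function(x, ...) {
  cat(sprintf("surface_map '%s': %d x %d A-scans, depth range [%d, %d], mean confidence %.2f\n",
              x$name, nrow(x$depth), ncol(x$depth), min(x$depth), max(x$depth),
              mean(x$confidence)))
  invisible(x)
}

#' Combine two surfaces into the choroid region
#'
#' The region is the half-open depth interval `[ceil(rbc), floor(csi))` per
#' A-scan. A-scans where the surfaces cross (`rbc > csi`) are marked
#' undefined and counted in the log; zero-length intervals remain defined.
#'
#' @param rbc,csi `surface_map`s on the same grid.
#' @return A `choroid_region` with integer matrices `rbc`, `csi` and a
#'   logical matrix `defined`.
#' @export
choroid_region <- function(rbc, csi) {
  stopifnot(inherits(rbc, "surface_map"), inherits(csi, "surface_map"))
  if (!all(dim(rbc$depth) == dim(csi$depth)))
    stop("surface grids do not match")
  lo <- ceiling(rbc$depth)
  hi <- floor(csi$depth)
  bad <- lo > hi
  if (any(bad))
    cl_log("choroid_region: %d A-scan(s) with rbc > csi marked undefined",
           sum(bad))
  structure(list(rbc = lo, csi = hi, defined = !bad),
            class = "choroid_region")
}

#' @export
print.choroid_region <- function(x, ...) {
  len <- (x$csi - x$rbc)[x$defined]
  cat(sprintf("choroid_region: %d x %d A-scans, %d defined, depth %0.1f +/- %0.1f voxels\n",
              nrow(x$rbc), ncol(x$rbc), sum(x$defined), mean(len), sd(len)))
  invisible(x)
}

## choroid region taken directly from phantom ground truth: first choroidal
## voxel is ceil(rbc), first scleral voxel is ceil(csi), matching the
## phantom's rendering rule (stroma where rbc <= z < csi)
true_region <- function(truth) {
  choroid_region(surface_map(ceiling(truth$rbc_surface), "rbc"),
                 surface_map(ceiling(truth$csi_surface), "csi"))
}

#' Total choroidal thickness map
#'
#' Thickness is the interval length in voxels converted to optical distance
#' using the axial sampling and further to anatomical distance by dividing
#' by the refractive index.
#'
#' @param region A `choroid_region`.
#' @param geometry The [scan_geometry()] of the source volume.
#' @return A [thickness_map()] at A-scan resolution (um).
#' @export
choroid_thickness_map <- function(region, geometry) {
  stopifnot(inherits(region, "choroid_region"))
  len <- pmax(region$csi - region$rbc, 0)
  um <- len * axial_um_per_voxel(geometry)
  um[!region$defined] <- NA_real_
  tmm <- transverse_mm_per_voxel(geometry)
  thickness_map(um, tmm["x"], tmm["y"])
}
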