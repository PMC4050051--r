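## Haller's/Sattler's layer separation from volume-to-surface voxel-ratio
## depth profiles. Within each 1 x 1 degree tile, segmented vessel voxels are
## binned by their depth above the scleral boundary (flattening to the local
## CSI); the per-bin ratio of vessel voxels to vessel-surface voxels is
## large where large-caliber vessels dominate (interiors outnumber walls)
## and near 1 for small vessels. Haller's layer runs from the scleral
## boundary through the ratio maximum to the first valley of the smoothed
## profile; Sattler's layer continues until the profile hits the noise floor
## or runs out of vessels.

#' Partition the field into 1 x 1 degree tiles
#'
#' Tiles are `floor(field/tile_deg)` per axis with `floor(n/n_tiles)` A-scans
#' each; remainder A-scans are assigned to the edge tiles. With the default
#' 512-A-scan, 36-degree geometry this gives 36 x 36 tiles of 14 B-scans.
#'
#' @param geometry A [scan_geometry()].
#' @param tile_deg Tile size in degrees (> 0).
#' @return A `tiling`: index vectors `tile_of_x`, `tile_of_y` (tile id per
#'   A-scan) and counts `n_tiles_x`, `n_tiles_y`.
#' @export
tile_volume <- function(geometry, tile_deg = 1) {
  if (tile_deg <= 0) stop("tile_deg must be > 0")
  axis_tiles <- function(n, field) {
    nt <- max(1L, floor(field / tile_deg))
    w <- n %/% nt
    rem <- n - nt * w
    ## remainder split between the two edge tiles
    sizes <- rep(w, nt)
    sizes[1] <- sizes[1] + rem %/% 2
    sizes[nt] <- sizes[nt] + rem - rem %/% 2
    rep(seq_len(nt), times = sizes)
  }
  structure(list(tile_of_x = axis_tiles(geometry$n_fast, geometry$field_deg_x),
                 tile_of_y = axis_tiles(geometry$n_slow, geometry$field_deg_y),
                 n_tiles_x = max(1L, floor(geometry$field_deg_x / tile_deg)),
                 n_tiles_y = max(1L, floor(geometry$field_deg_y / tile_deg))),
            class = "tiling")
}

## centered moving average over the defined bins. Isolated undefined bins
## (speckle fragmentation holes) are bridged when at least two window values
## are defined; longer undefined runs - in particular the terminal no-vessel
## run - stay undefined.
smooth_profile <- function(r, w) {
  if (w <= 1) return(r)
  stopifnot(w %% 2 == 1)
  h <- (w - 1L) / 2L
  n <- length(r)
  out <- rep(NA_real_, n)
  for (b in seq_len(n)) {
    win <- r[max(1L, b - h):min(n, b + h)]
    if (sum(!is.na(win)) >= 2L || (!is.na(r[b]) && any(!is.na(win))))
      out[b] <- mean(win, na.rm = TRUE)
  }
  out
}

#' Volume/surface voxel-ratio depth profile of one tile
#'
#' Each vessel voxel in the tile is assigned a depth-from-sclera bin
#' `b = (csi - 1) - z` (voxels above the deepest choroidal voxel of its
#' A-scan, increasing anteriorly). `ratio(b)` is the number of vessel voxels
#' in bin `b` divided by the number of vessel *surface* voxels (6-neighbour
#' rule, computed on the whole mask) in bin `b`; bins with no surface voxels
#' are undefined. The profile is smoothed with an NA-preserving moving
#' average of width `smooth_w`.
#'
#' @param vm A `vessel_mask` (labelled, noise-filtered).
#' @param region A `choroid_region`.
#' @param tiling A `tiling` from [tile_volume()].
#' @param tile Integer pair `(i, j)`: tile indices along x and y.
#' @param smooth_w Odd moving-average width in bins.
#' @return A `ratio_profile`: `depth_bins` (0-based), `ratio`, `smoothed`,
#'   and the raw counts `n_volume`, `n_surface`.
#' @export
ratio_profile <- function(vm, region, tiling, tile, smooth_w = 5L) {
  stopifnot(inherits(vm, "vessel_mask"), inherits(region, "choroid_region"))
  xs <- which(tiling$tile_of_x == tile[1])
  ys <- which(tiling$tile_of_y == tile[2])
  if (!length(xs) || !length(ys)) stop("tile out of range")
  ok <- region$defined[xs, ys, drop = FALSE]
  depth <- (region$csi - region$rbc)[xs, ys, drop = FALSE]
  if (!any(ok) || max(depth[ok]) <= 0) stop("empty tile region")
  nbins <- max(depth[ok])
  nz <- dim(vm$mask)[1]
  sub_m <- vm$mask[, xs, ys, drop = FALSE]
  sub_s <- vm$surface[, xs, ys, drop = FALSE]
  csi_sub <- region$csi[xs, ys, drop = FALSE]
  ## bin of every voxel in the tile block: (csi - 1) - z, 0-based
  zvals <- seq_len(nz) - 1L
  bin <- outer(zvals, as.vector(csi_sub - 1L), function(z, c) c - z)
  okv <- rep(as.vector(ok), each = nz)
  use_v <- as.vector(sub_m) & okv & bin >= 0 & bin < nbins
  use_s <- as.vector(sub_s) & okv & bin >= 0 & bin < nbins
  n_vol <- tabulate(bin[use_v] + 1L, nbins)
  n_surf <- tabulate(bin[use_s] + 1L, nbins)
  ratio <- ifelse(n_surf > 0, n_vol / n_surf, NA_real_)
  structure(list(tile = tile, depth_bins = 0:(nbins - 1L), ratio = ratio,
                 smoothed = smooth_profile(ratio, smooth_w),
                 n_volume = n_vol, n_surface = n_surf),
            class = "ratio_profile")
}

#' @export
print.ratio_profile <- function(x, ...) {
  cat(sprintf("ratio_profile tile (%d, %d): %d bins, %d defined, max ratio %.2f\n",
              x$tile[1], x$tile[2], length(x$ratio), sum(!is.na(x$ratio)),
              suppressWarnings(max(x$ratio, na.rm = TRUE))))
  invisible(x)
}

#' Locate the sublayer borders on one ratio profile
#'
#' Implements the valley rule: Haller's layer starts at the scleral boundary
#' and includes the highest voxel ratio; the first valley of the smoothed
#' profile anterior to the global maximum marks the Haller/Sattler border;
#' Sattler's inner border is the first bin, continuing anteriorly, that is
#' undefined or falls below `noise_floor` (no vessels, or noise). A profile
#' that hits the noise floor or runs out of defined bins before any valley
#' yields a zero-thickness Sattler's layer (`haller_sattler ==
#' sattler_inner`). Valley ties resolve to the most posterior tying bin.
#'
#' @param p A `ratio_profile` (smoothed).
#' @param noise_floor Ratio value treated as no-vessel noise.
#' @param prominence Minimum rise above a running minimum for the minimum to
#'   count as a valley; guards the discrete valley against counting noise on
#'   near-flat stretches of the profile.
#' @param tie_tol Values within `tie_tol` of the running minimum count as
#'   ties and keep the posterior (sclera-side) bin, so broad flat valleys
#'   resolve to their posterior edge.
#' @return List `haller_sattler`, `sattler_inner` (0-based depth bins) and
#'   `defined` (FALSE when the profile holds no defined bins).
#' @export
find_borders <- function(p, noise_floor = 1.05, prominence = 0.25,
                         tie_tol = 0.1) {
  s <- p$smoothed
  B <- length(s)
  def <- which(!is.na(s))
  if (!length(def))
    return(list(haller_sattler = NA_real_, sattler_inner = NA_real_,
                defined = FALSE))
  m <- def[which.max(s[def])]
  ## Haller's layer anchors at the highest ratio reached from the scleral
  ## boundary. When a comparable peak lies posterior to the global maximum
  ## with a deep valley between them, the posterior peak is the Haller mass
  ## and the anterior one belongs to Sattler's layer: the border is that
  ## valley.
  if (m > min(def) + 1L) {
    rmax <- -Inf; rmax_at <- NA_integer_
    best_v <- Inf; best_pk <- NA_integer_
    for (b in def[def < m]) {
      if (s[b] > rmax) { rmax <- s[b]; rmax_at <- b }
      if (rmax >= 0.8 * s[m] && s[b] < best_v) {
        best_v <- s[b]; best_pk <- rmax_at
      }
    }
    if (!is.na(best_pk) && best_v <= 0.55 * s[best_pk])
      m <- best_pk
  }
  border <- NA_integer_
  cur_min <- Inf
  cur_min_at <- NA_integer_
  ## level below which the flat-slope fallback may fire: near the profile
  ## floor, so it acts only on terminal declines that never rise again
  smin <- min(s[def])
  halfway <- smin + 0.2 * (s[m] - smin)
  b <- m + 1L
  degenerate <- FALSE
  while (b <= B) {
    if (is.na(s[b])) {  # degenerate: no vessels left
      border <- b
      degenerate <- TRUE
      break
    }
    ## thresholds scale with the local ratio level: wiggles on a high
    ## plateau are counting noise, the same absolute rise near ratio 1 is a
    ## real caliber transition
    tie_b <- if (is.finite(cur_min)) max(tie_tol, 0.05 * cur_min) else 0
    prom_b <- max(prominence,
                  0.15 * if (is.finite(cur_min)) cur_min else 0)
    if (s[b] < cur_min - tie_b) { cur_min <- s[b]; cur_min_at <- b }
    else if (s[b] >= cur_min + prom_b) { border <- cur_min_at; break }
    ## "first small ratio" fallback: descent has levelled off (two
    ## consecutive near-flat steps past the halfway level) without a valley
    slope_tol <- 0.1
    if (b > m + 2L && s[b] <= halfway && !is.na(s[b - 2L]) &&
        abs(s[b - 1L] - s[b]) < slope_tol &&
        abs(s[b - 2L] - s[b - 1L]) < slope_tol) { border <- b - 2L; break }
    b <- b + 1L
  }
  if (is.na(border)) {  # profile declined to its end without a valley
    border <- B + 1L
    degenerate <- TRUE
  }
  ## the border is where the descent first reaches the small-ratio level,
  ## not the dip floor itself: walk back to the most posterior bin already
  ## within `prominence` of the stopping level
  if (!degenerate && border <= B && !is.na(s[border])) {
    lvl <- s[border] + max(prominence, 0.15 * s[border]) / 2
    while (border > m + 1L && !is.na(s[border - 1L]) && s[border - 1L] <= lvl)
      border <- border - 1L
  }
  ## Sattler's inner border: continue anteriorly to the first bin that is
  ## undefined or below the noise floor. The scan starts at the anterior
  ## edge of the border valley, so a valley that itself dips below the
  ## floor does not zero out the layer above it.
  inner <- border
  if (!degenerate)
    while (inner <= B && !is.na(s[inner]) && s[inner] < noise_floor)
      inner <- inner + 1L
  while (inner <= B && !is.na(s[inner]) && s[inner] >= noise_floor)
    inner <- inner + 1L
  ## 1-based array index -> 0-based depth bin
  list(haller_sattler = border - 1L, sattler_inner = inner - 1L,
       defined = TRUE)
}

#' Sublayer borders for every tile
#'
#' Runs [ratio_profile()] and [find_borders()] over the whole tiling. Tiles
#' with empty regions or all-undefined profiles are marked missing and
#' counted in the log.
#'
#' @param vm A `vessel_mask`.
#' @param region A `choroid_region`.
#' @param tiling A `tiling`.
#' @param smooth_w,noise_floor,prominence See [ratio_profile()] and
#'   [find_borders()].
#' @return A `sublayer_borders`: matrices `haller_sattler`, `sattler_inner`
#'   (0-based bins, `NA` where missing) and `defined`, plus the profiles.
#' @export
sublayer_borders <- function(vm, region, tiling, smooth_w = 5L,
                             noise_floor = 1.05, prominence = 0.25) {
  nt_x <- tiling$n_tiles_x; nt_y <- tiling$n_tiles_y
  hs <- matrix(NA_real_, nt_x, nt_y)
  si <- matrix(NA_real_, nt_x, nt_y)
  profiles <- vector("list", nt_x * nt_y)
  for (tj in seq_len(nt_y))
    for (ti in seq_len(nt_x)) {
      p <- tryCatch(ratio_profile(vm, region, tiling, c(ti, tj), smooth_w),
                    error = function(e) NULL)
      profiles[[ti + nt_x * (tj - 1L)]] <- p
      if (is.null(p)) next
      b <- find_borders(p, noise_floor, prominence)
      if (b$defined) {
        hs[ti, tj] <- b$haller_sattler
        si[ti, tj] <- b$sattler_inner
      }
    }
  n_missing <- sum(is.na(hs))
  if (n_missing)
    cl_log("sublayer_borders: %d of %d tiles undefined", n_missing,
           nt_x * nt_y)
  structure(list(haller_sattler = hs, sattler_inner = si,
                 defined = !is.na(hs), profiles = profiles,
                 tiling = tiling),
            class = "sublayer_borders")
}

#' Convert sublayer borders to thickness maps
#'
#' Haller's thickness is the border depth; Sattler's is the span between the
#' border and the inner border; both converted from voxels to anatomical
#' micrometres.
#'
#' @param borders A `sublayer_borders`.
#' @param geometry The source [scan_geometry()].
#' @return List of tile-resolution [thickness_map()]s `sattler` and
#'   `haller`.
#' @export
borders_to_thickness <- function(borders, geometry) {
  axu <- axial_um_per_voxel(geometry)
  tiling <- borders$tiling
  tmm <- transverse_mm_per_voxel(geometry)
  mmx <- tmm["x"] * geometry$n_fast / tiling$n_tiles_x
  mmy <- tmm["y"] * geometry$n_slow / tiling$n_tiles_y
  haller <- borders$haller_sattler * axu
  sattler <- (borders$sattler_inner - borders$haller_sattler) * axu
  list(sattler = thickness_map(sattler, mmx, mmy),
       haller = thickness_map(haller, mmx, mmy))
}
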