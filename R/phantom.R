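## Synthetic 1060-nm OCT choroid phantom with voxel-level ground truth.
##
## The phantom emulates the anatomy the segmentation relies on: a hyperintense
## choroidal stroma bounded by two smooth surfaces (the RBC complex above, the
## choroidal-scleral interface below), hyporeflective tubular vessels in two
## caliber populations stratified by depth (large posterior = Haller's,
## medium/small anterior = Sattler's), depth-dependent signal attenuation and
## multiplicative speckle. Haller tubes are placed so that their anterior
## (top) surfaces cluster at a target depth: anatomically the Haller/Sattler
## boundary is the anterior limit of the large-caliber vasculature, so the
## phantom realizes that limit as a depth with small per-tube jitter.

## evaluate code under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(as.integer(seed))
  code
}

#' Scan geometry of the demonstration phantom
#'
#' A 256 x 128 x 128 voxel volume over a 6 x 6 degree field with 7 um optical
#' depth sampling. The field is narrower than a full 36-degree macular raster
#' so that, at 128 A-scans, the transverse sampling (~13.5 um) still resolves
#' Sattler-caliber vessels while the 1.5 mm central submacular disc fits
#' inside the mapped area.
#'
#' @param n_depth,n_fast,n_slow Voxel counts.
#' @param field_deg Angular field (degrees, square).
#' @return A [scan_geometry()].
#' @export
phantom_geometry <- function(n_depth = 256L, n_fast = 128L, n_slow = 128L,
                             field_deg = 6) {
  scan_geometry(n_depth, n_fast, n_slow, field_deg, field_deg,
                axial_sampling_um = 7, refractive_index = 1.4)
}

#' Configuration for the demonstration phantom
#'
#' [default_config()] with the geometry replaced by [phantom_geometry()]'s
#' dimensions.
#'
#' @param n_depth,n_fast,n_slow,field_deg Passed to [phantom_geometry()].
#' @return A configuration list.
#' @export
phantom_config <- function(n_depth = 256L, n_fast = 128L, n_slow = 128L,
                           field_deg = 6) {
  cfg <- default_config()
  cfg$n_depth <- as.integer(n_depth)
  cfg$n_fast <- as.integer(n_fast)
  cfg$n_slow <- as.integer(n_slow)
  cfg$field_deg_x <- field_deg
  cfg$field_deg_y <- field_deg
  cfg$axial_sampling_um <- 7
  cfg
}

#' Generate the two phantom boundary surfaces
#'
#' Builds smooth RBC-complex and choroidal-scleral interface surfaces as
#' low-order 2D cosine series with random coefficients. The sum of absolute
#' coefficient magnitudes is normalized to `amplitude`, so each surface stays
#' within `mean depth +/- amplitude`.
#'
#' @param geometry A [scan_geometry()].
#' @param rbc_mean,csi_mean Mean depths in voxels; must satisfy
#'   `rbc_mean < csi_mean` with margin greater than the amplitude sum.
#' @param amplitude Maximum surface deviation, voxels (same for both).
#' @param order Highest cosine order per transverse axis.
#' @param seed Integer seed; identical seeds give identical surfaces.
#' @return List with real-valued depth matrices `rbc` and `csi` (`[x, y]`).
#' @export
make_surfaces <- function(geometry, rbc_mean, csi_mean, amplitude = 6,
                          order = 2L, seed = 1L) {
  stopifnot(inherits(geometry, "scan_geometry"), amplitude >= 0)
  if (csi_mean - rbc_mean <= 2 * amplitude)
    stop("mean depths must be ordered rbc < csi with margin > amplitude sum")
  if (rbc_mean - amplitude < 0 || csi_mean + amplitude >= geometry$n_depth)
    stop("surfaces would escape [0, n_depth)")
  nx <- geometry$n_fast; ny <- geometry$n_slow
  one_surface <- function(mean_depth) {
    s <- matrix(mean_depth, nx, ny)
    if (amplitude > 0) {
      ks <- expand.grid(k = 0:order, l = 0:order)
      ks <- ks[ks$k + ks$l > 0, ]
      a <- runif(nrow(ks), -1, 1)
      a <- a * amplitude / sum(abs(a))
      xs <- (seq_len(nx) - 0.5) / nx
      ys <- (seq_len(ny) - 0.5) / ny
      for (i in seq_len(nrow(ks)))
        s <- s + a[i] * outer(cospi(ks$k[i] * xs), cospi(ks$l[i] * ys))
    }
    s
  }
  with_seed(seed, {
    rbc <- one_surface(rbc_mean)
    csi <- one_surface(csi_mean)
    list(rbc = rbc, csi = csi)
  })
}

#' Sample phantom vessel tubes in two caliber populations
#'
#' Tubes run roughly parallel to the fast or slow axis (alternating), with
#' mild sinusoidal undulation in depth and in the crossing transverse axis,
#' and follow the choroidal-scleral interface at a prescribed depth.
#' Haller-class tubes are placed so their anterior surfaces cluster at
#' `haller_bins` voxels above the interface (small per-tube jitter);
#' Sattler-class tubes occupy the anterior band above that.
#'
#' @param surfaces Output of [make_surfaces()].
#' @param geometry A [scan_geometry()].
#' @param sattler_radius_um,haller_radius_um Radius ranges, micrometres; the
#'   ranges must be disjoint with `max(sattler) < min(haller)`.
#' @param n_sattler,n_haller Tube counts (>= 0).
#' @param haller_bins Target Haller/Sattler boundary, voxels above the
#'   interface.
#' @param sattler_bins Target mean anterior extent of Sattler tubes above the
#'   boundary, voxels.
#' @param border_jitter SD of the per-tube anterior-surface jitter, voxels.
#' @param seed Integer seed.
#' @return List of vessel tubes (fields `axis`, `layer`, `radius_um`, `r_z`,
#'   `r_t`, `cross0`, `depth_bins0`, undulation parameters).
#' @export
sample_vessels <- function(surfaces, geometry,
                           sattler_radius_um = c(12, 30),
                           haller_radius_um = c(40, 100),
                           n_sattler = 34L, n_haller = 14L,
                           haller_bins = NULL, sattler_bins = NULL,
                           border_jitter = 0.5, seed = 1L) {
  stopifnot(n_sattler >= 0, n_haller >= 0)
  if (max(sattler_radius_um) >= min(haller_radius_um))
    stop("radius ranges must be disjoint (sattler max < haller min)")
  axu <- axial_um_per_voxel(geometry)
  tmm <- transverse_mm_per_voxel(geometry)
  if (is.null(haller_bins)) haller_bins <- 140 / axu
  if (is.null(sattler_bins)) sattler_bins <- 90 / axu
  ## both populations must fit distinctly in the thinnest column; Sattler
  ## tubes may still be truncated against the RBC complex locally (as the
  ## anatomy allows: Sattler's layer borders the choriocapillaris)
  min_choroid <- min(surfaces$csi - surfaces$rbc)
  need <- haller_bins + 0.5 * sattler_bins + 4
  if (min_choroid < need)
    stop(sprintf("choroid region too thin for both populations (min %.1f voxels, need %.1f)",
                 min_choroid, need))

  make_tube <- function(layer, radius_um, axis, cross0, top_bins) {
    r_z <- radius_um / axu
    r_t <- radius_um / 1000 / unname(if (axis == "x") tmm["y"] else tmm["x"])
    ## oblique course: posterior-pole vessels radiate rather than track the
    ## raster axes, so a tube crosses B-scans instead of lying inside one
    slope_mag <- if (layer == "haller") runif(1, 0.15, 0.35) else runif(1, 0, 0.04)
    list(layer = layer, axis = axis, radius_um = radius_um,
         r_z = r_z, r_t = r_t, cross0 = cross0,
         slope = sample(c(-1, 1), 1) * slope_mag,
         depth_bins0 = top_bins - r_z,
         und_z = c(amp = runif(1, 0, 0.5), cyc = runif(1, 0.5, 2),
                   phase = runif(1, 0, 2 * pi)),
         und_c = c(amp = runif(1, 0, 1.5), cyc = runif(1, 0.5, 2),
                   phase = runif(1, 0, 2 * pi)))
  }

  with_seed(seed, {
    tubes <- list()
    ## Haller: stratified cross positions, alternating orientation, tops at
    ## the target boundary depth
    if (n_haller > 0) {
      for (i in seq_len(n_haller)) {
        axis <- if (i %% 2 == 1) "x" else "y"
        n_cross <- if (axis == "x") geometry$n_slow else geometry$n_fast
        per_axis <- ceiling(n_haller / 2)
        slot <- (i - 1) %/% 2
        cross0 <- (slot + 0.5) / per_axis * n_cross + runif(1, -4, 4)
        cross0 <- min(max(cross0, 2), n_cross - 3)
        radius_um <- runif(1, haller_radius_um[1], haller_radius_um[2])
        top <- haller_bins + rnorm(1, 0, border_jitter)
        tubes[[length(tubes) + 1L]] <-
          make_tube("haller", radius_um, axis, cross0, top)
      }
    }
    ## Sattler: stratified cross positions in the anterior band (evens the
    ## per-tile vessel density)
    if (n_sattler > 0) {
      for (i in seq_len(n_sattler)) {
        axis <- if (i %% 2 == 1) "x" else "y"
        n_cross <- if (axis == "x") geometry$n_slow else geometry$n_fast
        per_axis <- ceiling(n_sattler / 2)
        slot <- (i - 1) %/% 2
        width <- n_cross / per_axis
        cross0 <- (slot + 0.5) * width + runif(1, -width / 2, width / 2)
        cross0 <- min(max(cross0, 2), n_cross - 3)
        radius_um <- runif(1, sattler_radius_um[1], sattler_radius_um[2])
        ## anterior extents fill the band up to a sharp cap at the target
        ## extent (the layer's inner envelope); tube bottoms rest on the
        ## boundary without penetrating the large-vessel zone, keeping the
        ## caliber populations stratified by depth
        r_z <- radius_um / axu
        t_lo <- 2 * r_z
        top <- haller_bins + runif(1, t_lo, max(sattler_bins, t_lo + 2))
        tubes[[length(tubes) + 1L]] <-
          make_tube("sattler", radius_um, axis, cross0, top)
      }
    }
    tubes
  })
}

## Rasterize one tube against the surfaces. Returns integer voxel triples
## (z, x, y; 0-based) restricted to the choroid region, plus the per-column
## anterior-most depth bin (distance from the deepest choroidal voxel).
rasterize_tube <- function(tube, surfaces, geometry) {
  nz <- geometry$n_depth; nx <- geometry$n_fast; ny <- geometry$n_slow
  n_along <- if (tube$axis == "x") nx else ny
  t <- seq_len(n_along) - 1L
  ph <- t / n_along * 2 * pi
  cross <- tube$cross0 + tube$slope * (t - n_along / 2) +
    tube$und_c["amp"] * sin(tube$und_c["cyc"] * ph + tube$und_c["phase"])
  depth <- tube$depth_bins0 + tube$und_z["amp"] * sin(tube$und_z["cyc"] * ph +
                                                      tube$und_z["phase"])
  cross_i <- pmin(pmax(round(cross), 0L), (if (tube$axis == "x") ny else nx) - 1L)
  if (tube$axis == "x") { xs <- t; ys <- cross_i } else { xs <- cross_i; ys <- t }
  ## deepest choroidal voxel per column and local surfaces
  csi <- surfaces$csi[cbind(xs + 1L, ys + 1L)]
  rbc <- surfaces$rbc[cbind(xs + 1L, ys + 1L)]
  z_bottom <- ceiling(csi) - 1L           # deepest choroidal voxel
  zc <- z_bottom - depth                  # centre depth in absolute z
  ## elliptical cross-section offsets (perpendicular plane: depth x cross)
  mdz <- ceiling(tube$r_z); mdt <- ceiling(tube$r_t)
  off <- expand.grid(dz = -mdz:mdz, dt = -mdt:mdt)
  off <- off[(off$dz / max(tube$r_z, 0.5))^2 +
             (off$dt / max(tube$r_t, 0.5))^2 <= 1, ]
  K <- nrow(off)
  z <- rep(round(zc), each = K) + off$dz
  ti <- rep(t, each = K)
  ci <- rep(cross_i, each = K) + off$dt
  keep <- ci >= 0L & ci < (if (tube$axis == "x") ny else nx)
  z <- z[keep]; ti <- ti[keep]; ci <- ci[keep]
  if (tube$axis == "x") { x <- ti; y <- ci } else { x <- ci; y <- ti }
  ## containment: strictly inside the choroid, keeping a 2-voxel
  ## choriocapillaris band below the RBC complex vessel-free
  rbc_l <- surfaces$rbc[cbind(x + 1L, y + 1L)]
  csi_l <- surfaces$csi[cbind(x + 1L, y + 1L)]
  keep <- z >= ceiling(rbc_l) + 2L & z <= ceiling(csi_l) - 1L & z >= 0L & z < nz
  z <- z[keep]; x <- x[keep]; y <- y[keep]
  if (!length(z))
    return(list(z = integer(), x = integer(), y = integer(),
                tops = data.frame(x = integer(), y = integer(),
                                  top_bin = integer())))
  bin <- (ceiling(surfaces$csi[cbind(x + 1L, y + 1L)]) - 1L) - z
  key <- x + nx * y
  top <- tapply(bin, key, max)
  kx <- as.integer(names(top)) %% nx
  ky <- as.integer(names(top)) %/% nx
  ## mark columns traversed by the centerline: a tube belongs to a tile only
  ## where its axis runs through it, not where its shell grazes it
  ckey <- unique(xs + nx * ys)
  list(z = as.integer(z), x = as.integer(x), y = as.integer(y),
       tops = data.frame(x = kx, y = ky, top_bin = as.integer(top),
                         center = as.integer(names(top)) %in% ckey))
}

#' Render a phantom OCT volume with ground truth
#'
#' Voxel intensity is `tissue_level * exp(-depth_below_RBC / tau) * speckle`,
#' where the tissue level is `background` outside the choroid, `stroma`
#' inside it, and `vessel` inside vessel tubes, and speckle is multiplicative
#' gamma noise with unit mean and shape `speckle_shape`. Setting `tau = Inf`
#' disables attenuation and `speckle_shape = Inf` disables speckle (the
#' noise-free limit is piecewise constant with exactly three levels).
#'
#' @param surfaces Output of [make_surfaces()].
#' @param tubes Output of [sample_vessels()].
#' @param geometry A [scan_geometry()].
#' @param levels Named numeric vector `c(background, stroma, vessel)`;
#'   must satisfy `vessel < stroma`.
#' @param tau Attenuation depth constant, voxels (`Inf` = off).
#' @param speckle_shape Gamma shape of the multiplicative speckle
#'   (`Inf` = off). The speckle factor has unit mean for any shape.
#' @param seed Integer seed (speckle only; geometry is already fixed by the
#'   surface and vessel seeds).
#' @param depth_offset Rigid axial shift of the whole anatomy, voxels
#'   (models session-to-session positioning differences).
#' @return List with `volume` (an [oct_volume()]) and `truth`
#'   (a `phantom_truth` object; see Details).
#'
#' @details `truth` carries the surfaces, the tube list, a per-voxel tube id
#'   array (`tube_id`, 0 = no vessel), the logical vessel mask, the per-tube
#'   per-column anterior depth bins (`tube_tops`), and the seed. Depth bins
#'   count voxels from the deepest choroidal voxel, increasing anteriorly.
#' @export
render_volume <- function(surfaces, tubes, geometry,
                          levels = c(background = 0.2, stroma = 1.0,
                                     vessel = 0.25),
                          tau = 250, speckle_shape = 25, seed = 1L,
                          depth_offset = 0) {
  stopifnot(inherits(geometry, "scan_geometry"))
  if (!is.infinite(tau) && tau <= 0) stop("tau must be > 0 (or Inf)")
  if (!is.infinite(speckle_shape) && speckle_shape <= 0)
    stop("speckle_shape must be > 0 (or Inf)")
  if (levels[["vessel"]] >= levels[["stroma"]])
    stop("intensity levels must be ordered vessel < stroma")
  nz <- geometry$n_depth; nx <- geometry$n_fast; ny <- geometry$n_slow
  if (depth_offset != 0)
    surfaces <- list(rbc = surfaces$rbc + depth_offset,
                     csi = surfaces$csi + depth_offset)

  ## tissue level array
  lev <- array(levels[["background"]], dim = c(nz, nx, ny))
  zidx <- seq_len(nz) - 1L
  rbc_col <- ceiling(surfaces$rbc)          # first choroidal voxel
  csi_col <- ceiling(surfaces$csi)          # first scleral voxel
  ## choroid stroma: rbc <= z < csi
  in_chor <- outer(zidx, as.vector(rbc_col), `>=`) &
    outer(zidx, as.vector(csi_col), `<`)
  lev[in_chor] <- levels[["stroma"]]

  tube_id <- array(0L, dim = c(nz, nx, ny))
  tube_tops <- vector("list", length(tubes))
  for (i in seq_along(tubes)) {
    r <- rasterize_tube(tubes[[i]], surfaces, geometry)
    if (length(r$z)) {
      idx <- r$z + 1L + nz * (r$x + nx * r$y)
      lev[idx] <- levels[["vessel"]]
      tube_id[idx] <- i
      tube_tops[[i]] <- r$tops
    } else {
      tube_tops[[i]] <- data.frame(x = integer(), y = integer(),
                                   top_bin = integer())
    }
  }

  ## depth-dependent attenuation below the RBC complex
  if (is.finite(tau)) {
    depth_below <- outer(zidx, as.vector(surfaces$rbc), `-`)
    depth_below[depth_below < 0] <- 0
    atten <- exp(-depth_below / tau)
    dim(atten) <- c(nz, nx, ny)
    lev <- lev * atten
  }
  if (is.finite(speckle_shape)) {
    lev <- with_seed(seed, lev * rgamma(length(lev), shape = speckle_shape,
                                        rate = speckle_shape))
  }

  truth <- structure(list(
    rbc_surface = surfaces$rbc, csi_surface = surfaces$csi,
    tubes = tubes, tube_id = tube_id, vessel_mask = tube_id > 0L,
    tube_tops = tube_tops, geometry = geometry, seed = as.integer(seed)),
    class = "phantom_truth")
  list(volume = oct_volume(lev, geometry), truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("phantom_truth: %d tubes (%d haller, %d sattler), %d vessel voxels\n",
              length(x$tubes),
              sum(vapply(x$tubes, function(t) t$layer == "haller", TRUE)),
              sum(vapply(x$tubes, function(t) t$layer == "sattler", TRUE)),
              sum(x$vessel_mask)))
  invisible(x)
}

#' Generate a complete phantom from a configuration
#'
#' Convenience wrapper: surfaces, vessels and rendering driven by the
#' `phantom_*` configuration keys. `tau`/`speckle_shape` values of `-1` in
#' the configuration disable attenuation/speckle.
#'
#' @param cfg Configuration list (see [phantom_config()]).
#' @param seed Integer master seed; surface, vessel and speckle seeds are
#'   derived from it.
#' @param depth_offset Axial shift in voxels, passed to [render_volume()].
#' @param noise_seed Optional separate speckle seed (defaults to a value
#'   derived from `seed`); used to re-render the same anatomy with fresh
#'   noise.
#' @return List with `volume`, `truth`, and `surfaces`.
#' @export
generate_phantom <- function(cfg = phantom_config(), seed = 1L,
                             depth_offset = 0, noise_seed = NULL) {
  geometry <- config_geometry(cfg)
  axu <- axial_um_per_voxel(geometry)
  chor_bins <- cfg$phantom_choroid_thickness_um / axu
  surfaces <- make_surfaces(geometry,
                            rbc_mean = cfg$phantom_rbc_depth,
                            csi_mean = cfg$phantom_rbc_depth + chor_bins,
                            amplitude = cfg$phantom_surface_amplitude,
                            seed = seed * 3L + 1L)
  tubes <- sample_vessels(surfaces, geometry,
                          sattler_radius_um = c(cfg$phantom_sattler_radius_um_min,
                                                cfg$phantom_sattler_radius_um_max),
                          haller_radius_um = c(cfg$phantom_haller_radius_um_min,
                                               cfg$phantom_haller_radius_um_max),
                          n_sattler = cfg$phantom_n_sattler,
                          n_haller = cfg$phantom_n_haller,
                          haller_bins = cfg$phantom_haller_thickness_um / axu,
                          sattler_bins = cfg$phantom_sattler_thickness_um / axu,
                          border_jitter = cfg$phantom_border_jitter,
                          seed = seed * 3L + 2L)
  tau <- if (cfg$phantom_tau < 0) Inf else cfg$phantom_tau
  k <- if (cfg$phantom_speckle_shape < 0) Inf else cfg$phantom_speckle_shape
  if (is.null(noise_seed)) noise_seed <- seed * 3L + 3L
  out <- render_volume(surfaces, tubes, geometry,
                       levels = c(background = cfg$phantom_background_level,
                                  stroma = cfg$phantom_stroma_level,
                                  vessel = cfg$phantom_vessel_level),
                       tau = tau, speckle_shape = k, seed = noise_seed,
                       depth_offset = depth_offset)
  cl_log("phantom: seed %d, %d tubes, %d vessel voxels", seed,
         length(tubes), sum(out$truth$vessel_mask))
  list(volume = out$volume, truth = out$truth, surfaces = surfaces)
}

## per-tile mean over A-scan columns of the anterior-most Sattler voxel
sattler_column_envelope <- function(truth, tiling) {
  nt_x <- tiling$n_tiles_x; nt_y <- tiling$n_tiles_y
  layer_of <- vapply(truth$tubes, function(t) t$layer, "")
  nx <- truth$geometry$n_fast
  col_top <- new.env(parent = emptyenv())
  tops_all <- do.call(rbind, truth$tube_tops[layer_of == "sattler"])
  out <- matrix(NA_real_, nt_x, nt_y)
  if (is.null(tops_all) || !nrow(tops_all)) return(out)
  key <- tops_all$x + nx * tops_all$y
  per_col <- tapply(tops_all$top_bin, key, max)
  kx <- as.integer(names(per_col)) %% nx
  ky <- as.integer(names(per_col)) %/% nx
  ti <- tiling$tile_of_x[kx + 1L]
  tj <- tiling$tile_of_y[ky + 1L]
  tkey <- ti + nt_x * (tj - 1L)
  ## the envelope: anterior-most depth attained by the layer in the tile
  m <- tapply(per_col, tkey, max)
  out[as.integer(names(m))] <- m
  out
}

#' True per-tile sublayer summary from phantom ground truth
#'
#' For each 1 x 1 degree tile, the true Haller/Sattler boundary is the mean
#' over Haller-class tubes crossing the tile of each tube's anterior-most
#' rendered voxel depth (voxels above the interface); the Sattler anterior
#' envelope is the analogous mean over Sattler-class tubes. Thicknesses are
#' converted to anatomical micrometres.
#'
#' @param truth A `phantom_truth` from [render_volume()].
#' @param tiling A tiling from [tile_volume()].
#' @return List with tile-resolution [thickness_map()]s `sattler` and
#'   `haller`, plus matrices `border_bins` and `sattler_top_bins`.
#' @export
true_tile_summary <- function(truth, tiling) {
  geometry <- truth$geometry
  axu <- axial_um_per_voxel(geometry)
  nt_x <- tiling$n_tiles_x; nt_y <- tiling$n_tiles_y
  border <- matrix(NA_real_, nt_x, nt_y)
  sat_top <- matrix(NA_real_, nt_x, nt_y)
  layer_of <- vapply(truth$tubes, function(t) t$layer, "")
  ## per tube, per tile: anterior-most bin among the tube's columns in tile
  per_tile <- function(layer, combine = NULL) {
    per_tube <- matrix(NA_real_, nt_x, nt_y)
    acc <- matrix(0, nt_x, nt_y); cnt <- matrix(0L, nt_x, nt_y)
    for (i in which(layer_of == layer)) {
      tops <- truth$tube_tops[[i]]
      if (!nrow(tops)) next
      ti <- tiling$tile_of_x[tops$x + 1L]
      tj <- tiling$tile_of_y[tops$y + 1L]
      key <- ti + nt_x * (tj - 1L)
      ## only tiles the tube's centerline passes through
      ckeys <- unique(key[tops$center])
      keep <- key %in% ckeys
      if (!any(keep)) next
      mx <- tapply(tops$top_bin[keep], key[keep], max)
      kk <- as.integer(names(mx))
      if (is.null(combine)) {
        acc[kk] <- acc[kk] + mx
        cnt[kk] <- cnt[kk] + 1L
      } else {
        per_tube[kk] <- pmax(per_tube[kk], mx, na.rm = TRUE)
      }
    }
    if (is.null(combine)) {
      out <- acc / cnt
      out[cnt == 0L] <- NA_real_
      out
    } else per_tube
  }
  ## Haller/Sattler boundary: mean over Haller tubes of each tube's
  ## anterior-most depth. Sattler inner limit: the anterior envelope of the
  ## Sattler vasculature, averaged over the tile's vessel-bearing A-scans
  ## (per-column anterior-most voxel, mean across columns).
  border <- per_tile("haller")
  sat_top <- sattler_column_envelope(truth, tiling)
  haller_um <- border * axu
  sattler_um <- pmax(sat_top - border, 0) * axu
  ## Sattler undefined where no Haller boundary exists; zero where Haller
  ## exists but no Sattler tubes do
  sattler_um[is.na(border)] <- NA_real_
  sattler_um[!is.na(border) & is.na(sat_top)] <- 0
  tmm <- transverse_mm_per_voxel(geometry)
  mmx <- tmm["x"] * geometry$n_fast / nt_x
  mmy <- tmm["y"] * geometry$n_slow / nt_y
  list(sattler = thickness_map(sattler_um, mmx, mmy),
       haller = thickness_map(haller_um, mmx, mmy),
       border_bins = border, sattler_top_bins = sat_top)
}
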