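# Brute-force oracles and small geometric fixtures, independent of the
# package's compiled kernels.

# count voxels with at least one 6-neighbour outside the mask (volume
# borders count as outside), by explicit shifting
surface_oracle <- function(mask) {
  d <- dim(mask)
  shifted <- function(dz, dx, dy) {
    out <- array(FALSE, d)
    zs <- seq_len(d[1]) + dz; xs <- seq_len(d[2]) + dx; ys <- seq_len(d[3]) + dy
    okz <- zs >= 1 & zs <= d[1]; okx <- xs >= 1 & xs <= d[2]
    oky <- ys >= 1 & ys <= d[3]
    out[which(okz), which(okx), which(oky)] <-
      mask[zs[okz], xs[okx], ys[oky], drop = FALSE]
    out
  }
  inside <- shifted(-1, 0, 0) & shifted(1, 0, 0) & shifted(0, -1, 0) &
    shifted(0, 1, 0) & shifted(0, 0, -1) & shifted(0, 0, 1)
  mask & !inside
}

# 6-connectivity flood fill from seeds restricted to cand (plain R BFS)
flood_oracle <- function(seeds, cand) {
  d <- dim(seeds)
  out <- seeds
  frontier <- which(seeds)
  off <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
               c(0, 0, -1), c(0, 0, 1))
  while (length(frontier)) {
    nxt <- integer()
    for (i in frontier) {
      z <- (i - 1) %% d[1] + 1
      x <- ((i - 1) %/% d[1]) %% d[2] + 1
      y <- (i - 1) %/% (d[1] * d[2]) + 1
      for (k in 1:6) {
        zz <- z + off[k, 1]; xx <- x + off[k, 2]; yy <- y + off[k, 3]
        if (zz < 1 || zz > d[1] || xx < 1 || xx > d[2] || yy < 1 || yy > d[3])
          next
        j <- zz + d[1] * (xx - 1 + d[2] * (yy - 1))
        if (cand[j] && !out[j]) { out[j] <- TRUE; nxt <- c(nxt, j) }
      }
    }
    frontier <- nxt
  }
  out
}

# digitized solid cylinder along the x axis: voxel centres within `radius`
# of the axis line at (z0, y0)
make_cylinder <- function(dim, z0, y0, radius, x_range = c(1, dim[2])) {
  arr <- array(FALSE, dim)
  zs <- seq_len(dim[1]); ys <- seq_len(dim[3])
  disc <- outer((zs - z0)^2, (ys - y0)^2, `+`) <= radius^2
  for (x in x_range[1]:x_range[2]) arr[, x, ][disc] <- TRUE
  arr
}

make_sphere <- function(dim, c0, radius) {
  arr <- array(FALSE, dim)
  zs <- seq_len(dim[1]); xs <- seq_len(dim[2]); ys <- seq_len(dim[3])
  for (y in ys) {
    d2 <- outer((zs - c0[1])^2, (xs - c0[2])^2, `+`) + (y - c0[3])^2
    arr[, , y] <- d2 <= radius^2
  }
  arr
}

# small, fast phantom configuration for smoke-level tests (coarse transverse
# sampling; not meant for accuracy checks)
tiny_phantom_cfg <- function() {
  cfg <- phantom_config(n_depth = 96L, n_fast = 48L, n_slow = 48L)
  cfg$phantom_rbc_depth <- 20
  cfg
}

# full-size phantoms for the acceptance checks, generated once per session
.acc_cache <- new.env(parent = emptyenv())
acceptance_phantom <- function(noise = TRUE) {
  key <- if (noise) "speckled" else "noisefree"
  if (is.null(.acc_cache[[key]])) {
    cfg <- phantom_config()
    if (!noise) {
      cfg$phantom_tau <- -1
      cfg$phantom_speckle_shape <- -1
      cfg$denoise_radius <- 0L
      cfg$candidate_percentile <- 25
    }
    ph <- generate_phantom(cfg, seed = 1)
    .acc_cache[[key]] <- list(cfg = cfg, phantom = ph,
                              result = analyze_volume(ph$volume, cfg))
  }
  .acc_cache[[key]]
}
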