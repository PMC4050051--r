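test_that("surfaces are flat in the zero-amplitude limit and reproducible", {
  g <- phantom_geometry(64, 16, 16)
  s <- make_surfaces(g, 15, 30, amplitude = 0, seed = 3)
  expect_true(all(s$rbc == 15) && all(s$csi == 30))
  s1 <- make_surfaces(g, 15, 30, amplitude = 3, seed = 9)
  s2 <- make_surfaces(g, 15, 30, amplitude = 3, seed = 9)
  expect_identical(s1, s2)
  s3 <- make_surfaces(g, 15, 30, amplitude = 3, seed = 10)
  expect_false(identical(s1$rbc, s3$rbc))
  expect_true(all(s1$csi - s1$rbc > 0))
  expect_error(make_surfaces(g, 30, 15, amplitude = 0), "ordered")
  expect_error(make_surfaces(g, 4, 62, amplitude = 6), "escape")
})

test_that("vessel sampling respects counts, caliber disjointness and region size", {
  g <- phantom_geometry(96, 32, 32)
  s <- make_surfaces(g, 20, 74, amplitude = 2, seed = 1)
  expect_length(sample_vessels(s, g, n_sattler = 0, n_haller = 0), 0)
  tubes <- sample_vessels(s, g, n_sattler = 0, n_haller = 5, seed = 2)
  expect_true(all(vapply(tubes, function(t) t$layer, "") == "haller"))
  expect_error(sample_vessels(s, g, sattler_radius_um = c(12, 50),
                              haller_radius_um = c(40, 100)), "disjoint")
  thin <- make_surfaces(g, 20, 40, amplitude = 1, seed = 1)
  expect_error(sample_vessels(thin, g), "too thin")
})

test_that("rendering is deterministic, contained and piecewise constant when noise-free", {
  cfg <- tiny_phantom_cfg()
  cfg$phantom_tau <- -1
  cfg$phantom_speckle_shape <- -1
  ph <- generate_phantom(cfg, seed = 5)
  ph2 <- generate_phantom(cfg, seed = 5)
  expect_identical(ph$volume$intensity, ph2$volume$intensity)

  ## exactly three intensity levels in the noise-free limit
  levels <- sort(unique(as.vector(ph$volume$intensity)))
  expect_length(levels, 3L)
  expect_equal(levels, c(cfg$phantom_background_level,
                         cfg$phantom_vessel_level,
                         cfg$phantom_stroma_level))

  ## exhaustive containment: every vessel voxel strictly inside the choroid
  idx <- which(ph$truth$vessel_mask)
  d <- dim(ph$truth$vessel_mask)
  z <- (idx - 1) %% d[1]
  x <- ((idx - 1) %/% d[1]) %% d[2]
  y <- (idx - 1) %/% (d[1] * d[2])
  rbc <- ph$truth$rbc_surface[cbind(x + 1, y + 1)]
  csi <- ph$truth$csi_surface[cbind(x + 1, y + 1)]
  expect_true(all(z >= ceiling(rbc)))
  expect_true(all(z <= ceiling(csi) - 1))
})

test_that("multiplicative speckle has unit mean", {
  cfg <- tiny_phantom_cfg()
  cfg_nf <- cfg
  cfg_nf$phantom_speckle_shape <- -1
  ph <- generate_phantom(cfg, seed = 8)
  nf <- generate_phantom(cfg_nf, seed = 8)
  fac <- ph$volume$intensity / nf$volume$intensity
  expect_gt(length(fac), 1e5)
  expect_lt(abs(mean(fac) - 1), 0.01)
})

test_that("render_volume rejects invalid noise and level settings", {
  g <- phantom_geometry(64, 16, 16)
  s <- make_surfaces(g, 15, 45, amplitude = 0, seed = 1)
  expect_error(render_volume(s, list(), g, tau = -2), "tau")
  expect_error(render_volume(s, list(), g, speckle_shape = 0), "speckle")
  expect_error(render_volume(s, list(), g,
                             levels = c(background = 0.2, stroma = 0.3,
                                        vessel = 0.5)), "ordered")
})

test_that("true tile summary reproduces an analytic single-tube case and a recount", {
  g <- phantom_geometry(96, 32, 32)
  s <- make_surfaces(g, 20, 74, amplitude = 0, seed = 1)
  ## one straight haller tube, no undulation, centered
  tube <- list(layer = "haller", axis = "x", radius_um = 50,
               r_z = 10, r_t = 3, cross0 = 16, slope = 0,
               depth_bins0 = 30,
               und_z = c(amp = 0, cyc = 1, phase = 0),
               und_c = c(amp = 0, cyc = 1, phase = 0))
  out <- render_volume(s, list(tube), g, tau = Inf, speckle_shape = Inf)
  tiling <- tile_volume(g, g$field_deg_x)  # single tile
  ts <- true_tile_summary(out$truth, tiling)
  ## anterior-most voxel: centre depth 30 + floor(r_z) = 40 bins above the
  ## deepest choroidal voxel
  axu <- choroidlayers:::axial_um_per_voxel(g)
  expect_equal(ts$border_bins[1, 1], 40)
  expect_equal(ts$haller$values[1, 1], 40 * axu)
  expect_equal(ts$sattler$values[1, 1], 0)  # no sattler tubes

  ## independent recount from the voxel-level tube id array
  d <- dim(out$truth$tube_id)
  idx <- which(out$truth$tube_id == 1L)
  z <- (idx - 1) %% d[1]
  x <- ((idx - 1) %/% d[1]) %% d[2]
  y <- (idx - 1) %/% (d[1] * d[2])
  bins <- (ceiling(out$truth$csi_surface[cbind(x + 1, y + 1)]) - 1) - z
  expect_equal(max(bins), 40)

  ## no tubes at all: everything missing
  empty <- render_volume(s, list(), g, tau = Inf, speckle_shape = Inf)
  ts0 <- true_tile_summary(empty$truth, tiling)
  expect_true(all(is.na(ts0$haller$values)))
  expect_true(all(is.na(ts0$sattler$values)))
})
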