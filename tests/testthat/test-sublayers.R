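test_that("tiling partitions the field with 14 B-scans per degree tile", {
  g <- scan_geometry()  # 512 x 512, 36 x 36 degrees
  t <- tile_volume(g, 1)
  expect_equal(t$n_tiles_x, 36L)
  expect_equal(t$n_tiles_y, 36L)
  widths <- table(t$tile_of_x)
  expect_true(all(widths[2:35] == 14))  # interior tiles
  expect_equal(length(t$tile_of_x), 512L)  # every A-scan in exactly one tile
  expect_equal(sum(widths), 512)

  t1 <- tile_volume(g, 36)
  expect_equal(t1$n_tiles_x, 1L)
  expect_error(tile_volume(g, 0), "tile_deg")
})

test_that("the ratio profile of a 3x3x3 cube matches exhaustive enumeration", {
  g <- scan_geometry(32, 9, 9, 1, 1)
  mask <- array(FALSE, c(32, 9, 9))
  ## flat CSI at z = 20: depth bins 0..2 are 0-based z = 19, 18, 17
  mask[18:20, 4:6, 4:6] <- TRUE
  vm <- label_components(mask)
  reg <- choroid_region(surface_map(matrix(5L, 9, 9), "rbc"),
                        surface_map(matrix(20L, 9, 9), "csi"))
  p <- ratio_profile(vm, reg, tile_volume(g, 1), c(1, 1), smooth_w = 1)
  ## bins 0 and 2 are cube faces (9 surface voxels each); bin 1 holds the
  ## centre voxel as the only interior one
  expect_equal(p$ratio[1:3], c(9 / 9, 9 / 8, 9 / 9))
  expect_equal(p$n_volume[1:3], c(9L, 9L, 9L))
  expect_true(all(is.na(p$ratio[4:length(p$ratio)])))
})

test_that("an empty tile yields an all-undefined profile", {
  g <- scan_geometry(32, 9, 9, 1, 1)
  vm <- label_components(array(FALSE, c(32, 9, 9)))
  reg <- choroid_region(surface_map(matrix(5L, 9, 9), "rbc"),
                        surface_map(matrix(20L, 9, 9), "csi"))
  p <- ratio_profile(vm, reg, tile_volume(g, 1), c(1, 1))
  expect_true(all(is.na(p$ratio)))
  expect_false(find_borders(p)$defined)
})

test_that("volume/surface ratio increases strictly with cylinder radius", {
  ## whole-component ratios, verified against the brute-force shift oracle
  ratios <- vapply(2:8, function(r) {
    dim <- c(2 * r + 5, 20, 2 * r + 5)
    cyl <- make_cylinder(dim, r + 3, r + 3, r)
    vm <- label_components(cyl)
    expect_equal(vm$components$n_surface, sum(surface_oracle(cyl)))
    vm$components$n_voxels / vm$components$n_surface
  }, 0)
  expect_true(all(diff(ratios) > 0))
})

test_that("the valley rule reproduces its hand-traceable cases", {
  mk <- function(v) structure(list(smoothed = v), class = "ratio_profile")
  ## ratios from the sclera: maximum at bin 0, first valley at bin 2,
  ## vessels end at the undefined bin 6
  b <- find_borders(mk(c(5, 4, 2, 3, 2, 1, NA, NA)), noise_floor = 0.5)
  expect_equal(b$haller_sattler, 2)
  expect_equal(b$sattler_inner, 6)

  ## monotonically decreasing, no interior valley: zero Sattler thickness
  b2 <- find_borders(mk(c(6, 5, 4, 3, 2.5, 2, 1.5, NA, NA)), noise_floor = 1.05)
  expect_equal(b2$haller_sattler, b2$sattler_inner)

  ## a valley dipping below the noise floor does not zero the layer above
  b3 <- find_borders(mk(c(6, 5, 3, 1.0, 1.5, 1.8, 1.8, 1.5, 1.0, NA)))
  expect_lt(b3$haller_sattler, b3$sattler_inner)
  expect_equal(b3$sattler_inner, 8)
})

test_that("two stacked cylinders put the ratio maximum in the large-caliber band", {
  g <- scan_geometry(64, 21, 21, 1, 1)
  big <- make_cylinder(c(64, 21, 21), 45, 11, 6)   # posterior, large
  small <- make_cylinder(c(64, 21, 21), 20, 11, 2) # anterior, small
  vm <- label_components(big | small)
  reg <- choroid_region(surface_map(matrix(5L, 21, 21), "rbc"),
                        surface_map(matrix(60L, 21, 21), "csi"))
  p <- ratio_profile(vm, reg, tile_volume(g, 1), c(1, 1))
  ## the posterior (large) cylinder spans bins 9..21, the small one 38..42
  m <- which.max(p$smoothed)
  expect_true(m - 1 >= 8 && m - 1 <= 22)
  expect_gt(max(p$smoothed[9:23], na.rm = TRUE),
            max(p$smoothed[38:44], na.rm = TRUE))
})

test_that("borders convert to thickness maps in anatomical micrometres", {
  g <- scan_geometry(512, 28, 28, 2, 2, axial_sampling_um = 3.5,
                     refractive_index = 1.4)
  tiling <- tile_volume(g, 1)
  borders <- structure(list(
    haller_sattler = matrix(c(40, NA, 20, 10), 2, 2),
    sattler_inner = matrix(c(60, NA, 30, 10), 2, 2),
    defined = matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2),
    tiling = tiling), class = "sublayer_borders")
  maps <- borders_to_thickness(borders, g)
  expect_equal(maps$haller$values[1, 1], 100)  # 40 bins * 2.5 um
  expect_equal(maps$sattler$values[1, 1], 50)
  expect_true(is.na(maps$haller$values[2, 1]))
  expect_equal(maps$sattler$values[2, 2], 0)
})

test_that("border indices depend only on the mask, not the intensity scale", {
  cfg <- tiny_phantom_cfg()
  ph <- generate_phantom(cfg, seed = 4)
  res1 <- analyze_volume(ph$volume, cfg)
  scaled <- oct_volume(ph$volume$intensity * 3.7, ph$volume$geometry)
  res2 <- analyze_volume(scaled, cfg)
  expect_identical(res1$borders$haller_sattler, res2$borders$haller_sattler)
  expect_identical(res1$borders$sattler_inner, res2$borders$sattler_inner)
})

test_that("layer thicknesses sum to at most the total choroidal thickness", {
  cfg <- tiny_phantom_cfg()
  ph <- generate_phantom(cfg, seed = 6)
  res <- analyze_volume(ph$volume, cfg)
  total <- res$total_map
  ## compare at tile resolution: mean total per tile
  tiling <- res$tiling
  for (i in seq_len(tiling$n_tiles_x))
    for (j in seq_len(tiling$n_tiles_y)) {
      s <- res$maps$sattler$values[i, j]
      h <- res$maps$haller$values[i, j]
      if (is.na(s) || is.na(h)) next
      xs <- which(tiling$tile_of_x == i); ys <- which(tiling$tile_of_y == j)
      expect_lte(s + h, max(total$values[xs, ys], na.rm = TRUE) + 1e-9)
    }
})
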