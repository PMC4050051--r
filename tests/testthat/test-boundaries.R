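# Synthetic two-interface volumes with known boundaries; the contrast model
# matches the phantom's: dark above the RBC complex, bright choroid, dark
# sclera.
slab_volume <- function(g, rbc, csi, bg = 0.2, stroma = 1.0) {
  arr <- array(bg, c(g$n_depth, g$n_fast, g$n_slow))
  z <- seq_len(g$n_depth) - 1L
  for (y in seq_len(g$n_slow))
    for (x in seq_len(g$n_fast)) {
      r <- if (is.matrix(rbc)) rbc[x, y] else rbc
      c <- if (is.matrix(csi)) csi[x, y] else csi
      arr[z >= r & z < c, x, y] <- stroma
    }
  oct_volume(arr, g)
}

test_that("flat interfaces are detected within one voxel", {
  g <- phantom_geometry(96, 32, 32)
  vol <- slab_volume(g, 20, 60)
  rbc <- detect_surface(vol, "rbc")
  csi <- detect_surface(vol, "csi")
  expect_true(all(abs(rbc$depth - 20) <= 1))
  expect_true(all(abs(csi$depth - 60) <= 1))
  expect_true(all(rbc$confidence > 0.5))
})

test_that("infinite smoothness flattens a tilted interface to one depth per B-scan", {
  g <- phantom_geometry(96, 32, 32)
  tilt <- matrix(rep(round(seq(50, 70, length.out = 32)), 32), 32, 32)
  vol <- slab_volume(g, 20, tilt)
  s <- detect_surface(vol, "csi", lambda = Inf)
  for (j in seq_len(32)) expect_length(unique(s$depth[, j]), 1L)
  ## and the flat depth sits inside the tilted range, near its middle
  expect_true(all(s$depth >= 50 & s$depth <= 70))
})

test_that("a constant volume yields a flagged zero-confidence surface, not an error", {
  g <- phantom_geometry(64, 16, 16)
  vol <- oct_volume(array(1, c(64, 16, 16)), g)
  s <- detect_surface(vol, "csi")
  expect_true(all(s$confidence == 0))
})

test_that("choroid regions combine surfaces with half-open semantics", {
  rbc <- surface_map(matrix(150L, 4, 4), "rbc")
  csi <- surface_map(matrix(300L, 4, 4), "csi")
  reg <- choroid_region(rbc, csi)
  expect_true(all(reg$csi - reg$rbc == 150))
  expect_true(all(reg$defined))

  ## zero-length intervals stay defined
  reg0 <- choroid_region(surface_map(matrix(100L, 2, 2), "rbc"),
                         surface_map(matrix(100L, 2, 2), "csi"))
  expect_true(all(reg0$defined) && all(reg0$csi - reg0$rbc == 0))

  ## a single crossing A-scan is undefined, the rest intact
  d <- matrix(100L, 3, 3); d[2, 2] <- 40L
  regx <- choroid_region(surface_map(matrix(80L, 3, 3), "rbc"),
                         surface_map(d, "csi"))
  expect_false(regx$defined[2, 2])
  expect_equal(sum(regx$defined), 8L)

  expect_error(choroid_region(surface_map(matrix(1L, 2, 2), "rbc"),
                              surface_map(matrix(2L, 3, 3), "csi")),
               "do not match")
})

test_that("thickness conversion applies the optical-to-anatomical calibration", {
  g <- scan_geometry(512, 16, 16, 1, 1, axial_sampling_um = 3.5,
                     refractive_index = 1.4)
  reg <- choroid_region(surface_map(matrix(100L, 16, 16), "rbc"),
                        surface_map(matrix(200L, 16, 16), "csi"))
  tm <- choroid_thickness_map(reg, g)
  expect_equal(tm$values, matrix(250, 16, 16))  # 100 voxels -> 250 um
  g1 <- scan_geometry(512, 16, 16, 1, 1, axial_sampling_um = 3.5,
                      refractive_index = 1)
  tm1 <- choroid_thickness_map(reg, g1)
  expect_equal(tm1$values, matrix(350, 16, 16))  # optical == anatomical at n = 1

  ## monotonicity: raising csi by k raises thickness by exactly k * axu
  k <- 7L
  reg2 <- choroid_region(surface_map(matrix(100L, 16, 16), "rbc"),
                         surface_map(matrix(200L + k, 16, 16), "csi"))
  tm2 <- choroid_thickness_map(reg2, g)
  expect_equal(tm2$values - tm$values,
               matrix(k * 3.5 / 1.4, 16, 16))
})

test_that("detected surfaces on a noise-free phantom match truth within one voxel RMS", {
  cfg <- tiny_phantom_cfg()
  cfg$phantom_tau <- -1; cfg$phantom_speckle_shape <- -1
  ph <- generate_phantom(cfg, seed = 2)
  rbc <- detect_surface(ph$volume, "rbc")
  csi <- detect_surface(ph$volume, "csi")
  err_r <- rbc$depth - ceiling(ph$truth$rbc_surface)
  err_c <- csi$depth - ceiling(ph$truth$csi_surface)
  expect_lt(sqrt(mean(err_r^2)), 1)
  expect_lt(sqrt(mean(err_c^2)), 1)
})
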