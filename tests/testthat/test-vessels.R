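small_geom <- function(nz = 40, nx = 40, ny = 40)
  scan_geometry(nz, nx, ny, 1, 1)

# a dark cylinder embedded in bright stroma, full-depth choroid region
cylinder_scene <- function(radius = 4, nz = 40, nx = 40, ny = 40,
                           z0 = 20, y0 = 20) {
  g <- small_geom(nz, nx, ny)
  cyl <- make_cylinder(c(nz, nx, ny), z0, y0, radius)
  arr <- array(1, c(nz, nx, ny))
  arr[cyl] <- 0.25
  vol <- oct_volume(arr, g)
  reg <- choroid_region(surface_map(matrix(0L, nx, ny), "rbc"),
                        surface_map(matrix(nz, nx, ny), "csi"))
  list(g = g, vol = vol, reg = reg, cyl = cyl)
}

test_that("the median denoiser is the identity at radius 0 and removes impulses", {
  g <- small_geom(16, 8, 8)
  arr <- array(0.5, c(16, 8, 8))
  vol <- oct_volume(arr, g)
  expect_identical(denoise(vol, 0)$intensity, arr)
  expect_identical(denoise(vol, 2)$intensity, arr)  # constant unchanged
  arr2 <- arr; arr2[8, 4, 4] <- 5
  out <- denoise(oct_volume(arr2, g), 1)
  expect_equal(out$intensity[8, 4, 4], 0.5)
})

test_that("candidate selection hits its limits and classifies a two-level scene", {
  sc <- cylinder_scene()
  tiling <- tile_volume(sc$g, 1)
  ## p -> 0: the threshold collapses to the minimum intensity; on a scene
  ## with distinct values only the minimal voxel(s) survive
  grad <- sc$vol
  grad$intensity <- grad$intensity +
    array(seq(0, 1e-4, length.out = length(grad$intensity)),
          dim(grad$intensity))
  lo <- candidate_mask(grad, sc$reg, 1e-4, tiling)
  expect_lte(sum(lo), 1L)
  hi <- candidate_mask(sc$vol, sc$reg, 99.999, tiling)
  expect_equal(sum(hi), 40L * 40L * 40L)  # the whole region
  ## a percentile below the vessel fraction classifies the two-level scene
  ## exactly
  cand <- candidate_mask(sc$vol, sc$reg, 3, tiling)
  expect_identical(c(cand), c(sc$cyl))
})

test_that("cone votes concentrate on the cylinder centerline", {
  sc <- cylinder_scene(radius = 4)
  tiling <- tile_volume(sc$g, 1)
  cand <- candidate_mask(sc$vol, sc$reg, 3, tiling)
  expect_equal(sum(cone_vote(sc$vol, sc$reg, array(FALSE, dim(cand)))), 0)
  acc <- cone_vote(sc$vol, sc$reg, cand, g0 = 1e-6)
  expect_true(all(acc[!cand] == 0))  # votes land in candidates only
  top <- which(acc >= max(acc) * 0.999)
  d <- dim(acc)
  z <- (top - 1) %% d[1] + 1
  y <- (top - 1) %/% (d[1] * d[2]) + 1
  ## argmax voxels within 1 voxel of the true centerline (z = 20, y = 20)
  expect_true(all(sqrt((z - 20)^2 + (y - 20)^2) <= sqrt(2) + 1e-9))
})

test_that("votes from separated cylinders never mix", {
  g <- small_geom(40, 30, 80)
  c1 <- make_cylinder(c(40, 30, 80), 20, 15, 3)
  c2 <- make_cylinder(c(40, 30, 80), 20, 65, 3)
  arr <- array(1, c(40, 30, 80)); arr[c1 | c2] <- 0.25
  vol <- oct_volume(arr, g)
  reg <- choroid_region(surface_map(matrix(0L, 30, 80), "rbc"),
                        surface_map(matrix(40L, 30, 80), "csi"))
  cand <- c1 | c2
  acc <- cone_vote(vol, reg, cand, L = 12, g0 = 1e-6)
  ## centres are 50 voxels apart, > 2L: support splits into two components
  vm <- label_components(acc > 0)
  expect_equal(nrow(vm$components), 2L)
  expect_true(all(acc[, , 30:50] == 0))
})

test_that("core extraction is nested in the vote quantile and handles empty input", {
  sc <- cylinder_scene(radius = 4)
  tiling <- tile_volume(sc$g, 1)
  cand <- candidate_mask(sc$vol, sc$reg, 3, tiling)
  acc <- cone_vote(sc$vol, sc$reg, cand, g0 = 1e-6)
  c50 <- extract_cores(acc, cand, 50)
  c95 <- extract_cores(acc, cand, 95)
  expect_true(all(!c95 | c50))  # nestedness
  ## q = 50 cores contain the centerline and form one component
  ctr <- make_cylinder(dim(cand), 20, 20, 0.1)
  expect_true(all(c50[ctr]))
  expect_equal(nrow(label_components(c50)$components), 1L)
  expect_equal(sum(extract_cores(array(0, dim(cand)), cand, 50)), 0L)
})

test_that("geodesic dilation matches a brute-force flood fill", {
  sc <- cylinder_scene(radius = 3, nz = 24, nx = 16, ny = 24, z0 = 12, y0 = 12)
  cand <- sc$cyl
  ctr <- make_cylinder(dim(cand), 12, 12, 0.1)
  expect_identical(dilate_cores(ctr, cand, 0), ctr)  # identity at 0
  grown <- dilate_cores(ctr, cand, 10)
  expect_identical(c(grown), c(flood_oracle(ctr, cand)))
  expect_identical(c(grown), c(cand))  # fills the whole cylinder
  expect_identical(c(dilate_cores(cand, cand, 5)), c(cand))  # fixed point
})

test_that("component labelling counts voxels and surface voxels exactly", {
  a <- array(FALSE, c(9, 9, 9))
  a[4:6, 4:6, 4:6] <- TRUE
  vm <- label_components(a)
  expect_equal(vm$components$n_voxels, 27L)
  expect_equal(vm$components$n_surface, 26L)  # only the centre is interior

  b <- array(FALSE, c(9, 9, 9))
  b[3:7, 3:7, 3:7] <- TRUE
  vmb <- label_components(b)
  expect_equal(vmb$components$n_voxels, 125L)
  expect_equal(vmb$components$n_surface, 98L)  # 125 - 27 interior

  ## diagonal contact joins under 26-connectivity
  d <- array(FALSE, c(4, 4, 4))
  d[1, 1, 1] <- TRUE; d[2, 2, 2] <- TRUE
  expect_equal(nrow(label_components(d)$components), 1L)
})

test_that("surface voxel counts agree with the shift oracle on spheres", {
  for (r in c(3, 5)) {
    sp <- make_sphere(c(15, 15, 15), c(8, 8, 8), r)
    vm <- label_components(sp)
    expect_equal(vm$components$n_surface, sum(surface_oracle(sp)))
    expect_equal(vm$components$n_voxels, sum(sp))
  }
})

test_that("noise removal drops sub-threshold components only", {
  a <- array(FALSE, c(10, 10, 10))
  pts <- cbind(c(1, 3, 5, 7, 9), c(1, 3, 5, 7, 9), c(1, 3, 5, 7, 9))
  a[pts] <- TRUE
  expect_equal(sum(remove_noise(label_components(a), 2)$mask), 0L)
  b <- a
  b[4:6, 1:3, 7:9] <- TRUE  # a 27-voxel cube among singletons
  vmb <- remove_noise(label_components(b), 2)
  expect_equal(sum(vmb$mask), 27L)
  expect_equal(nrow(vmb$components), 1L)
  expect_identical(remove_noise(label_components(a), 1)$mask, a)  # identity
})

test_that("the segmentation pipeline stays inside the choroid region", {
  cfg <- tiny_phantom_cfg()
  ph <- generate_phantom(cfg, seed = 3)
  res <- analyze_volume(ph$volume, cfg)
  rm3 <- choroidlayers:::region_mask(res$region, cfg$n_depth)
  expect_true(all(!res$vessel_mask$mask | rm3))
})
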