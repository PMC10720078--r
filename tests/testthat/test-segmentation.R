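test_that("threshold window is inclusive at both bounds", {
  vol <- image_volume(array(c(-900, -200, 300, 500, 501, -1000, 0, 499),
                            dim = c(2, 2, 2)), c(1, 1, 1))
  m <- threshold_mask(vol)
  expect_identical(as.logical(m$voxels[1:5]), c(FALSE, TRUE, TRUE, TRUE, FALSE))
  # uniform -1000 volume -> empty mask
  m2 <- threshold_mask(image_volume(array(-1000, c(3, 3, 3)), c(1, 1, 1)))
  expect_false(any(m2$voxels))
})

test_that("threshold foreground count equals a brute-force voxel loop", {
  set.seed(21)
  arr <- array(round(runif(125, -1000, 1000)), dim = c(5, 5, 5))
  vol <- image_volume(arr, c(1, 1, 1))
  m <- threshold_mask(vol)
  count <- 0L
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    if (arr[i, j, k] >= -200 && arr[i, j, k] <= 500) count <- count + 1L
  expect_identical(sum(m$voxels), count)
})

test_that("threshold widening is monotone", {
  set.seed(22)
  vol <- image_volume(array(round(runif(216, -1000, 1000)), dim = c(6, 6, 6)),
                      c(1, 1, 1))
  m1 <- threshold_mask(vol, segmentation_config(hu_lo = -100, hu_hi = 400))
  m2 <- threshold_mask(vol, segmentation_config(hu_lo = -200, hu_hi = 500))
  expect_true(all(m2$voxels[m1$voxels]))
})

test_that("crop_roi clears exactly the foreground outside the box", {
  full <- binary_mask(array(TRUE, c(10, 10, 10)), c(1, 1, 1))
  same <- crop_roi(full, roi_box(c(-1, -1, -1), c(10, 10, 10)))
  expect_identical(same$voxels, full$voxels)
  half <- crop_roi(full, roi_box(c(-0.5, -0.5, -0.5), c(4.4, 9.5, 9.5)))
  expect_identical(sum(half$voxels), 500L)
  # random mask, random box, brute force predicate
  set.seed(23)
  mk <- binary_mask(array(runif(1000) > 0.5, c(10, 10, 10)), c(1, 1, 1),
                    origin = c(-2, 0, 1))
  box <- roi_box(c(-1.2, 2.3, 1.7), c(4.9, 7.1, 8.2))
  got <- crop_roi(mk, box)
  want <- 0
  for (i in 0:9) for (j in 0:9) for (k in 0:9) {
    w <- c(-2, 0, 1) + c(i, j, k)
    if (mk$voxels[i + 1, j + 1, k + 1] &&
        all(w >= box$min) && all(w <= box$max)) want <- want + 1
  }
  expect_identical(sum(got$voxels), as.integer(want))
  expect_warning(crop_roi(mk, roi_box(c(100, 100, 100), c(110, 110, 110))),
                 "does not intersect")
})

test_that("region growing returns exactly the seed's component", {
  arr <- array(FALSE, c(12, 12, 12))
  arr[2:4, 2:4, 2:4] <- TRUE     # cube A
  arr[8:10, 8:10, 8:10] <- TRUE  # cube B, disjoint
  m <- binary_mask(arr, c(1, 1, 1))
  grown <- region_grow(m, c(2, 2, 2))
  expect_identical(sum(grown$voxels), 27L)
  expect_true(all(which(grown$voxels, arr.ind = TRUE) <= 4))
  grownB <- region_grow(m, c(8, 8, 8))
  expect_identical(sum(grownB$voxels), 27L)
  expect_true(all(which(grownB$voxels, arr.ind = TRUE) >= 8))
  expect_error(region_grow(m, c(6, 6, 6)), "background")
})

test_that("region growing is idempotent, seed-invariant and a subset", {
  set.seed(24)
  arr <- array(runif(16^3) > 0.6, c(16, 16, 16))
  m <- binary_mask(arr, c(1, 1, 1))
  seedv <- which(arr, arr.ind = TRUE)[1, ] - 1
  g1 <- region_grow(m, as.numeric(seedv))
  expect_true(all(arr[g1$voxels]))                 # subset of input
  g2 <- region_grow(g1, as.numeric(seedv))
  expect_identical(g1$voxels, g2$voxels)           # idempotent
  # any other seed inside the same component gives the same output
  inside <- which(g1$voxels, arr.ind = TRUE)
  other <- inside[nrow(inside), ] - 1
  g3 <- region_grow(m, as.numeric(other))
  expect_identical(g1$voxels, g3$voxels)
})

test_that("segment_vessel recovers the phantom and drops detached clutter", {
  rp <- cylinder_phantom(radius = 8, length = 40, spacing = 1)
  va <- rp$truth$tubes[[1]]$volume
  m <- segment_vessel(rp$volume, c(0, 0, 20))
  vm <- sum(m$voxels) * prod(m$spacing)
  expect_lt(abs(vm - va) / va, 0.03)
  # add a detached 350-HU cube: excluded by connectivity
  vol2 <- rp$volume
  vol2$voxels[2:4, 2:4, 2:4] <- 350
  m2 <- segment_vessel(vol2, c(0, 0, 20))
  expect_identical(sum(m2$voxels), sum(m$voxels))
  expect_false(any(m2$voxels[2:4, 2:4, 2:4]))
  # seeding inside the cube returns only the cube
  cube_seed <- voxel_to_world(vol2, c(2, 2, 2))
  m3 <- segment_vessel(vol2, cube_seed)
  expect_identical(sum(m3$voxels), 27L)
})

test_that("noisy phantoms are still segmented with high Dice", {
  rp <- cylinder_phantom(radius = 8, length = 40, spacing = 1,
                         noise_sd = 50, seed = 7)
  m <- segment_vessel(rp$volume, c(0, 0, 20))
  truth <- rp$lumen_mask$voxels
  got <- m$voxels
  dice <- 2 * sum(truth & got) / (sum(truth) + sum(got))
  expect_gt(dice, 0.97)
})

test_that("seed-deviation mode and config validation behave", {
  rp <- cylinder_phantom(radius = 6, length = 20, spacing = 1)
  # deviation wide enough to keep the partial-volume boundary shell
  cfg <- segmentation_config(mode = "seed-deviation", seed_deviation = 700)
  m <- segment_vessel(rp$volume, c(0, 0, 10), config = cfg)
  va <- rp$truth$tubes[[1]]$volume
  expect_lt(abs(sum(m$voxels) - va) / va, 0.05)
  expect_error(segmentation_config(hu_lo = 10, hu_hi = 10), "hu_lo")
  expect_error(segmentation_config(connectivity = 4), "connectivity")
  expect_error(segmentation_config(mode = "seed-deviation"), "seed_deviation")
})
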