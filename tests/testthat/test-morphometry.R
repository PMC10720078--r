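# shared phantoms for the measurement tests
cyl_rp <- cylinder_phantom(radius = 8, length = 40, spacing = 1)
cyl_mask <- segment_vessel(cyl_rp$volume, c(0, 0, 20))
cyl_tree <- extract_tree(skeletonize(cyl_mask))

test_that("cross-sectional area of a cylinder matches the circle", {
  # partial-volume (fractional) mask: sub-voxel boundary accuracy
  a <- cross_section_area(cyl_rp$fraction, c(0, 0, 20), c(0, 0, 1))
  expect_lt(abs(a - pi * 64) / (pi * 64), 0.02)
  # hard mask at 1 mm voxels (8-voxel radius): voxel-limited accuracy
  ab <- cross_section_area(cyl_mask, c(0, 0, 20), c(0, 0, 1))
  expect_lt(abs(ab - pi * 64) / (pi * 64), 0.07)
  # plane centered outside the vessel (but inside the grid) -> 0
  expect_identical(cross_section_area(cyl_mask, c(10, 5, 20), c(0, 0, 1)), 0)
  # tilted 45 degrees: ellipse, area = circle / cos(45)
  n45 <- c(sin(pi / 4), 0, cos(pi / 4))
  a45 <- cross_section_area(cyl_rp$fraction, c(0, 0, 20), n45)
  expect_lt(abs(a45 - pi * 64 / cos(pi / 4)) / (pi * 64 / cos(pi / 4)), 0.05)
  expect_error(cross_section_area(cyl_mask, c(500, 0, 0), c(0, 0, 1)),
               "outside")
  expect_error(cross_section_area(cyl_mask, c(0, 0, 20), c(0, 0, 2)), "unit")
})

test_that("area profiles are flat for constant radius, monotone for taper", {
  prof <- area_profile(cyl_mask, cyl_tree$branches$trunk,
                       measurement_config(), trim = "both")
  expect_lt(max(prof$areas) / min(prof$areas), 1.05)
  # linear taper 8 -> 5 mm: areas decrease along arclength (2% ripple allowed)
  tspec <- phantom_spec(list(tube_spec(
    straight_segment(c(0, 0, 0), c(0, 0, 40)), 8, radius_end = 5)),
    spacing = c(1, 1, 1))
  trp <- rasterize_phantom(tspec)
  tm <- segment_vessel(trp$volume, c(0, 0, 20))
  ttree <- extract_tree(skeletonize(tm))
  tprof <- area_profile(tm, ttree$branches$trunk, measurement_config(),
                        trim = "both")
  a <- tprof$areas
  ok <- a[-1] <= a[-length(a)] * 1.02
  expect_true(all(ok))
  expect_error(area_profile(cyl_mask, cyl_tree$branches$trunk,
                            measurement_config(exclusion_margin = 100)),
               "exclusion margin")
})

test_that("volume_from_profile uses local control spacing", {
  prof <- structure(list(arclengths = c(0, 1, 2), areas = c(100, 100, 100),
                         extent = 3), class = "cross_section_profile")
  expect_equal(volume_from_profile(prof), 300)
  expect_error(volume_from_profile(structure(
    list(arclengths = numeric(0), areas = numeric(0)),
    class = "cross_section_profile")), "empty")
  # cylinder volume over the trimmed extent within 3 %
  prof2 <- area_profile(cyl_rp$fraction, cyl_tree$branches$trunk,
                        measurement_config(), trim = "both")
  v <- volume_from_profile(prof2)
  expect_lt(abs(v - pi * 64 * prof2$extent) / (pi * 64 * prof2$extent), 0.03)
})

test_that("volume is additive when a profile is split", {
  prof <- area_profile(cyl_mask, cyl_tree$branches$trunk,
                       measurement_config(), trim = "both")
  n <- length(prof$arclengths)
  m <- n %/% 2
  sub <- function(idx) structure(list(arclengths = prof$arclengths[idx],
                                      areas = prof$areas[idx]),
                                 class = "cross_section_profile")
  v_whole <- volume_from_profile(prof)
  v_split <- volume_from_profile(sub(1:m)) + volume_from_profile(sub((m + 1):n))
  expect_lt(abs(v_whole - v_split) / v_whole, 0.005)
})

test_that("MIP diameter recovers the cylinder diameter in both orientations", {
  # axis along z (perpendicular to the axial plane)
  d <- diameter_mip(cyl_rp$volume, cyl_mask, cyl_tree, "MPA",
                    measurement_config(diameter_offset = 15))
  expect_lt(abs(d - 16), 1)
  # axis inside the axial plane (along x)
  spec <- phantom_spec(list(tube_spec(
    straight_segment(c(0, 0, 0), c(40, 0, 0)), 8)), spacing = c(1, 1, 1))
  rp2 <- rasterize_phantom(spec)
  m2 <- segment_vessel(rp2$volume, c(20, 0, 0))
  tr2 <- extract_tree(skeletonize(m2))
  d2 <- diameter_mip(rp2$volume, m2, tr2, "MPA",
                     measurement_config(diameter_offset = 15))
  expect_lt(abs(d2 - 16), 1)
  expect_error(diameter_mip(cyl_rp$volume, cyl_mask, cyl_tree, "MPA",
                            measurement_config(diameter_offset = 100)),
               "offset")
})

test_that("measure_all fills all nine fields within tolerance on a PA tree", {
  rp <- pa_tree_phantom(spacing = 1)
  mask <- segment_vessel(rp$volume, c(0, 0, 30))
  tr <- extract_tree(skeletonize(mask), centerline_config(), seed = c(0, 0, 10))
  meas <- measure_all(rp$volume, mask, tr)
  ta <- c(pi * 18^2, pi * 12^2, pi * 12^2)
  ga <- c(meas$a_mpa, meas$a_rpa, meas$a_lpa)
  expect_true(all(abs(ga - ta) / ta < 0.03))
  ex <- attr(meas, "extents")
  vt <- vapply(c("mpa", "rpa", "lpa"),
               function(k) ex[[k]][["extent"]], numeric(1))
  gv <- c(meas$v_mpa, meas$v_rpa, meas$v_lpa)
  expect_true(all(abs(gv - ta * vt) / (ta * vt) < 0.05))
  gd <- c(meas$d_mpa, meas$d_rpa, meas$d_lpa)
  expect_true(all(abs(gd - c(36, 24, 24)) / c(36, 24, 24) < 0.03))
})

test_that("single-branch trees fill only the MPA fields", {
  meas <- measure_all(cyl_rp$volume, cyl_mask, cyl_tree,
                      measurement_config(diameter_offset = 15))
  expect_true(is.finite(meas$d_mpa) && is.finite(meas$a_mpa) &&
                is.finite(meas$v_mpa))
  expect_true(all(is.na(c(meas$d_rpa, meas$a_rpa, meas$v_rpa,
                          meas$d_lpa, meas$a_lpa, meas$v_lpa))))
})

test_that("measurements are invariant under whole-voxel translation", {
  # embed the phantom twice in one enlarged grid, at offsets differing by a
  # whole-voxel shift, so the voxel lattice (and any index tie-breaking) is
  # shared by both copies
  cfg <- measurement_config(diameter_offset = 15)
  d <- dim(cyl_mask$voxels)
  shift <- c(2L, 3L, 1L)
  embed <- function(arr, off, fill) {
    big <- array(fill, d + 5L)
    big[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]),
        off[3] + seq_len(d[3])] <- arr
    big
  }
  run <- function(off) {
    vol <- image_volume(embed(cyl_rp$volume$voxels, off, -850),
                        cyl_rp$volume$spacing, cyl_rp$volume$origin)
    mask <- binary_mask(embed(cyl_mask$voxels, off, FALSE),
                        cyl_mask$spacing, cyl_mask$origin)
    measure_all(vol, mask, extract_tree(skeletonize(mask)), cfg)
  }
  m1 <- run(c(0L, 0L, 0L))
  m2 <- run(shift)
  # section samples landing exactly on half-voxel boundaries flip with
  # last-ulp coordinate differences; anything beyond that is invariant
  for (k in c("d_mpa", "a_mpa", "v_mpa"))
    expect_equal(m2[[k]], m1[[k]], tolerance = 2e-3)
})

test_that("profile volume agrees with lumen voxel counting over one extent", {
  prof <- area_profile(cyl_mask, cyl_tree$branches$trunk,
                       measurement_config(), trim = "both")
  v_prof <- volume_from_profile(prof)
  # voxel-count volume over the same axial extent (cylinder axis = z)
  zlo <- min(prof$arclengths) + cyl_tree$branches$trunk$points[1, 3] -
    prof$arclengths[1] - (prof$arclengths[2] - prof$arclengths[1]) / 2
  zhi <- zlo + prof$extent
  zc <- cyl_mask$origin[3] + (seq_len(dim(cyl_mask$voxels)[3]) - 1) *
    cyl_mask$spacing[3]
  sel <- zc >= zlo & zc < zhi
  v_count <- sum(cyl_mask$voxels[, , sel]) * prod(cyl_mask$spacing)
  expect_lt(abs(v_prof - v_count) / v_count, 0.03)
})
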