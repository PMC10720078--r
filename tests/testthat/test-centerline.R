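# one shared Y-tree per file: extraction is the expensive step
tree_rp <- pa_tree_phantom(spacing = 1)
tree_mask <- segment_vessel(tree_rp$volume, c(0, 0, 30))
tree_skel <- skeletonize(tree_mask)

test_that("cylinder skeleton follows the axis within one voxel", {
  rp <- cylinder_phantom(radius = 8, length = 40, spacing = 1)
  m <- segment_vessel(rp$volume, c(0, 0, 20))
  sk <- skeletonize(m)
  g <- sk$graph
  xy <- cbind(igraph::V(g)$x, igraph::V(g)$y)
  expect_lt(max(abs(xy)), 1 + 1e-9)
  # single path: all degrees <= 2, two endpoints
  deg <- igraph::degree(g)
  expect_true(all(deg <= 2))
  expect_identical(sum(deg == 1), 2L)
})

test_that("degenerate blobs skeletonize without crashing", {
  cube <- binary_mask(array(TRUE, c(3, 3, 3)), c(1, 1, 1))
  sk <- skeletonize(cube, closing = 0)
  expect_lte(igraph::vcount(sk$graph), 3)
  expect_error(skeletonize(binary_mask(array(FALSE, c(3, 3, 3)), c(1, 1, 1))),
               "empty")
  two <- array(FALSE, c(10, 10, 10)); two[2:3, 2:3, 2:3] <- TRUE
  two[7:8, 7:8, 7:8] <- TRUE
  expect_error(skeletonize(binary_mask(two, c(1, 1, 1))), "components")
})

test_that("Y-tree skeleton has exactly one junction after pruning", {
  g <- pamorph:::.merge_junctions(
    pamorph:::.prune_spurs(tree_skel$graph, 5), 5)
  deg <- igraph::degree(g)
  expect_identical(sum(deg >= 3), 1L)
  expect_identical(sum(deg == 1), 3L)
})

test_that("a path graph yields a single branch and no bifurcation", {
  rp <- cylinder_phantom(radius = 6, length = 30, spacing = 1)
  m <- segment_vessel(rp$volume, c(0, 0, 15))
  tr <- extract_tree(skeletonize(m))
  expect_named(tr$branches, "trunk")
  expect_null(tr$bifurcation)
})

test_that("bifurcation lands within two voxel diagonals of the truth", {
  tr <- extract_tree(tree_skel, centerline_config(), seed = c(0, 0, 10))
  expect_named(tr$branches, c("trunk", "child_1", "child_2"))
  expect_lt(sqrt(sum((tr$bifurcation - c(0, 0, 60))^2)), 2 * sqrt(3))
  # children start within a voxel diagonal of the bifurcation
  for (ch in c("child_1", "child_2"))
    expect_lt(sqrt(sum((tr$branches[[ch]]$points[1, ] - tr$bifurcation)^2)),
              sqrt(3) + 1e-9)
  # RPA analog (child_1) lies on the smaller-x side
  expect_lt(mean(tr$branches$child_1$points[, 1]),
            mean(tr$branches$child_2$points[, 1]))
})

test_that("short spurs are pruned without changing the branch count", {
  arr <- tree_mask$voxels
  # attach a 3 mm one-voxel-wide spur to the trunk surface (anchor one voxel
  # inside the lumen so the spur is connected)
  idx <- world_to_voxel(tree_mask, c(17, 0, 30)) + 1
  stopifnot(arr[idx[1], idx[2], idx[3]])
  arr[idx[1] + (1:4), idx[2], idx[3]] <- TRUE
  m2 <- binary_mask(arr, tree_mask$spacing, tree_mask$origin)
  tr0 <- extract_tree(tree_skel, centerline_config(), seed = c(0, 0, 10))
  tr2 <- extract_tree(skeletonize(m2), centerline_config(), seed = c(0, 0, 10))
  expect_identical(length(tr2$branches), length(tr0$branches))
})

test_that("smooth_resample keeps straight lines straight and counts points", {
  tt <- seq(0, 20, by = 0.7)
  path <- cbind(1 + 2 * tt, 3 - tt, 0.5 * tt)
  for (f in c(0, 0.5, 1)) {
    cl <- smooth_resample(path, centerline_config(smoothing_factor = f))
    d <- cl$points - cl$points[rep(1, nrow(cl$points)), ]
    dir <- c(2, -1, 0.5) / sqrt(sum(c(2, -1, 0.5)^2))
    perp <- d - outer(as.numeric(d %*% dir), dir)
    expect_lt(max(abs(perp)), 1e-6)
  }
  straight <- cbind(0, 0, seq(0, 10, by = 0.5))
  cl <- smooth_resample(straight, centerline_config())
  expect_identical(nrow(cl$points), 11L)
  expect_equal(cl$arclengths, 0:10, tolerance = 1e-9)
  expect_equal(cl$tangents[5, ], c(0, 0, 1), tolerance = 1e-9)
  expect_error(smooth_resample(cbind(0, 0, c(0, 1)),
                               centerline_config(control_spacing = 5)),
               "shorter")
})

test_that("smoothing a jittered arc reduces RMS error and total curvature", {
  set.seed(31)
  th <- seq(0, pi / 3, length.out = 90)
  R <- 30
  path <- cbind(R * cos(th) + rnorm(90, 0, 0.3),
                R * sin(th) + rnorm(90, 0, 0.3),
                rnorm(90, 0, 0.3))
  rms <- function(p) sqrt(mean((sqrt(p[, 1]^2 + p[, 2]^2 + p[, 3]^2) - R)^2))
  cl <- smooth_resample(path, centerline_config(smoothing_factor = 0.5))
  expect_lt(rms(cl$points), rms(path))
  raw_turn <- total_turning(path)
  for (f in c(0.25, 0.5, 1)) {
    cl <- smooth_resample(path, centerline_config(smoothing_factor = f))
    expect_lte(total_turning(cl$points), raw_turn + 1e-9)
  }
})

test_that("branch arclengths match the analytic tube lengths", {
  rp <- cylinder_phantom(radius = 8, length = 40, spacing = 1)
  m <- segment_vessel(rp$volume, c(0, 0, 20))
  tr <- extract_tree(skeletonize(m))
  expect_lt(abs(max(tr$branches$trunk$arclengths) - 40) / 40, 0.02)
  arc <- circular_arc(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0),
                      arc_radius = 60, arc_angle = pi / 2)
  spec <- phantom_spec(list(tube_spec(arc, 8)), spacing = c(1, 1, 1))
  rpa <- rasterize_phantom(spec)
  seedp <- as.numeric(curve_point(arc, 40))
  ma <- segment_vessel(rpa$volume, seedp)
  tra <- extract_tree(skeletonize(ma), centerline_config(), seed = seedp)
  expect_lt(abs(max(tra$branches$trunk$arclengths) - arc$length) / arc$length,
            0.03)
})

test_that("tree extraction is equivariant under whole-voxel translation", {
  rp <- cylinder_phantom(radius = 6, length = 24, spacing = 1)
  m <- segment_vessel(rp$volume, c(0, 0, 12))
  d <- dim(m$voxels)
  shift <- c(3L, 2L, 4L)
  big <- array(FALSE, d + shift)
  big[shift[1] + seq_len(d[1]), shift[2] + seq_len(d[2]),
      shift[3] + seq_len(d[3])] <- m$voxels
  m2 <- binary_mask(big, m$spacing, m$origin)
  tr1 <- extract_tree(skeletonize(m))
  tr2 <- extract_tree(skeletonize(m2))
  p1 <- tr1$branches$trunk$points
  p2 <- tr2$branches$trunk$points
  expect_equal(nrow(p1), nrow(p2))
  expect_equal(p2, t(t(p1) + shift * m$spacing), tolerance = 1e-6)
})
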