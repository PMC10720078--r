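#' Measurement configuration
#'
#' @param exclusion_margin arclength trimmed at the bifurcation end of every
#'   branch and at the trunk's valve end before area/volume integration (mm,
#'   default 5 -- roughly one branch radius).
#' @param mip_slab slab thickness of the axial maximum intensity projection
#'   used for the 1D diameter (mm, default 10).
#' @param diameter_offset distance from the bifurcation along each branch at
#'   which the 1D diameter and representative area are taken (mm, default 15;
#'   measured proximally for the trunk, distally for the children).
#' @param section_halfsize half-width of the resampled section plane (mm,
#'   default 30).
#' @param section_step in-plane sampling step of the section plane (mm,
#'   default 0.25).
#' @param hu_threshold in-lumen threshold on the MIP image (HU, default -200,
#'   the lower bound of the segmentation window).
#' @return A `measurement_config`.
#' @export
measurement_config <- function(exclusion_margin = 5, mip_slab = 10,
                               diameter_offset = 15, section_halfsize = 30,
                               section_step = 0.25, hu_threshold = -200) {
  vals <- c(exclusion_margin, mip_slab, diameter_offset, section_halfsize,
            section_step)
  if (any(vals <= 0)) stop("all measurement_config distances must be positive")
  structure(list(exclusion_margin = exclusion_margin, mip_slab = mip_slab,
                 diameter_offset = diameter_offset,
                 section_halfsize = section_halfsize,
                 section_step = section_step, hu_threshold = hu_threshold),
            class = "measurement_config")
}

# trilinear sample of a numeric 3D array at world points (outside -> 0)
.sample_linear <- function(arr, spacing, origin, pts) {
  d <- dim(arr)
  u <- t((t(pts) - origin) / spacing)        # continuous 0-based voxel coords
  i0 <- floor(u); w <- u - i0
  acc <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ii <- i0[, 1] + dx; jj <- i0[, 2] + dy; kk <- i0[, 3] + dz
    wt <- (if (dx) w[, 1] else 1 - w[, 1]) *
          (if (dy) w[, 2] else 1 - w[, 2]) *
          (if (dz) w[, 3] else 1 - w[, 3])
    ok <- ii >= 0 & ii < d[1] & jj >= 0 & jj < d[2] & kk >= 0 & kk < d[3] & wt > 0
    if (any(ok)) {
      lin <- ii[ok] + d[1] * (jj[ok] + d[2] * kk[ok]) + 1
      acc[ok] <- acc[ok] + wt[ok] * arr[lin]
    }
  }
  acc
}

.sample_nearest <- function(arr, spacing, origin, pts) {
  d <- dim(arr)
  idx <- .round_half_up(t((t(pts) - origin) / spacing))
  ok <- idx[, 1] >= 0 & idx[, 1] < d[1] & idx[, 2] >= 0 & idx[, 2] < d[2] &
        idx[, 3] >= 0 & idx[, 3] < d[3]
  out <- numeric(nrow(pts))
  if (any(ok)) {
    lin <- idx[ok, 1] + d[1] * (idx[ok, 2] + d[2] * idx[ok, 3]) + 1
    out[ok] <- as.numeric(arr[lin])
  }
  out
}

.orthonormal_frame <- function(normal) {
  n <- normal / sqrt(sum(normal^2))
  ref <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- c(n[2] * ref[3] - n[3] * ref[2],
         n[3] * ref[1] - n[1] * ref[3],
         n[1] * ref[2] - n[2] * ref[1])
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  list(n = n, u = u, v = v)
}

# in-plane lumen region through `point` orthogonal to `normal`: mask samples
# >= 0.5 (nearest for binary, trilinear for fractional masks), optionally
# restricted to samples whose radius-normalized distance to this branch's
# centerline is smaller than to any competitor branch (a radius-weighted
# Voronoi partition of the junction region), then reduced to the 8-connected
# region containing the center sample.
#
# `competitors` is a list of list(points = n-by-3 matrix, radius = scalar).
.section_region <- function(mask, point, normal, halfsize, step,
                            own_points = NULL, own_radius = 1,
                            competitors = NULL) {
  point <- as.numeric(point)
  fr <- .orthonormal_frame(normal)
  gg <- seq(-halfsize, halfsize, by = step)
  m <- length(gg)
  uv <- cbind(rep(gg, times = m), rep(gg, each = m))
  pts <- cbind(point[1] + uv[, 1] * fr$u[1] + uv[, 2] * fr$v[1],
               point[2] + uv[, 1] * fr$u[2] + uv[, 2] * fr$v[2],
               point[3] + uv[, 1] * fr$u[3] + uv[, 2] * fr$v[3])
  arr <- if (is.logical(mask$voxels))
    array(as.double(mask$voxels), dim = dim(mask$voxels)) else mask$voxels
  vals <- if (is.logical(mask$voxels))
    .sample_nearest(arr, mask$spacing, mask$origin, pts)
  else
    .sample_linear(arr, mask$spacing, mask$origin, pts)
  member <- vals >= 0.5
  if (!is.null(competitors) && !is.null(own_points) && any(member)) {
    reach <- halfsize * sqrt(2) + 2 * step
    nears <- lapply(competitors, function(cb)
      list(points = .points_within(cb$points, point, reach),
           radius = cb$radius %||% 1))
    nears <- nears[vapply(nears, function(x) nrow(x$points) > 0, logical(1))]
    if (length(nears) > 0) {
      idx <- which(member)
      ownn <- .points_within(own_points, point, reach + 10)
      do <- .min_dist(pts[idx, , drop = FALSE], ownn) / own_radius
      dc <- rep(Inf, length(idx))
      for (cb in nears)
        dc <- pmin(dc, .min_dist(pts[idx, , drop = FALSE], cb$points) / cb$radius)
      # samples within one radius of the measured branch's centerline belong
      # to its own tube and are never reassigned; beyond that, the nearer
      # branch wins, with a hysteresis favouring the branch being measured
      member[idx[do > 1 & dc < do - 0.1]] <- FALSE
    }
  }
  ctr <- (m %/% 2) * m + (m %/% 2) + 1   # gg is odd-length, 0 at the middle
  out <- list(member = member, m = m, uv = uv, ctr = ctr, step = step,
              region = rep(FALSE, m * m))
  if (!member[ctr]) return(out)
  plane <- array(member, dim = c(m, m, 1L))
  region <- cpp_flood(as.logical(plane), dim(plane),
                      c((ctr - 1) %% m, (ctr - 1) %/% m, 0L), 26L)
  out$region <- as.logical(region)
  out
}

.points_within <- function(pts, center, radius) {
  if (is.null(pts) || length(pts) == 0) return(matrix(numeric(0), 0, 3))
  pts <- as.matrix(pts)
  d2 <- (pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2 +
        (pts[, 3] - center[3])^2
  pts[d2 <= radius^2, , drop = FALSE]
}

.min_dist <- function(a, b) {
  if (nrow(b) == 0) return(rep(Inf, nrow(a)))
  out <- rep(Inf, nrow(a))
  for (j in seq_len(nrow(b))) {
    d2 <- (a[, 1] - b[j, 1])^2 + (a[, 2] - b[j, 2])^2 + (a[, 3] - b[j, 3])^2
    out <- pmin(out, d2)
  }
  sqrt(out)
}

#' Cross-sectional area on a plane through a point
#'
#' The mask is resampled on a square planar grid orthogonal to `normal`
#' through `point` (nearest-neighbor for a binary mask, trilinear for a
#' fractional mask); the area is the in-plane 8-connected region containing
#' the center sample, times the sampling step squared. Returns 0 when the
#' center sample is background. Near a junction, samples nearer a competitor
#' branch's centerline than this branch's are excluded before the region is
#' grown, so overlapping vessel sections are partitioned rather than double
#' counted.
#'
#' @param mask a [binary_mask()] (binary or fractional).
#' @param point world point on the centerline (mm).
#' @param normal unit section normal (the centerline tangent).
#' @param config a [measurement_config()].
#' @param own_points optional control points (n-by-3, mm) of this branch.
#' @param own_radius approximate lumen radius of this branch (mm), used to
#'   radius-normalize the partition distances.
#' @param competitors optional list of `list(points =, radius =)` describing
#'   the tree's other branches, enabling the junction partition.
#' @return area in mm^2.
#' @export
cross_section_area <- function(mask, point, normal,
                               config = measurement_config(),
                               own_points = NULL, own_radius = 1,
                               competitors = NULL) {
  point <- as.numeric(point)
  world_to_voxel(mask, point)   # bounds error if outside
  if (abs(sqrt(sum(normal^2)) - 1) > 1e-6) stop("`normal` must be a unit vector")
  sec <- .section_region(mask, point, normal, config$section_halfsize,
                         config$section_step, own_points, own_radius,
                         competitors)
  sum(sec$region) * config$section_step^2
}

#' Cross-sectional area profile along a branch
#'
#' One area per surviving control point, using the point's tangent as the
#' section normal. Control points within `exclusion_margin` of the trimmed
#' ends are dropped: both ends for the trunk (pulmonary valve and
#' bifurcation), the bifurcation (start) end only for children.
#'
#' @param mask a [binary_mask()].
#' @param branch a `centerline` (see [smooth_resample()]).
#' @param config a [measurement_config()].
#' @param trim which ends to trim: `"both"` (trunk), `"start"` (child),
#'   `"end"` or `"none"`.
#' @param competitors optional list describing the tree's other branches
#'   (each a `centerline`, an n-by-3 point matrix, or a
#'   `list(points =, radius =)`); their control points partition
#'   junction-region sections by the radius-normalized nearest-centerline
#'   rule.
#' @param own_radius approximate lumen radius of `branch` (mm) for the
#'   partition.
#' @param window optional `c(lo, hi)` arclength window (mm) overriding the
#'   `trim` rule, e.g. computed from a refined bifurcation location.
#' @return A `cross_section_profile`: `arclengths`, `areas`, `extent` (the
#'   covered arclength extent including the half-slab beyond each terminal
#'   control point, so that [volume_from_profile()] integrates over it).
#' @export
area_profile <- function(mask, branch, config = measurement_config(),
                         trim = c("both", "start", "end", "none"),
                         competitors = NULL, own_radius = 1, window = NULL) {
  trim <- match.arg(trim)
  s <- branch$arclengths
  S <- max(s)
  if (is.null(window)) {
    lo <- if (trim %in% c("both", "start")) config$exclusion_margin else 0
    hi <- if (trim %in% c("both", "end")) S - config$exclusion_margin else S
  } else {
    lo <- window[1]; hi <- window[2]
  }
  keep <- which(s >= lo - 1e-9 & s <= hi + 1e-9)
  if (length(keep) < 3)
    stop("fewer than 3 control points survive the exclusion margin")
  comp <- .competitor_list(competitors)
  areas <- vapply(keep, function(i)
    cross_section_area(mask, branch$points[i, ], branch$tangents[i, ], config,
                       own_points = branch$points, own_radius = own_radius,
                       competitors = comp),
    numeric(1))
  sk <- s[keep]
  n <- length(sk)
  extent <- (sk[n] - sk[1]) + (sk[2] - sk[1]) / 2 + (sk[n] - sk[n - 1]) / 2
  structure(list(arclengths = sk, areas = areas, extent = extent),
            class = "cross_section_profile")
}

#' Vessel volume from an area profile
#'
#' `V = sum A(s_i) * ds_i` with `ds_i` the local control-point spacing
#' (half the distance between the two flanking control points; terminal
#' points get their full adjacent interval). At 1 mm uniform control spacing
#' this reduces to the plain sum of the per-slice areas.
#'
#' @param profile a `cross_section_profile`.
#' @return volume in mm^3.
#' @export
volume_from_profile <- function(profile) {
  s <- profile$arclengths; a <- profile$areas
  n <- length(s)
  if (n == 0) stop("empty profile")
  if (n == 1) stop("profile needs at least 2 points to define a spacing")
  ds <- numeric(n)
  ds[1] <- s[2] - s[1]
  ds[n] <- s[n] - s[n - 1]
  if (n > 2) ds[2:(n - 1)] <- (s[3:n] - s[1:(n - 2)]) / 2
  sum(a * ds)
}

# normalize the various accepted competitor forms to list(points, radius)
.competitor_list <- function(competitors) {
  if (is.null(competitors) || length(competitors) == 0) return(NULL)
  if (inherits(competitors, "centerline")) competitors <- list(competitors)
  lapply(competitors, function(b) {
    if (inherits(b, "centerline")) list(points = b$points, radius = 1)
    else if (is.list(b) && !is.null(b$points))
      list(points = as.matrix(b$points), radius = b$radius %||% 1)
    else list(points = as.matrix(b), radius = 1)
  })
}

# robust local lumen radius of a branch: median circular-equivalent radius of
# plain (unpartitioned) sections at mid-branch quantiles
.branch_radius <- function(mask, branch, config) {
  S <- max(branch$arclengths)
  qs <- S * c(0.35, 0.45, 0.5, 0.55, 0.65)
  areas <- vapply(qs, function(sq) {
    i <- which.min(abs(branch$arclengths - sq))
    cross_section_area(mask, branch$points[i, ], branch$tangents[i, ], config)
  }, numeric(1))
  sqrt(median(areas) / pi)
}

# total least-squares intersection of the branch axes: fit a line to a clear
# segment of each branch near the junction and find the point minimizing the
# summed squared distance to the lines
.fit_line <- function(pts) {
  ctr <- colMeans(pts)
  d <- prcomp(pts)$rotation[, 1]
  list(c = ctr, d = d / sqrt(sum(d^2)))
}

.refine_bifurcation <- function(branches, bif_raw, offset = 15) {
  # fit windows scale with the measurement offset: the junction-distorted
  # zone extends roughly one trunk radius along each branch
  lo <- 2 / 3 * offset; hi <- 5 / 3 * offset; hi_t <- 8 / 15 * offset
  lines <- list()
  tr <- branches$trunk
  if (!is.null(tr)) {
    S <- max(tr$arclengths)
    w <- tr$arclengths >= S - hi & tr$arclengths <= S - hi_t
    if (sum(w) >= 5) lines$trunk <- .fit_line(tr$points[w, , drop = FALSE])
  }
  for (ch in grep("^child_", names(branches), value = TRUE)) {
    b <- branches[[ch]]
    w <- b$arclengths >= lo & b$arclengths <= hi
    if (sum(w) >= 5) lines[[ch]] <- .fit_line(b$points[w, , drop = FALSE])
  }
  if (length(lines) < 2) return(bif_raw)
  A <- matrix(0, 3, 3); bb <- rep(0, 3)
  for (ln in lines) {
    P <- diag(3) - tcrossprod(ln$d)
    A <- A + P
    bb <- bb + P %*% ln$c
  }
  x <- tryCatch(as.numeric(solve(A, bb)), error = function(e) NULL)
  if (is.null(x) || is.null(bif_raw)) return(x %||% bif_raw)
  if (sqrt(sum((x - bif_raw)^2)) > 2 / 3 * offset) bif_raw else x
}

# signed arclength coordinate of the projection of `point` onto the branch
.arclength_anchor <- function(branch, point) {
  d2 <- rowSums(t(t(branch$points) - as.numeric(point))^2)
  i <- which.min(d2)
  branch$arclengths[i] +
    sum((as.numeric(point) - branch$points[i, ]) * branch$tangents[i, ])
}

# interpolate a centerline at an exact arclength
.branch_at <- function(branch, s) {
  p <- vapply(1:3, function(j)
    approx(branch$arclengths, branch$points[, j], xout = s, ties = "ordered")$y,
    numeric(1))
  tg <- vapply(1:3, function(j)
    approx(branch$arclengths, branch$tangents[, j], xout = s, ties = "ordered")$y,
    numeric(1))
  list(point = p, tangent = tg / sqrt(sum(tg^2)))
}

.artery_branch <- function(tree, artery) {
  switch(artery, MPA = "trunk", RPA = "child_1", LPA = "child_2",
         stop("unknown artery: ", artery))
}

# measurement arclength: children are measured `offset` distal to the
# bifurcation; the trunk ends at the bifurcation, so its point lies `offset`
# proximal to it. `anchor` is the (refined) bifurcation's arclength
# coordinate on this branch; without one the branch end stands in for it.
.measurement_arclength <- function(branch, artery, config, anchor = NULL) {
  S <- max(branch$arclengths)
  s <- if (artery == "MPA") (anchor %||% S) - config$diameter_offset
       else (anchor %||% 0) + config$diameter_offset
  if (s < 0 || s > S)
    stop("branch shorter than the measurement offset (",
         round(S, 1), " mm vs offset ", config$diameter_offset, " mm)")
  s
}

#' Vessel diameter on an axial slab MIP
#'
#' Builds an axial maximum intensity projection over a `mip_slab`-thick slab
#' centered at the measurement point (`diameter_offset` from the bifurcation
#' along the artery), then measures the in-lumen chord through the point
#' perpendicular to the branch's in-plane long-axis direction. Lumen
#' membership on the MIP is `HU >= hu_threshold` with bilinear, sub-pixel
#' boundary interpolation.
#'
#' @param volume the HU [image_volume()].
#' @param mask unused by the measurement itself, accepted for interface
#'   symmetry (may be `NULL`).
#' @param tree a `centerline_tree`.
#' @param artery `"MPA"`, `"RPA"` or `"LPA"`.
#' @param config a [measurement_config()].
#' @return diameter in mm.
#' @export
diameter_mip <- function(volume, mask, tree, artery = c("MPA", "RPA", "LPA"),
                         config = measurement_config()) {
  artery <- match.arg(artery)
  bname <- .artery_branch(tree, artery)
  branch <- tree$branches[[bname]]
  if (is.null(branch)) stop("tree has no ", bname, " branch for ", artery)
  s0 <- .measurement_arclength(branch, artery, config, tree$anchors[[bname]])
  p0 <- .branch_at(branch, s0)$point

  d <- dim(volume$voxels)
  kz <- .round_half_up((p0[3] + c(-1, 1) * config$mip_slab / 2 -
                          volume$origin[3]) / volume$spacing[3])
  kz <- pmin(pmax(kz, 0), d[3] - 1)
  mip <- apply(volume$voxels[, , (kz[1]:kz[2]) + 1, drop = FALSE], c(1, 2), max)

  step <- min(volume$spacing[1:2]) / 8
  chord_at <- function(s) {
    at <- .branch_at(branch, s)
    p <- at$point
    # chord direction: perpendicular (in-plane) to the branch's long axis
    axis2d <- at$tangent[1:2]
    if (sqrt(sum(axis2d^2)) < 0.2) {
      w <- c(1, 0)  # branch nearly perpendicular to the axial plane: circular
    } else {
      axis2d <- axis2d / sqrt(sum(axis2d^2))
      w <- c(-axis2d[2], axis2d[1])
    }
    sample_mip <- function(tvals) {
      q <- cbind(p[1] + tvals * w[1], p[2] + tvals * w[2])
      .bilinear2d(mip, volume$spacing[1:2], volume$origin[1:2], q)
    }
    half_chord <- function(dir) {
      tmax <- 2 * config$section_halfsize
      tv <- seq(0, tmax, by = step)
      vals <- sample_mip(dir * tv)
      out <- which(vals < config$hu_threshold)
      if (length(out) == 0) return(tmax)
      k <- out[1]
      if (k == 1) return(0)
      # sub-pixel crossing between samples k-1 and k
      v0 <- vals[k - 1]; v1 <- vals[k]
      tv[k - 1] + step * (v0 - config$hu_threshold) / (v0 - v1)
    }
    if (sample_mip(0)[1] < config$hu_threshold) return(NA_real_)
    half_chord(1) + half_chord(-1)
  }
  # average chords over the slab footprint along the branch: single-point
  # chords carry ~half-voxel quantization noise from the projected edge
  S <- max(branch$arclengths)
  ss <- s0 + seq(-config$mip_slab / 2, config$mip_slab / 2, length.out = 11)
  ss <- ss[ss >= 0 & ss <= S]
  chords <- vapply(ss, chord_at, numeric(1))
  if (all(is.na(chords)))
    stop("measurement point is outside the lumen on the MIP")
  mean(chords, na.rm = TRUE)
}

.bilinear2d <- function(img, spacing, origin, pts) {
  d <- dim(img)
  u <- cbind((pts[, 1] - origin[1]) / spacing[1],
             (pts[, 2] - origin[2]) / spacing[2])
  i0 <- floor(u); w <- u - i0
  acc <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) {
    ii <- i0[, 1] + dx; jj <- i0[, 2] + dy
    wt <- (if (dx) w[, 1] else 1 - w[, 1]) * (if (dy) w[, 2] else 1 - w[, 2])
    ok <- ii >= 0 & ii < d[1] & jj >= 0 & jj < d[2] & wt > 0
    if (any(ok)) acc[ok] <- acc[ok] + wt[ok] * img[cbind(ii[ok] + 1, jj[ok] + 1)]
  }
  acc[is.na(acc)] <- -Inf
  acc
}

#' All nine central pulmonary artery measurements
#'
#' Computes per-artery diameter (axial slab MIP chord), representative
#' cross-sectional area (profile area at the same offset point used for the
#' diameter) and volume (profile-integrated over the trimmed extent) for the
#' trunk (MPA) and the two children (RPA = `child_1`, LPA = `child_2`).
#' With a single-branch tree only the MPA fields are filled; RPA/LPA are
#' `NA`.
#'
#' @inheritParams diameter_mip
#' @param mask the vessel [binary_mask()] (binary or fractional).
#' @return A `vessel_measurements` object with fields `d_mpa`, `a_mpa`,
#'   `v_mpa`, `d_rpa`, `a_rpa`, `v_rpa`, `d_lpa`, `a_lpa`, `v_lpa`; the
#'   trimmed extents used for each volume are attached as attribute
#'   `extents`.
#' @export
measure_all <- function(volume, mask, tree, config = measurement_config()) {
  if (is.null(tree$branches$trunk)) stop("tree has no trunk branch")
  branches <- tree$branches
  radii <- lapply(branches, function(b) .branch_radius(mask, b, config))
  bif <- if (length(branches) > 1)
    .refine_bifurcation(branches, tree$bifurcation,
                        offset = config$diameter_offset) else NULL
  tree$anchors <- if (!is.null(bif))
    lapply(branches, .arclength_anchor, point = bif)
  tree$bifurcation_refined <- bif

  out <- list(d_mpa = NA_real_, a_mpa = NA_real_, v_mpa = NA_real_,
              d_rpa = NA_real_, a_rpa = NA_real_, v_rpa = NA_real_,
              d_lpa = NA_real_, a_lpa = NA_real_, v_lpa = NA_real_)
  extents <- list()
  for (artery in c("MPA", "RPA", "LPA")) {
    bname <- .artery_branch(tree, artery)
    branch <- branches[[bname]]
    if (is.null(branch)) next
    lowc <- tolower(artery)
    S <- max(branch$arclengths)
    anchor <- tree$anchors[[bname]]
    window <- if (artery == "MPA") {
      c(config$exclusion_margin,
        min(S, (anchor %||% S) - config$exclusion_margin))
    } else {
      c(max(0, (anchor %||% 0) + config$exclusion_margin), S)
    }
    competitors <- lapply(setdiff(names(branches), bname), function(nm)
      list(points = branches[[nm]]$points, radius = radii[[nm]]))
    prof <- area_profile(mask, branch, config, competitors = competitors,
                         own_radius = radii[[bname]], window = window)
    s_meas <- .measurement_arclength(branch, artery, config, anchor)
    a_rep <- approx(prof$arclengths, prof$areas, xout = s_meas,
                    ties = "ordered", rule = 2)$y
    out[[paste0("d_", lowc)]] <- diameter_mip(volume, mask, tree, artery, config)
    out[[paste0("a_", lowc)]] <- a_rep
    out[[paste0("v_", lowc)]] <- volume_from_profile(prof)
    extents[[lowc]] <- c(min(prof$arclengths), max(prof$arclengths),
                         extent = prof$extent)
    # sanity gate: near-circular vessels should have A ~ pi (D/2)^2
    d <- out[[paste0("d_", lowc)]]
    if (is.finite(d) && a_rep > 0 &&
        abs(a_rep - pi * (d / 2)^2) > 0.25 * a_rep)
      message(artery, ": area deviates > 25% from the circular equivalent ",
              "of the measured diameter (non-circular section?)")
  }
  structure(out, class = "vessel_measurements", extents = extents,
            bifurcation = bif)
}

#' @export
print.vessel_measurements <- function(x, ...) {
  cat("<vessel_measurements>\n")
  for (art in c("mpa", "rpa", "lpa"))
    cat(sprintf("  %s: D = %.2f mm, A = %.2f mm^2, V = %.2f mm^3\n",
                toupper(art), x[[paste0("d_", art)]], x[[paste0("a_", art)]],
                x[[paste0("v_", art)]]))
  invisible(x)
}
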