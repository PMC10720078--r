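#' Parametric centerline curves for synthetic vessel phantoms
#'
#' Three curve families with closed-form arclength and tangents: straight
#' segments, circular arcs (constant curvature), and polylines.  Exact
#' parameterization keeps the phantom ground truth analytic.
#'
#' @param from,to world endpoints (mm) of a straight segment.
#' @return A `tube_curve` object.
#' @export
straight_segment <- function(from, to) {
  from <- as.numeric(from); to <- as.numeric(to)
  L <- sqrt(sum((to - from)^2))
  if (!is.finite(L) || L <= 0) stop("segment must have positive length")
  structure(list(type = "straight", base = from, axis = (to - from) / L,
                 length = L), class = "tube_curve")
}

#' @rdname straight_segment
#' @param start start point (mm).
#' @param tangent unit initial tangent.
#' @param turn_toward unit vector, perpendicular to `tangent`, giving the
#'   direction the tangent rotates toward along the arc.
#' @param arc_radius radius of the centerline circle (mm).
#' @param arc_angle angular extent (radians, in `(0, pi]`).
#' @export
circular_arc <- function(start, tangent, turn_toward, arc_radius, arc_angle) {
  start <- as.numeric(start)
  t0 <- as.numeric(tangent); t0 <- t0 / sqrt(sum(t0^2))
  n0 <- as.numeric(turn_toward)
  n0 <- n0 - sum(n0 * t0) * t0           # enforce orthogonality
  nn <- sqrt(sum(n0^2))
  if (nn < 1e-12) stop("`turn_toward` must not be parallel to `tangent`")
  n0 <- n0 / nn
  if (!is.finite(arc_radius) || arc_radius <= 0) stop("arc_radius must be > 0")
  if (!is.finite(arc_angle) || arc_angle <= 0 || arc_angle > pi)
    stop("arc_angle must be in (0, pi]")
  center <- start + arc_radius * n0
  structure(list(type = "arc", center = center, u = -n0, v = t0,
                 arc_radius = arc_radius, arc_angle = arc_angle,
                 length = arc_radius * arc_angle), class = "tube_curve")
}

#' @rdname straight_segment
#' @param points n-by-3 matrix of polyline vertices (mm).
#' @export
polyline_curve <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 2)
  seg <- sqrt(rowSums(diff(points)^2))
  if (any(seg <= 0)) stop("polyline has a zero-length segment")
  structure(list(type = "polyline", points = points,
                 cum = c(0, cumsum(seg)), length = sum(seg)),
            class = "tube_curve")
}

#' Evaluate a curve (and its unit tangent) at arclength positions
#' @param curve a `tube_curve`.
#' @param s numeric vector of arclengths in `[0, length]` (mm).
#' @return `curve_point()`: n-by-3 matrix of points; `curve_tangent()`:
#'   n-by-3 matrix of unit tangents.
#' @export
curve_point <- function(curve, s) {
  s <- pmin(pmax(s, 0), curve$length)
  switch(curve$type,
    straight = t(curve$base + outer(curve$axis, s)),
    arc = {
      phi <- s / curve$arc_radius
      t(curve$center + curve$arc_radius *
          (outer(curve$u, cos(phi)) + outer(curve$v, sin(phi))))
    },
    polyline = {
      out <- matrix(0, length(s), 3)
      for (j in 1:3)
        out[, j] <- approx(curve$cum, curve$points[, j], xout = s, rule = 2)$y
      out
    })
}

#' @rdname curve_point
#' @export
curve_tangent <- function(curve, s) {
  s <- pmin(pmax(s, 0), curve$length)
  switch(curve$type,
    straight = matrix(curve$axis, length(s), 3, byrow = TRUE),
    arc = {
      phi <- s / curve$arc_radius
      t(-outer(curve$u, sin(phi)) + outer(curve$v, cos(phi)))
    },
    polyline = {
      k <- pmin(findInterval(s, curve$cum, rightmost.closed = TRUE),
                nrow(curve$points) - 1)
      d <- curve$points[k + 1, , drop = FALSE] - curve$points[k, , drop = FALSE]
      d / sqrt(rowSums(d^2))
    })
}

.curve_bbox <- function(curve) {
  pts <- switch(curve$type,
    straight = curve_point(curve, c(0, curve$length)),
    arc = curve_point(curve, seq(0, curve$length, length.out = 181)),
    polyline = curve$points)
  list(lo = apply(pts, 2, min), hi = apply(pts, 2, max))
}

#' Tube specification: curve + radius profile + lumen attenuation
#'
#' @param curve a `tube_curve`.
#' @param radius lumen radius at the start of the curve (mm, > 0).
#' @param radius_end radius at the end (mm); default equal to `radius`
#'   (constant radius). A differing value gives a linear taper in arclength.
#' @param lumen_hu attenuation of the contrast-filled lumen (HU); the default
#'   350 HU lies inside the usual segmentation window.
#' @return A `tube_spec`.
#' @export
tube_spec <- function(curve, radius, radius_end = NULL, lumen_hu = 350) {
  if (!inherits(curve, "tube_curve")) stop("`curve` must be a tube_curve")
  radius_end <- radius_end %||% radius
  if (radius <= 0 || radius_end <= 0) stop("tube radius must be > 0 everywhere")
  structure(list(curve = curve, r0 = radius, r1 = radius_end,
                 lumen_hu = lumen_hu), class = "tube_spec")
}

.tube_radius <- function(tube, s) {
  tube$r0 + (tube$r1 - tube$r0) * pmin(pmax(s / tube$curve$length, 0), 1)
}

# closed-form partial volume of a linearly tapered circular tube over [s0, s1]
.tube_volume_closed <- function(tube, s0 = 0, s1 = tube$curve$length) {
  L <- tube$curve$length
  k <- (tube$r1 - tube$r0) / L
  F <- function(s) pi * (tube$r0^2 * s + tube$r0 * k * s^2 + k^2 * s^3 / 3)
  F(s1) - F(s0)
}

#' Grid geometry for phantom rasterization
#' @param dim integer length-3 voxel counts.
#' @param spacing voxel size (mm) per axis.
#' @param origin world position (mm) of the center of voxel `(0,0,0)`.
#' @export
grid_spec <- function(dim, spacing, origin = c(0, 0, 0)) {
  dim <- as.integer(dim); spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("non-positive grid spacing")
  if (any(dim < 1)) stop("grid must have at least one voxel per axis")
  structure(list(dim = dim, spacing = spacing, origin = as.numeric(origin)),
            class = "grid_spec")
}

.auto_grid <- function(tubes, spacing, margin_mm = NULL) {
  los <- his <- NULL
  for (tb in tubes) {
    bb <- .curve_bbox(tb$curve)
    rmax <- max(tb$r0, tb$r1)
    los <- rbind(los, bb$lo - rmax)
    his <- rbind(his, bb$hi + rmax)
  }
  lo <- apply(los, 2, min); hi <- apply(his, 2, max)
  margin <- margin_mm %||% pmax(4 * spacing, 3)
  lo <- lo - margin; hi <- hi + margin
  grid_spec(ceiling((hi - lo) / spacing) + 1L, spacing, lo)
}

#' Phantom specification: tubes on a CT grid
#'
#' @param tubes list of [tube_spec()] objects (non-empty).
#' @param trunk index of the designated trunk (MPA analog), or `NULL`.
#' @param children integer pair indexing the two child tubes (RPA/LPA
#'   analogs), or `NULL`. Children must start at the trunk's endpoint.
#' @param background_hu ambient attenuation (HU); default -850 (lung-like).
#' @param grid a [grid_spec()], or `NULL` to fit the grid around the tubes.
#' @param spacing grid spacing used when `grid` is `NULL`; the default
#'   follows a typical CT pulmonary angiography reconstruction
#'   (0.68 mm in-plane, 0.45 mm slice step).
#' @param noise_sd Gaussian HU noise standard deviation (>= 0).
#' @param seed RNG seed for the noise (optional).
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(tubes, trunk = NULL, children = NULL,
                         background_hu = -850, grid = NULL,
                         spacing = c(0.68, 0.68, 0.45),
                         noise_sd = 0, seed = NULL) {
  if (!is.list(tubes) || length(tubes) == 0)
    stop("`tubes` must be a non-empty list of tube_spec objects")
  if (!all(vapply(tubes, inherits, logical(1), "tube_spec")))
    stop("`tubes` must contain tube_spec objects")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(children)) {
    if (is.null(trunk)) stop("`children` requires a designated `trunk`")
    bif <- curve_point(tubes[[trunk]]$curve, tubes[[trunk]]$curve$length)
    for (ch in children) {
      st <- curve_point(tubes[[ch]]$curve, 0)
      if (sqrt(sum((st - bif)^2)) > 1e-6)
        stop("child tube ", ch, " does not start at the trunk endpoint")
    }
  }
  grid <- grid %||% .auto_grid(tubes, spacing)
  structure(list(tubes = tubes, trunk = trunk, children = children,
                 background_hu = background_hu, grid = grid,
                 noise_sd = noise_sd, seed = seed),
            class = "phantom_spec")
}

# analytic ground truth: independent of rasterization and noise
.phantom_truth <- function(spec) {
  tubes <- spec$tubes
  tube_truth <- lapply(tubes, function(tb) {
    L <- tb$curve$length
    list(length = L,
         radius = function(s) .tube_radius(tb, s),
         area = function(s) pi * .tube_radius(tb, s)^2,
         diameter = function(s) 2 * .tube_radius(tb, s),
         centerline = function(s) curve_point(tb$curve, s),
         tangent = function(s) curve_tangent(tb$curve, s),
         volume = .tube_volume_closed(tb),
         volume_between = function(s0, s1) .tube_volume_closed(tb, s0, s1))
  })
  # internal consistency: area integral reproduces the closed-form volume
  for (i in seq_along(tubes)) {
    s <- seq(0, tube_truth[[i]]$length, length.out = 2001)
    a <- tube_truth[[i]]$area(s)
    vnum <- sum((a[-1] + a[-length(a)]) / 2 * diff(s))
    if (abs(vnum - tube_truth[[i]]$volume) > 1e-3 * tube_truth[[i]]$volume)
      stop("internal error: analytic volume inconsistent with area profile")
  }
  bif <- NULL
  if (!is.null(spec$trunk) && !is.null(spec$children))
    bif <- as.numeric(curve_point(tubes[[spec$trunk]]$curve,
                                  tubes[[spec$trunk]]$curve$length))
  structure(list(tubes = tube_truth, trunk = spec$trunk,
                 children = spec$children, bifurcation = bif),
            class = "phantom_truth")
}

.tube_cpp_descriptor <- function(tb) {
  cv <- tb$curve
  bb <- .curve_bbox(cv)
  rmax <- max(tb$r0, tb$r1)
  base <- list(r0 = tb$r0, r1 = tb$r1, length = cv$length,
               bbox_lo = bb$lo - rmax - 1e-9, bbox_hi = bb$hi + rmax + 1e-9)
  if (cv$type == "straight")
    c(base, list(type = 1L, base = cv$base, axis = cv$axis))
  else if (cv$type == "arc")
    c(base, list(type = 2L, center = cv$center, u = cv$u, v = cv$v,
                 arc_radius = cv$arc_radius, arc_angle = cv$arc_angle))
  else
    c(base, list(type = 3L, points = cv$points))
}

#' Rasterize a phantom onto its CT grid
#'
#' Voxel HU is linear in the in-voxel lumen fraction (partial-volume
#' blending); boundary voxels are estimated by 3x3x3 supersampling after an
#' 8-corner classification. Gaussian noise (if any) is added last. The
#' returned truth is analytic, not rasterized, so it is unaffected by grid or
#' noise settings.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` (an [image_volume()]), `truth`
#'   (analytic `phantom_truth`), `fraction` (a fractional [binary_mask()] of
#'   in-voxel lumen fractions) and `lumen_mask` (its >= 0.5 level set).
#' @export
rasterize_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  g <- spec$grid
  # clearance precondition: every tube inside the grid with >= 2 voxel margin
  ext_lo <- g$origin + 2 * g$spacing
  ext_hi <- g$origin + (g$dim - 1 - 2) * g$spacing
  for (tb in spec$tubes) {
    bb <- .curve_bbox(tb$curve)
    rmax <- max(tb$r0, tb$r1)
    if (any(bb$lo - rmax < ext_lo) || any(bb$hi + rmax > ext_hi))
      stop("tube exits the grid (need >= 2 voxels clearance)")
  }
  hus <- vapply(spec$tubes, function(t) t$lumen_hu, numeric(1))
  frac <- array(0, dim = g$dim)
  for (hu in unique(hus)) {
    desc <- lapply(spec$tubes[hus == hu], .tube_cpp_descriptor)
    f <- cpp_rasterize(desc, g$dim, g$spacing, g$origin)
    dim(f) <- g$dim
    frac <- pmax(frac, f)    # union across attenuation groups
  }
  # HU field for a single lumen attenuation (the common case); with mixed
  # attenuations each tube group blends against the background independently
  hu_arr <- array(spec$background_hu, dim = g$dim)
  for (hu in unique(hus)) {
    desc <- lapply(spec$tubes[hus == hu], .tube_cpp_descriptor)
    if (length(unique(hus)) == 1) {
      f <- frac
    } else {
      f <- cpp_rasterize(desc, g$dim, g$spacing, g$origin)
      dim(f) <- g$dim
    }
    hu_arr <- pmax(hu_arr, spec$background_hu + f * (hu - spec$background_hu))
  }
  if (spec$noise_sd > 0) {
    restore <- .seed_guard(spec$seed)
    hu_arr <- hu_arr + array(rnorm(length(hu_arr), 0, spec$noise_sd), dim = g$dim)
    if (!is.null(restore)) restore()
  }
  list(volume = image_volume(hu_arr, g$spacing, g$origin),
       truth = .phantom_truth(spec),
       fraction = binary_mask(frac, g$spacing, g$origin),
       lumen_mask = binary_mask(frac >= 0.5, g$spacing, g$origin))
}

#' Bifurcating pulmonary-artery tree phantom
#'
#' A straight trunk (MPA analog) along +z ending at the bifurcation, and two
#' circular-arc children (RPA toward -x, LPA toward +x, LPS convention)
#' leaving the bifurcation at the stated angles from the trunk axis in the
#' x-z plane. Default radii are of the order of the dilated main pulmonary
#' artery seen in pulmonary hypertension (trunk radius 18 mm).
#'
#' @param trunk_radius trunk lumen radius (mm), default 18.
#' @param branch_radii radii of the two children (mm), default `c(12, 12)`.
#' @param trunk_length trunk length (mm), default 60.
#' @param branch_lengths child arclengths (mm), default `c(50, 50)`.
#' @param branch_angles take-off angles from the trunk axis (degrees, each in
#'   `(10, 170)`), default `c(45, 45)`.
#' @param extra_turn additional tangent rotation along each child arc
#'   (degrees); 0 gives straight children. Default 25.
#' @param lumen_hu,background_hu attenuation palette (HU).
#' @param grid,spacing,noise_sd,seed passed to [phantom_spec()].
#' @return A `phantom_spec` with trunk/children designated.
#' @export
make_pa_tree_spec <- function(trunk_radius = 18, branch_radii = c(12, 12),
                              trunk_length = 60, branch_lengths = c(50, 50),
                              branch_angles = c(45, 45), extra_turn = 25,
                              lumen_hu = 350, background_hu = -850,
                              grid = NULL, spacing = c(0.68, 0.68, 0.45),
                              noise_sd = 0, seed = NULL) {
  if (any(c(trunk_radius, branch_radii, trunk_length, branch_lengths) <= 0))
    stop("radii and lengths must be positive")
  if (any(branch_angles <= 10 | branch_angles >= 170))
    stop("branch angles must lie in (10, 170) degrees")
  bif <- c(0, 0, trunk_length)
  trunk <- tube_spec(straight_segment(c(0, 0, 0), bif),
                     trunk_radius, lumen_hu = lumen_hu)
  mk_child <- function(side, ang_deg, len, rad) {
    a <- ang_deg * pi / 180
    tangent <- c(side * sin(a), 0, cos(a))
    turn <- c(side * cos(a), 0, -sin(a))    # rotates the tangent away from +z
    if (extra_turn > 0) {
      dAng <- extra_turn * pi / 180
      tube_spec(circular_arc(bif, tangent, turn, len / dAng, dAng),
                rad, lumen_hu = lumen_hu)
    } else {
      tube_spec(straight_segment(bif, bif + len * tangent),
                rad, lumen_hu = lumen_hu)
    }
  }
  child_r <- mk_child(-1, branch_angles[1], branch_lengths[1], branch_radii[1])
  child_l <- mk_child(+1, branch_angles[2], branch_lengths[2], branch_radii[2])
  # children must not overlap beyond the junction region
  s1 <- seq(0, child_r$curve$length, by = 1)
  s2 <- seq(0, child_l$curve$length, by = 1)
  p1 <- curve_point(child_r$curve, s1); p2 <- curve_point(child_l$curve, s2)
  clear <- 2 * max(branch_radii)
  keep1 <- s1 > clear; keep2 <- s2 > clear
  if (any(keep1) && any(keep2)) {
    dmin <- min(sqrt(outer(rowSums(p1[keep1, , drop = FALSE]^2), rep(1, sum(keep2))) +
                     outer(rep(1, sum(keep1)), rowSums(p2[keep2, , drop = FALSE]^2)) -
                     2 * p1[keep1, , drop = FALSE] %*% t(p2[keep2, , drop = FALSE])))
    if (dmin < sum(branch_radii))
      stop("child tubes overlap beyond the junction")
  }
  phantom_spec(list(trunk, child_r, child_l), trunk = 1L, children = c(2L, 3L),
               background_hu = background_hu, grid = grid, spacing = spacing,
               noise_sd = noise_sd, seed = seed)
}
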