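#' Centerline extraction configuration
#'
#' @param smoothing_factor dimensionless in `[0, 1]`: 0 interpolates the raw
#'   voxel path, 1 collapses to the least-squares straight line; the default
#'   0.5 maps to a moderate spline penalty (see the methods vignette for the
#'   exact mapping).
#' @param extend_to_surface thinning retracts free tube ends by roughly one
#'   radius; if `TRUE` (default) free branch endpoints are extended along the
#'   end tangent until the centerline exits the mask, so branch arclength
#'   matches the vessel length.
#' @param tangent_window half-window (mm, default 4) of the secant used for
#'   control-point tangents: the tangent at arclength s is the direction from
#'   the curve point at s - window to the point at s + window. Sub-voxel
#'   residual wiggle of a skeleton-derived path perturbs pointwise
#'   derivatives far more than positions; the windowed secant is stable while
#'   the bias for vessel-scale curvature radii is negligible.
#' @param recenter_iterations number of sectionwise recentering passes after
#'   branch extraction: each control point is moved to the centroid of its
#'   perpendicular lumen cross-section (movement capped at 2 mm per pass, the
#'   3 mm nearest each branch end frozen), then the branch is re-smoothed.
#'   Corrects the off-axis drift of the voxel skeleton near junctions.
#'   Default 2; 0 disables.
#' @param control_spacing distance between successive control points after
#'   arclength-uniform resampling (mm, default 1).
#' @param resample_resolution spline evaluation step before resampling (mm,
#'   default 1).
#' @param spur_length_min skeleton leaf branches shorter than this are pruned
#'   (mm, default 5).
#' @return A `centerline_config`.
#' @export
centerline_config <- function(smoothing_factor = 0.5, control_spacing = 1,
                              resample_resolution = 1, spur_length_min = 5,
                              extend_to_surface = TRUE,
                              tangent_window = 4,
                              recenter_iterations = 2) {
  if (smoothing_factor < 0 || smoothing_factor > 1)
    stop("smoothing_factor must be in [0, 1]")
  if (control_spacing <= 0) stop("control_spacing must be > 0")
  if (resample_resolution <= 0) stop("resample_resolution must be > 0")
  structure(list(smoothing_factor = smoothing_factor,
                 control_spacing = control_spacing,
                 resample_resolution = resample_resolution,
                 spur_length_min = spur_length_min,
                 extend_to_surface = extend_to_surface,
                 tangent_window = tangent_window,
                 recenter_iterations = recenter_iterations),
            class = "centerline_config")
}

#' Skeletonize a vessel mask
#'
#' Topology-preserving 3D thinning (distance-ordered homotopic thinning with
#' curve-endpoint preservation) reduces the mask to a one-voxel-wide,
#' connected curve skeleton. Skeleton voxels become nodes of a graph whose
#' edges join 26-neighbors, weighted by world distance.
#'
#' @param mask a binary [binary_mask()] with exactly one connected component.
#' @param closing number of morphological closing passes applied before
#'   thinning (default 1); voxelized vessel unions can contain sub-voxel
#'   tunnels near junction creases which would survive topology-preserving
#'   thinning as spurious skeleton loops.
#' @return A `skeleton` object: igraph with vertex attributes `x`, `y`, `z`
#'   (world mm) and `ix`, `iy`, `iz` (0-based voxel indices), plus grid
#'   geometry.
#' @export
skeletonize <- function(mask, closing = 1) {
  bin <- mask_binary_array(mask)
  if (!any(bin)) stop("empty mask: nothing to skeletonize")
  lab <- cpp_label(as.logical(bin), dim(bin), 26L)
  if (max(lab) > 1)
    stop("mask has ", max(lab), " connected components; expected exactly one")
  if (closing > 0)
    bin <- mask_binary_array(binary_closing(
      binary_mask(bin, mask$spacing, mask$origin), closing))
  sk <- cpp_skeletonize(as.logical(bin), dim(bin), mask$spacing)
  dim(sk) <- dim(bin)
  idx <- which(sk, arr.ind = TRUE) - 1L   # 0-based
  out <- .skeleton_from_indices(idx, mask$spacing, mask$origin, dim(bin))
  out$mask <- bin
  out
}

.skeleton_from_indices <- function(idx, spacing, origin, dims) {
  n <- nrow(idx)
  coords <- t(t(idx) * spacing + origin)
  # adjacency between 26-neighbor skeleton voxels (vectorized key matching)
  key <- idx[, 1] + dims[1] * (idx[, 2] + dims[2] * idx[, 3])
  from <- integer(0); to <- integer(0)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  for (o in seq_len(nrow(offs))) {
    nkey <- (idx[, 1] + offs$dx[o]) +
      dims[1] * ((idx[, 2] + offs$dy[o]) + dims[2] * (idx[, 3] + offs$dz[o]))
    j <- match(nkey, key)
    hit <- !is.na(j) & j > seq_len(n)
    from <- c(from, which(hit)); to <- c(to, j[hit])
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(from)) {
    w <- sqrt(rowSums((coords[from, , drop = FALSE] - coords[to, , drop = FALSE])^2))
    g <- igraph::add_edges(g, rbind(from, to), weight = w)
  }
  igraph::V(g)$x <- coords[, 1]; igraph::V(g)$y <- coords[, 2]; igraph::V(g)$z <- coords[, 3]
  igraph::V(g)$ix <- idx[, 1]; igraph::V(g)$iy <- idx[, 2]; igraph::V(g)$iz <- idx[, 3]
  structure(list(graph = g, spacing = spacing, origin = origin, dims = dims),
            class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton> %d voxels, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

.vertex_coords <- function(g, v = igraph::V(g)) {
  cbind(igraph::vertex_attr(g, "x", v),
        igraph::vertex_attr(g, "y", v),
        igraph::vertex_attr(g, "z", v))
}

# decompose a graph into maximal paths between nodes of degree != 2
.branches_from_graph <- function(g) {
  deg <- igraph::degree(g)
  out <- list()
  if (igraph::vcount(g) == 0) return(out)
  breaks <- which(deg != 2)
  if (length(breaks) == 0) breaks <- 1L   # pure cycle: break it arbitrarily
  visited <- rep(FALSE, igraph::ecount(g))
  for (b in breaks) {
    if (deg[b] == 0) { out[[length(out) + 1]] <- b; next }
    for (e in as.integer(igraph::incident(g, b))) {
      if (visited[e]) next
      visited[e] <- TRUE
      ends <- as.integer(igraph::ends(g, e, names = FALSE))
      cur <- if (ends[1] == b) ends[2] else ends[1]
      path <- c(b, cur)
      while (deg[cur] == 2 && cur != b) {
        es <- as.integer(igraph::incident(g, cur))
        e2 <- es[!visited[es]]
        if (length(e2) == 0) break
        visited[e2[1]] <- TRUE
        ends <- as.integer(igraph::ends(g, e2[1], names = FALSE))
        nxt <- if (ends[1] == cur) ends[2] else ends[1]
        path <- c(path, nxt)
        cur <- nxt
      }
      out[[length(out) + 1]] <- path
    }
  }
  out
}

.path_length <- function(g, path) {
  if (length(path) < 2) return(0)
  p <- .vertex_coords(g, path)
  sum(sqrt(rowSums(diff(p)^2)))
}

# merge junction clusters: contract junction-to-junction branches shorter
# than min_len (thinning can split one anatomical junction into several
# nearby skeleton junctions connected by short internal paths)
.merge_junctions <- function(g, min_len) {
  repeat {
    deg <- igraph::degree(g)
    paths <- .branches_from_graph(g)
    cand <- NULL
    for (p in paths) {
      a <- p[1]; z <- p[length(p)]
      if (a != z && deg[a] >= 3 && deg[z] >= 3 &&
          .path_length(g, p) < min_len) { cand <- p; break }
    }
    if (is.null(cand)) return(g)
    a <- cand[1]; z <- cand[length(cand)]
    pa <- .vertex_coords(g, a)
    for (e in as.integer(igraph::incident(g, z))) {
      ends <- as.integer(igraph::ends(g, e, names = FALSE))
      w <- if (ends[1] == z) ends[2] else ends[1]
      if (w %in% cand) next
      pw <- .vertex_coords(g, w)
      g <- igraph::add_edges(g, c(a, w),
                             weight = sqrt(sum((pa - pw)^2)))
    }
    g <- igraph::delete_vertices(g, cand[-1])
  }
}

# iteratively remove leaf branches shorter than spur_length_min
.prune_spurs <- function(g, spur_min) {
  repeat {
    deg <- igraph::degree(g)
    paths <- .branches_from_graph(g)
    drop <- integer(0)
    for (p in paths) {
      if (length(p) < 2) next
      a <- p[1]; z <- p[length(p)]
      leaf_a <- deg[a] == 1 && deg[z] >= 3
      leaf_z <- deg[z] == 1 && deg[a] >= 3
      if (!(leaf_a || leaf_z)) next
      if (.path_length(g, p) >= spur_min) next
      drop <- c(drop, if (leaf_a) p[-length(p)] else p[-1])
    }
    drop <- unique(drop)
    if (length(drop) == 0) return(g)
    g <- igraph::delete_vertices(g, drop)
  }
}

#' Extract a branch tree from a skeleton
#'
#' Prunes short leaf branches ("spurs"), decomposes the remaining skeleton
#' into branches between endpoints and junctions, designates a trunk (the
#' branch containing `seed`, or the longest branch), locates the bifurcation
#' where the trunk meets its two longest children, and smooths/resamples
#' every branch via [smooth_resample()].
#'
#' Children are named so that `child_1` has the smaller mean x coordinate
#' (the right lung side in LPS orientation).
#'
#' @param skeleton a `skeleton` from [skeletonize()].
#' @param config a [centerline_config()].
#' @param seed optional world point (mm) marking the trunk.
#' @return A `centerline_tree`: list of `branches` (named `trunk`, `child_1`,
#'   `child_2`) and `bifurcation` (world mm, or `NULL` for a single-branch
#'   tree).
#' @export
extract_tree <- function(skeleton, config = centerline_config(), seed = NULL) {
  g <- skeleton$graph
  repeat {
    g2 <- .merge_junctions(.prune_spurs(g, config$spur_length_min),
                           config$spur_length_min)
    if (igraph::vcount(g2) == igraph::vcount(g)) { g <- g2; break }
    g <- g2
  }
  paths <- .branches_from_graph(g)
  if (length(paths) == 0) stop("skeleton is empty after pruning")
  lens <- vapply(paths, function(p) .path_length(g, p), numeric(1))

  if (!is.null(seed)) {
    co <- .vertex_coords(g)
    seed <- as.numeric(seed)
    nearest <- which.min((co[, 1] - seed[1])^2 + (co[, 2] - seed[2])^2 +
                           (co[, 3] - seed[3])^2)
    cand <- which(vapply(paths, function(p) nearest %in% p, logical(1)))
    trunk_i <- cand[which.max(lens[cand])]
  } else {
    trunk_i <- which.max(lens)
  }
  trunk_path <- paths[[trunk_i]]
  deg <- igraph::degree(g)

  ends <- c(trunk_path[1], trunk_path[length(trunk_path)])
  junctions <- ends[deg[ends] >= 3]
  mk_branch <- function(p) {
    pts <- .vertex_coords(g, p)
    if (isTRUE(config$extend_to_surface) && !is.null(skeleton$mask)) {
      step <- min(skeleton$spacing) / 2
      if (deg[p[1]] == 1) {
        tmp <- .extend_end(pts[rev(seq_len(nrow(pts))), , drop = FALSE],
                           skeleton, step)
        pts <- tmp[rev(seq_len(nrow(tmp))), , drop = FALSE]
      }
      if (deg[p[length(p)]] == 1)
        pts <- .extend_end(pts, skeleton, step)
    }
    smooth_resample(pts, config)
  }

  if (length(junctions) == 0) {
    branches <- .recenter_all(list(trunk = mk_branch(trunk_path)),
                              skeleton, config)
    return(structure(list(branches = branches, bifurcation = NULL),
                     class = "centerline_tree"))
  }
  # score candidate junctions by the total length of the other branches there
  branch_ends <- lapply(paths, function(p) c(p[1], p[length(p)]))
  score <- vapply(junctions, function(j) {
    others <- setdiff(which(vapply(branch_ends, function(e) j %in% e, logical(1))),
                      trunk_i)
    sum(sort(lens[others], decreasing = TRUE)[1:min(2, length(others))])
  }, numeric(1))
  jv <- junctions[which.max(score)]
  bif <- as.numeric(.vertex_coords(g, jv))

  # orient trunk to end at the bifurcation
  if (trunk_path[1] == jv) trunk_path <- rev(trunk_path)
  child_is <- setdiff(which(vapply(branch_ends, function(e) jv %in% e, logical(1))),
                      trunk_i)
  child_is <- child_is[lens[child_is] >= 2 * config$control_spacing]
  child_is <- child_is[order(lens[child_is], decreasing = TRUE)]
  child_is <- head(child_is, 2)
  children <- lapply(child_is, function(i) {
    p <- paths[[i]]
    if (p[length(p)] == jv) p <- rev(p)   # orient to start at the bifurcation
    p
  })
  if (length(children) == 2) {
    mx <- vapply(children, function(p) mean(.vertex_coords(g, p)[, 1]), numeric(1))
    children <- children[order(mx)]
  }
  branches <- c(list(trunk = mk_branch(trunk_path)),
                setNames(lapply(children, mk_branch),
                         paste0("child_", seq_along(children))))
  branches <- .recenter_all(branches, skeleton, config)
  structure(list(branches = branches, bifurcation = bif),
            class = "centerline_tree")
}

.recenter_all <- function(branches, skeleton, config) {
  if (config$recenter_iterations <= 0 || is.null(skeleton$mask))
    return(branches)
  maskobj <- binary_mask(skeleton$mask, skeleton$spacing, skeleton$origin)
  cs <- config$control_spacing
  rcfg <- measurement_config(section_halfsize = 25 * cs, section_step = cs)
  radii <- lapply(branches, function(b) .branch_radius(maskobj, b, rcfg))
  nms <- names(branches)
  for (nm in nms) {
    comp <- lapply(setdiff(nms, nm), function(n2)
      list(points = branches[[n2]]$points, radius = radii[[n2]]))
    branches[[nm]] <- .recenter_branch(branches[[nm]], skeleton, config,
                                       competitors = comp,
                                       own_radius = radii[[nm]],
                                       halfsize = 25 * cs, step = cs,
                                       max_move = 2 * cs, freeze_mm = 3 * cs)
  }
  branches
}

#' @export
print.centerline_tree <- function(x, ...) {
  cat("<centerline_tree>\n")
  for (nm in names(x$branches)) {
    b <- x$branches[[nm]]
    cat(sprintf("  %s: %d control points, %.1f mm\n", nm, nrow(b$points),
                max(b$arclengths)))
  }
  if (!is.null(x$bifurcation))
    cat(sprintf("  bifurcation at (%.1f, %.1f, %.1f) mm\n",
                x$bifurcation[1], x$bifurcation[2], x$bifurcation[3]))
  invisible(x)
}

# extend the last point of a path along the end tangent until it leaves the
# mask, recentering each added point on the in-plane chord midpoints;
# recovers the ~1 radius lost to thinning without drifting off-axis
.extend_end <- function(pts, skeleton, step, max_extend = 60) {
  n <- nrow(pts)
  # direction from a generous window so single-voxel skeleton jitter
  # does not tilt the extension
  k <- max(1, n - 15)
  dir <- pts[n, ] - pts[k, ]
  nn <- sqrt(sum(dir^2))
  if (nn < 1e-9) return(pts)
  dir <- dir / nn
  d <- dim(skeleton$mask)
  inside <- function(p) {
    i <- .round_half_up((p - skeleton$origin) / skeleton$spacing)
    if (any(i < 0) || any(i > d - 1)) return(FALSE)
    skeleton$mask[i[1] + 1, i[2] + 1, i[3] + 1]
  }
  add <- NULL
  t <- step
  while (t <= max_extend) {
    p <- pts[n, ] + t * dir
    if (!inside(p)) break
    add <- rbind(add, p)
    t <- t + step
  }
  if (is.null(add)) return(pts)
  # nearest-voxel lookups plus the half-voxel bleed of the >= 50% lumen mask
  # overshoot the physical surface; trim the extension back accordingly
  halfvox <- sum(abs(dir) * skeleton$spacing) / 2
  keep <- seq_len(nrow(add)) * step <= t - step / 2 - halfvox
  if (!any(keep)) return(pts)
  rbind(pts, unname(add[keep, , drop = FALSE]))
}

# move each control point to the centroid of its perpendicular lumen section
# (8-connected region containing the point, junction-partitioned against the
# competitor branches), then re-smooth; corrects the off-axis drift of voxel
# skeletons near junctions. Movement is capped per pass and the ends are
# frozen so branch endpoints stay put.
.recenter_branch <- function(cl, skeleton, config, competitors = NULL,
                             own_radius = 1, halfsize = 25, step = 1,
                             max_move = 2, freeze_mm = 3) {
  maskobj <- binary_mask(skeleton$mask, skeleton$spacing, skeleton$origin)
  for (it in seq_len(config$recenter_iterations)) {
    pts <- cl$points
    S <- max(cl$arclengths)
    for (i in seq_len(nrow(pts))) {
      s <- cl$arclengths[i]
      if (s < freeze_mm || s > S - freeze_mm) next
      sec <- .section_region(maskobj, pts[i, ], cl$tangents[i, ], halfsize,
                             step, own_points = cl$points,
                             own_radius = own_radius,
                             competitors = competitors)
      if (!any(sec$region)) next
      du <- mean(sec$uv[sec$region, 1]); dv <- mean(sec$uv[sec$region, 2])
      shift <- sqrt(du^2 + dv^2)
      if (shift > max_move) { du <- du * max_move / shift; dv <- dv * max_move / shift }
      fr <- .orthonormal_frame(cl$tangents[i, ])
      pts[i, ] <- pts[i, ] + du * fr$u + dv * fr$v
    }
    cl <- smooth_resample(pts, config)
  }
  cl
}

# penalty mapping: factor 0 -> interpolation, 1 -> least-squares line.
# smooth.spline rescales the abscissa to [0,1], so the penalty is independent
# of the branch length; lambda = 1e-4 * f/(1-f) puts factor 0.5 at 1e-4.
.smooth_lambda <- function(factor) 1e-4 * factor / (1 - factor)

#' Smooth and resample a raw centerline path
#'
#' Fits each coordinate against cumulative chordlength with a penalized cubic
#' smoothing spline whose penalty is scaled so that `smoothing_factor = 0`
#' interpolates the input and `smoothing_factor = 1` collapses to the
#' least-squares straight line. The smoothed curve is then resampled at
#' arclength-uniform control points; tangents come from the spline
#' derivative.
#'
#' @param path n-by-3 matrix of ordered world points (mm), e.g. skeleton
#'   voxel centers.
#' @param config a [centerline_config()].
#' @return A `centerline`: `points` (m-by-3), `tangents` (m-by-3, unit),
#'   `arclengths` (strictly increasing, from 0).
#' @export
smooth_resample <- function(path, config = centerline_config()) {
  path <- as.matrix(path)
  if (ncol(path) != 3) stop("`path` must be an n-by-3 matrix")
  if (nrow(path) < 2) stop("path too short to resample")
  tt <- c(0, cumsum(sqrt(rowSums(diff(path)^2))))
  if (max(tt) < 2 * config$control_spacing)
    stop("path shorter than twice the control spacing")
  f <- config$smoothing_factor
  fit_coord <- function(y) {
    if (nrow(path) < 4 || f == 0) {
      sf <- splinefun(tt, y, method = "natural")
      list(eval = sf, deriv = function(t) sf(t, deriv = 1))
    } else if (f == 1) {
      cf <- coef(lm(y ~ tt))
      list(eval = function(t) cf[1] + cf[2] * t,
           deriv = function(t) rep(cf[2], length(t)))
    } else {
      ss <- smooth.spline(tt, y, lambda = .smooth_lambda(f), all.knots = TRUE)
      list(eval = function(t) predict(ss, t)$y,
           deriv = function(t) predict(ss, t, deriv = 1)$y)
    }
  }
  fits <- lapply(1:3, function(j) fit_coord(path[, j]))
  te <- seq(0, max(tt), by = config$resample_resolution)
  if (te[length(te)] < max(tt)) te <- c(te, max(tt))
  dense <- sapply(fits, function(fj) fj$eval(te))
  if (!is.matrix(dense)) dense <- matrix(dense, ncol = 3)
  s_dense <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
  s_total <- max(s_dense)
  s_ctrl <- seq(0, s_total, by = config$control_spacing)
  rem <- s_total - s_ctrl[length(s_ctrl)]
  if (rem > 0.2 * config$control_spacing) {
    s_ctrl <- c(s_ctrl, s_total)        # short extra interval (>= 20%)
  } else if (rem > 0 && length(s_ctrl) > 1) {
    s_ctrl[length(s_ctrl)] <- s_total   # stretch the last interval (<= 120%)
  }
  t_ctrl <- approx(s_dense, te, xout = s_ctrl, ties = "ordered")$y
  pts <- sapply(fits, function(fj) fj$eval(t_ctrl))
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 3)
  arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  # windowed secant tangents (robust to sub-voxel residual wiggle)
  w <- config$tangent_window %||% 4
  n <- nrow(pts)
  tan <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    j1 <- max(which(arc <= arc[i] - w), 1)
    j2 <- min(c(which(arc >= arc[i] + w), n))
    if (j1 == j2) { j1 <- max(1, i - 1); j2 <- min(n, i + 1) }
    tan[i, ] <- pts[j2, ] - pts[j1, ]
  }
  tan <- tan / sqrt(rowSums(tan^2))
  structure(list(points = pts, tangents = tan, arclengths = arc),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d control points, %.1f mm\n",
              nrow(x$points), max(x$arclengths)))
  invisible(x)
}
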