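# Shared fixture builders: all fixtures are generated in code at test time.

cylinder_phantom <- function(radius = 8, length = 40, spacing = 1,
                             noise_sd = 0, seed = NULL) {
  spec <- phantom_spec(list(tube_spec(
    straight_segment(c(0, 0, 0), c(0, 0, length)), radius)),
    spacing = rep(spacing, 3), noise_sd = noise_sd, seed = seed)
  rasterize_phantom(spec)
}

pa_tree_phantom <- function(spacing = 1, scale = 1, noise_sd = 0,
                            seed = NULL) {
  spec <- make_pa_tree_spec(
    trunk_radius = 18 * scale, branch_radii = c(12, 12) * scale,
    trunk_length = 60 * scale, branch_lengths = c(50, 50) * scale,
    spacing = rep(spacing, 3), noise_sd = noise_sd, seed = seed)
  rasterize_phantom(spec)
}

# run segmentation -> centerline on a rasterized phantom
phantom_tree <- function(rp, seed_point, clcfg = centerline_config()) {
  mask <- segment_vessel(rp$volume, seed_point)
  extract_tree(skeletonize(mask), clcfg, seed = seed_point)
}

# analytic inside test replicating the phantom tube geometry, for
# Monte-Carlo oracles independent of the rasterizer
inside_tube_oracle <- function(tube, pts) {
  cv <- tube$curve
  if (cv$type == "straight") {
    d <- t(t(pts) - cv$base)
    s <- d %*% cv$axis
    perp2 <- rowSums(d^2) - s^2
    r <- tube$r0 + (tube$r1 - tube$r0) * pmin(pmax(s / cv$length, 0), 1)
    s >= 0 & s <= cv$length & perp2 <= r^2
  } else if (cv$type == "arc") {
    q <- t(t(pts) - cv$center)
    u <- cv$u; v <- cv$v
    w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    qu <- q %*% u; qv <- q %*% v; z <- q %*% w
    phi <- atan2(qv, qu)
    rho <- sqrt(qu^2 + qv^2)
    s <- cv$arc_radius * phi
    r <- tube$r0 + (tube$r1 - tube$r0) * pmin(pmax(s / cv$length, 0), 1)
    phi >= 0 & phi <= cv$arc_angle & (z^2 + (rho - cv$arc_radius)^2) <= r^2
  } else {
    stop("oracle supports straight and arc tubes")
  }
}

inside_any_tube_oracle <- function(tubes, pts) {
  hit <- rep(FALSE, nrow(pts))
  for (tb in tubes) hit <- hit | inside_tube_oracle(tb, pts)
  hit
}

# brute-force AUC by explicit pair counting (ties count 1/2)
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (x in pos) for (y in neg)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(pos) * length(neg))
}

# total discrete turning angle of an ordered polyline
total_turning <- function(pts) {
  d <- diff(pts)
  d <- d / sqrt(rowSums(d^2))
  if (nrow(d) < 2) return(0)
  dots <- pmin(pmax(rowSums(d[-nrow(d), , drop = FALSE] *
                              d[-1, , drop = FALSE]), -1), 1)
  sum(acos(dots))
}
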