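#' Segmentation configuration
#'
#' Vessel segmentation follows the CT angiography workflow: an HU-window mask
#' (default -200..500 HU, bounds inclusive), optional axis-aligned ROI
#' cropping standing in for manual cleanup, and seeded region growing
#' realized as connected-component selection.
#'
#' @param hu_lo,hu_hi inclusive window bounds in HU (defaults -200 and 500).
#' @param connectivity voxel connectivity for region growing: 6, 18 or 26
#'   (default 26, the most permissive, least sensitive to thin-vessel
#'   staircase breaks).
#' @param mode `"window"` grows within the HU-window mask;
#'   `"seed-deviation"` grows within `seed HU +/- seed_deviation`.
#' @param seed_deviation HU half-width for seed-deviation mode.
#' @return A `segmentation_config`.
#' @export
segmentation_config <- function(hu_lo = -200, hu_hi = 500, connectivity = 26,
                                mode = c("window", "seed-deviation"),
                                seed_deviation = NULL) {
  if (hu_lo >= hu_hi) stop("hu_lo must be < hu_hi")
  if (!connectivity %in% c(6L, 18L, 26L)) stop("connectivity must be 6, 18 or 26")
  mode <- match.arg(mode)
  if (mode == "seed-deviation" && (is.null(seed_deviation) || seed_deviation <= 0))
    stop("seed-deviation mode requires a positive `seed_deviation`")
  structure(list(hu_lo = hu_lo, hu_hi = hu_hi,
                 connectivity = as.integer(connectivity),
                 mode = mode, seed_deviation = seed_deviation),
            class = "segmentation_config")
}

#' Axis-aligned ROI box (world mm)
#' @param min_corner,max_corner world corners (mm); `min_corner < max_corner`
#'   per axis.
#' @export
roi_box <- function(min_corner, max_corner) {
  min_corner <- as.numeric(min_corner); max_corner <- as.numeric(max_corner)
  if (any(min_corner >= max_corner)) stop("ROI box min must be < max per axis")
  structure(list(min = min_corner, max = max_corner), class = "roi_box")
}

#' HU-window threshold mask
#'
#' Foreground iff `hu_lo <= HU <= hu_hi` (inclusive at both bounds).
#'
#' @param volume an [image_volume()].
#' @param config a [segmentation_config()].
#' @return A binary [binary_mask()].
#' @export
threshold_mask <- function(volume, config = segmentation_config()) {
  if (length(volume$voxels) == 0) stop("empty volume")
  fg <- volume$voxels >= config$hu_lo & volume$voxels <= config$hu_hi
  binary_mask(fg, volume$spacing, volume$origin)
}

#' Clear mask foreground outside an ROI box
#'
#' Stand-in for manual removal of non-relevant structures: foreground outside
#' the box is cleared, the grid is unchanged. An empty intersection produces
#' a warning and an empty mask.
#'
#' @param mask a [binary_mask()].
#' @param box a [roi_box()].
#' @export
crop_roi <- function(mask, box) {
  d <- dim(mask$voxels)
  # voxel-center world coordinates per axis
  inside <- lapply(1:3, function(ax) {
    w <- mask$origin[ax] + (seq_len(d[ax]) - 1) * mask$spacing[ax]
    w >= box$min[ax] & w <= box$max[ax]
  })
  if (!all(vapply(inside, any, logical(1)))) {
    warning("ROI box does not intersect the grid; returning an empty mask")
    empty <- array(if (is.logical(mask$voxels)) FALSE else 0, dim = d)
    return(binary_mask(empty, mask$spacing, mask$origin))
  }
  keep <- array(outer(outer(inside[[1]], inside[[2]], "&"), inside[[3]], "&"), dim = d)
  v <- mask$voxels
  if (is.logical(v)) v <- v & keep else v <- v * keep
  binary_mask(v, mask$spacing, mask$origin)
}

#' Seeded region growing on a mask
#'
#' Returns exactly the connected component (at the configured connectivity)
#' of the mask that contains the seed; all other components ("scattered
#' branches") are discarded.
#'
#' @param mask a binary [binary_mask()].
#' @param seed world point (mm) inside the vessel.
#' @param config a [segmentation_config()].
#' @export
region_grow <- function(mask, seed, config = segmentation_config()) {
  idx <- world_to_voxel(mask, seed)
  bin <- mask_binary_array(mask)
  if (!bin[idx[1] + 1, idx[2] + 1, idx[3] + 1])
    stop(sprintf("seed voxel (%d,%d,%d) is background", idx[1], idx[2], idx[3]))
  out <- cpp_flood(as.logical(bin), dim(bin), idx, config$connectivity)
  dim(out) <- dim(bin)
  binary_mask(out, mask$spacing, mask$origin)
}

#' Full vessel segmentation: window -> optional ROI crop -> region grow
#'
#' @param volume an [image_volume()].
#' @param seed world point (mm) inside the target vessel (e.g. the MPA).
#' @param box optional [roi_box()].
#' @param config a [segmentation_config()].
#' @param verbose log voxel counts after each stage.
#' @return A binary [binary_mask()].
#' @export
segment_vessel <- function(volume, seed, box = NULL,
                           config = segmentation_config(), verbose = FALSE) {
  if (config$mode == "seed-deviation") {
    idx <- world_to_voxel(volume, seed)
    hu0 <- volume$voxels[idx[1] + 1, idx[2] + 1, idx[3] + 1]
    fg <- abs(volume$voxels - hu0) <= config$seed_deviation
    m <- binary_mask(fg, volume$spacing, volume$origin)
  } else {
    m <- threshold_mask(volume, config)
  }
  if (verbose) message("threshold: ", sum(m$voxels), " voxels")
  if (!is.null(box)) {
    m <- crop_roi(m, box)
    if (verbose) message("roi crop: ", sum(m$voxels), " voxels")
  }
  out <- region_grow(m, seed, config)
  if (verbose) message("region grow: ", sum(out$voxels), " voxels")
  out
}

.shift_or <- function(bin, reduce = `|`) {
  d <- dim(bin)
  out <- bin
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sx <- pmin(pmax(seq_len(d[1]) + dx, 1), d[1])
    sy <- pmin(pmax(seq_len(d[2]) + dy, 1), d[2])
    sz <- pmin(pmax(seq_len(d[3]) + dz, 1), d[3])
    out <- reduce(out, bin[sx, sy, sz])
  }
  out
}

#' Morphological closing of a binary mask (26-neighborhood)
#'
#' One dilation followed by one erosion per iteration. Seals sub-voxel
#' tunnels and crevices that voxelization can open near vessel junctions.
#'
#' @param mask a binary [binary_mask()].
#' @param iterations number of closing passes (default 1).
#' @export
binary_closing <- function(mask, iterations = 1) {
  bin <- mask_binary_array(mask)
  for (i in seq_len(iterations)) {
    bin <- .shift_or(bin, `|`)     # dilate
    bin <- .shift_or(bin, `&`)     # erode
  }
  binary_mask(bin, mask$spacing, mask$origin)
}

#' Partial-volume refinement of a hard segmentation
#'
#' Converts a binary vessel mask into a fractional lumen mask by inverting
#' the linear partial-volume model `HU = background + f * (lumen -
#' background)` voxelwise, restricted to the segmented component dilated by
#' one voxel. Useful when the lumen and background attenuations are known
#' (phantoms, or estimated from the image); sub-voxel boundary information
#' substantially sharpens downstream area and volume estimates.
#'
#' @param volume the HU [image_volume()].
#' @param mask the binary segmentation of the vessel.
#' @param lumen_hu,background_hu attenuation of pure lumen / pure background.
#' @return A fractional [binary_mask()].
#' @export
refine_mask_fraction <- function(volume, mask, lumen_hu, background_hu) {
  stopifnot(lumen_hu != background_hu)
  bin <- mask_binary_array(mask)
  d <- dim(bin)
  # one-voxel 26-dilation by shifting
  dil <- bin
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    src <- list(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
    sx <- pmin(pmax(src$x + dx, 1), d[1])
    sy <- pmin(pmax(src$y + dy, 1), d[2])
    sz <- pmin(pmax(src$z + dz, 1), d[3])
    dil <- dil | bin[sx, sy, sz]
  }
  f <- (volume$voxels - background_hu) / (lumen_hu - background_hu)
  f <- pmin(pmax(f, 0), 1)
  f[!dil] <- 0
  binary_mask(array(f, dim = d), mask$spacing, mask$origin)
}
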