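#' Spatial data model: CT volumes, masks and world coordinates
#'
#' An `image_volume` is a 3D scalar grid of Hounsfield Units (HU) with
#' per-axis voxel spacing (mm) and a world origin (mm, position of the
#' *center* of voxel `(0,0,0)`).  Voxel indices are 0-based throughout the
#' package and the slice axis is always the third (z) axis; the in-memory
#' orientation is canonical axial LPS (left-posterior-superior), so "right
#' lung" means smaller x.
#'
#' @param voxels 3D numeric array of HU values (finite).
#' @param spacing numeric length-3, voxel size in mm per axis (all > 0).
#' @param origin numeric length-3, world position (mm) of the center of voxel
#'   `(0,0,0)`. Default `c(0,0,0)`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3)
    stop("`voxels` must be a 3D array")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers (mm)")
  if (length(origin) != 3 || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)")
  if (any(!is.finite(voxels)))
    stop("HU values must be finite")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' Binary or fractional lumen mask on an image grid
#'
#' A `binary_mask` shares the grid geometry of its parent volume.  Voxels are
#' either logical (a hard segmentation) or numeric in `[0, 1]` (a
#' partial-volume lumen-fraction mask; its `>= 0.5` level set is the hard
#' mask).
#'
#' @param voxels 3D logical array, or numeric array with values in `[0, 1]`.
#' @param spacing,origin grid geometry, as in [image_volume()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3)
    stop("`voxels` must be a 3D array")
  if (is.numeric(voxels)) {
    rng <- range(voxels)
    if (!all(is.finite(rng)) || rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
      stop("fractional mask values must lie in [0, 1]")
  } else if (!is.logical(voxels)) {
    stop("`voxels` must be logical or numeric in [0, 1]")
  }
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  stopifnot(length(spacing) == 3, all(spacing > 0), length(origin) == 3)
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "binary_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %s mm, origin %s mm, HU [%g, %g]\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ","),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  fg <- if (is.logical(x$voxels)) sum(x$voxels) else sum(x$voxels >= 0.5)
  cat(sprintf("<binary_mask> %s voxels (%s), %d foreground, spacing %s mm\n",
              paste(dim(x$voxels), collapse = "x"),
              if (is.logical(x$voxels)) "binary" else "fractional",
              fg, paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' Hard (logical) view of a possibly fractional mask
#' @param mask a [binary_mask()].
#' @param level lumen-fraction threshold, default 0.5.
#' @return logical 3D array.
#' @export
mask_binary_array <- function(mask, level = 0.5) {
  if (is.logical(mask$voxels)) mask$voxels else mask$voxels >= level
}

#' Map 0-based voxel indices to world coordinates (mm)
#'
#' Uses the voxel-center convention: `world = origin + index * spacing`,
#' with 0-based integer indices.
#'
#' @param volume an [image_volume()] or [binary_mask()].
#' @param index integer triple (0-based), or an n-by-3 matrix of triples.
#' @return numeric length-3 point, or n-by-3 matrix of points (mm).
#' @export
voxel_to_world <- function(volume, index) {
  idx <- if (is.matrix(index)) index else matrix(as.numeric(index), ncol = 3)
  d <- dim(volume$voxels)
  if (any(idx < 0) || any(t(t(idx) - (d - 1)) > 0))
    stop("voxel index out of bounds")
  out <- t(t(idx) * volume$spacing + volume$origin)
  if (is.matrix(index)) out else as.numeric(out)
}

#' Map world coordinates (mm) to the nearest 0-based voxel index
#'
#' Inverse of [voxel_to_world()] up to rounding to the nearest voxel center.
#'
#' @inheritParams voxel_to_world
#' @param point numeric length-3 world point (mm), or n-by-3 matrix.
#' @param clamp if `TRUE`, indices are clamped into the grid instead of
#'   erroring when out of bounds.
#' @return integer triple (0-based) or n-by-3 matrix.
#' @export
world_to_voxel <- function(volume, point, clamp = FALSE) {
  p <- if (is.matrix(point)) point else matrix(as.numeric(point), ncol = 3)
  idx <- .round_half_up(t((t(p) - volume$origin) / volume$spacing))
  d <- dim(volume$voxels)
  if (clamp) {
    idx <- pmax(idx, 0)
    idx <- t(pmin(t(idx), d - 1))
  } else if (any(idx < 0) || any(t(t(idx) - (d - 1)) > 0)) {
    stop("world point maps outside the grid")
  }
  storage.mode(idx) <- "integer"
  if (is.matrix(point)) idx else as.integer(idx)
}

# ---------------------------------------------------------------------------
# File formats
# ---------------------------------------------------------------------------

# half-up rounding: unlike round()'s half-to-even rule it commutes with
# integer shifts, which keeps voxel lookups translation-equivariant
.round_half_up <- function(x) floor(x + 0.5)

.is_nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)
.is_nrrd_path  <- function(path) grepl("\\.nrrd$", path, ignore.case = TRUE)

# decompose an axis-aligned affine into permutation/sign/spacing; errors on
# oblique orientations (reorientation to canonical axial is only supported for
# permutation+flip affines)
.decompose_affine <- function(aff) {
  R <- aff[1:3, 1:3]
  perm <- integer(3); sgn <- numeric(3); sp <- numeric(3)
  for (j in 1:3) {
    col <- R[, j]
    ax <- which.max(abs(col))
    if (any(abs(col[-ax]) > 1e-4 * max(abs(col))))
      stop("oblique image orientation is not supported; reorient the file first")
    perm[j] <- ax
    sgn[j] <- sign(col[ax])
    sp[j] <- abs(col[ax])
  }
  if (length(unique(perm)) != 3) stop("degenerate image affine")
  list(perm = perm, sgn = sgn, spacing = sp, trans = aff[1:3, 4])
}

#' Read a CT volume from NIfTI or NRRD
#'
#' Voxel values are returned unmodified (HU). The file's affine must be
#' axis-aligned (any permutation/flip); the volume is reoriented on read to
#' the canonical orientation with positive, diagonal direction matrix so the
#' third axis is the slice axis. DICOM series are not supported; convert to
#' NIfTI first (NIfTI is the canonical on-disk format of this package).
#'
#' @param path path to a `.nii`, `.nii.gz` or `.nrrd` file.
#' @return An [image_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (dir.exists(path))
    stop("DICOM series directories are not supported; convert to NIfTI")
  if (.is_nifti_path(path)) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) == 4 && dim(arr)[4] == 1) dim(arr) <- dim(arr)[1:3]
    if (length(dim(arr)) != 3) stop("expected a 3D volume in ", path)
    aff <- RNifti::xform(img)
    dec <- .decompose_affine(aff)
    arr2 <- aperm(arr, order(dec$perm))
    sgn <- dec$sgn[order(dec$perm)]
    sp <- dec$spacing[order(dec$perm)]
    org <- dec$trans
    d <- dim(arr2)
    for (ax in 1:3) {
      if (sgn[ax] < 0) {
        arr2 <- .flip_axis(arr2, ax)
        org[ax] <- org[ax] - sp[ax] * (d[ax] - 1)
      }
    }
    image_volume(arr2, sp, org)
  } else if (.is_nrrd_path(path)) {
    .read_nrrd(path)
  } else {
    stop("unsupported volume format: ", path, " (use .nii, .nii.gz or .nrrd)")
  }
}

.flip_axis <- function(arr, ax) {
  idx <- lapply(dim(arr), seq_len)
  idx[[ax]] <- rev(idx[[ax]])
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

#' Write a volume or mask to NIfTI or NRRD
#'
#' Masks are written as 0/1 (or fractional) floating point volumes.
#'
#' @param volume an [image_volume()] or [binary_mask()].
#' @param path output path ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  arr <- volume$voxels
  if (is.logical(arr)) { arr <- array(as.double(arr), dim = dim(arr)) }
  if (.is_nifti_path(path)) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- volume$spacing
    aff <- rbind(cbind(diag(volume$spacing), volume$origin), c(0, 0, 0, 1))
    img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
    img <- RNifti::`qform<-`(img, structure(aff, code = 1L))
    RNifti::writeNifti(img, path)
  } else if (.is_nrrd_path(path)) {
    .write_nrrd(arr, volume$spacing, volume$origin, path)
  } else {
    stop("unsupported volume format: ", path)
  }
  invisible(path)
}

#' @rdname read_volume
#' @details `read_mask()` reads a mask written by [write_volume()]; values in
#'   `(0, 1)` are preserved as a fractional mask, otherwise the mask is
#'   logical.
#' @export
read_mask <- function(path) {
  vol <- read_volume(path)
  v <- vol$voxels
  if (all(v %in% c(0, 1))) v <- array(v == 1, dim = dim(v))
  binary_mask(v, vol$spacing, vol$origin)
}

# --- minimal NRRD (raw encoding, little endian) ----------------------------

.write_nrrd <- function(arr, spacing, origin, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    "type: double",
    "dimension: 3",
    sprintf("sizes: %d %d %d", dim(arr)[1], dim(arr)[2], dim(arr)[3]),
    "encoding: raw",
    "endian: little",
    "space dimension: 3",
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            spacing[1], spacing[2], spacing[3]),
    sprintf("space origin: (%.17g,%.17g,%.17g)", origin[1], origin[2], origin[3]),
    ""
  )
  writeLines(hdr, con, sep = "\n")
  writeBin(as.double(arr), con, size = 8, endian = "little")
  invisible(path)
}

.read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  lines <- character()
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0) stop("truncated NRRD header in ", path)
    if (ln == "") break
    lines <- c(lines, ln)
  }
  if (!grepl("^NRRD", lines[1])) stop("not a NRRD file: ", path)
  field <- function(name) {
    hit <- grep(paste0("^", name, ": "), lines, value = TRUE)
    if (length(hit) == 0) return(NULL)
    sub(paste0("^", name, ": "), "", hit[1])
  }
  type <- field("type") %||% "double"
  sizes <- as.integer(strsplit(field("sizes"), "\\s+")[[1]])
  if (length(sizes) != 3) stop("only 3D NRRD volumes are supported")
  enc <- field("encoding")
  if (!identical(enc, "raw")) stop("only raw NRRD encoding is supported")
  endian <- field("endian") %||% "little"
  nums <- function(s) as.numeric(regmatches(s, gregexpr("-?[0-9.eE+]+", s))[[1]])
  sd_field <- field("space directions")
  spacing <- c(1, 1, 1)
  if (!is.null(sd_field)) {
    m <- matrix(nums(sd_field), nrow = 3, byrow = TRUE)
    if (any(abs(m - diag(diag(m))) > 1e-9))
      stop("oblique NRRD space directions are not supported")
    spacing <- diag(m)
  }
  origin <- c(0, 0, 0)
  if (!is.null(field("space origin"))) origin <- nums(field("space origin"))
  n <- prod(sizes)
  sz <- switch(type, double = 8, float = 4, int = 4, short = 2,
               uchar = 1, stop("unsupported NRRD type: ", type))
  what <- if (type %in% c("double", "float")) "double" else "integer"
  vals <- readBin(con, what, n = n, size = sz, endian = endian,
                  signed = !(type == "uchar"))
  if (length(vals) != n) stop("truncated NRRD data in ", path)
  image_volume(array(as.double(vals), dim = sizes), spacing, origin)
}

# ---------------------------------------------------------------------------
# Centerline and measurement tables
# ---------------------------------------------------------------------------

#' Export a centerline tree as a flat table
#'
#' One row per control point with columns `branch_id`, `point_index`,
#' `x_mm`, `y_mm`, `z_mm`, `arclength_mm`, `area_mm2` (NA when no
#' cross-sectional profile has been attached).
#'
#' @param tree a `centerline_tree` (see [extract_tree()]) or a single
#'   `centerline`.
#' @return data.frame.
#' @export
centerline_table <- function(tree) {
  branches <- if (inherits(tree, "centerline")) list(branch = tree) else tree$branches
  rows <- lapply(names(branches), function(nm) {
    b <- branches[[nm]]
    ar <- b$areas %||% rep(NA_real_, nrow(b$points))
    data.frame(branch_id = nm,
               point_index = seq_len(nrow(b$points)) - 1L,
               x_mm = b$points[, 1], y_mm = b$points[, 2], z_mm = b$points[, 3],
               arclength_mm = b$arclengths, area_mm2 = ar,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname centerline_table
#' @param path output file path (`.csv` or `.json`).
#' @export
write_centerline <- function(tree, path) {
  tab <- centerline_table(tree)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    payload <- list(branches = split(tab[, -1], tab$branch_id))
    if (!is.null(tree$bifurcation)) payload$bifurcation_mm <- tree$bifurcation
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}

#' Write a one-row measurement table
#'
#' Columns are named exactly `D_MPA, A_MPA, V_MPA, D_RPA, A_RPA, V_RPA,
#' D_LPA, A_LPA, V_LPA` to match the cohort schema.
#'
#' @param measurements a `vessel_measurements` object (see [measure_all()]).
#' @param path output CSV path.
#' @export
write_measurements_csv <- function(measurements, path) {
  df <- as.data.frame(as.list(unclass(measurements)))
  names(df) <- toupper(names(df))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
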