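#' Run the full morphometry pipeline
#'
#' Orchestrates phantom (or volume input) -> segmentation -> centerline ->
#' measurement, and optionally a synthetic-cohort statistics stage, writing
#' every intermediate artifact plus a JSON manifest (config hash, per-stage
#' outputs with MD5 checksums, per-stage summaries). With the same config and
#' seed the deterministic stages produce byte-identical outputs and manifest
#' hashes.
#'
#' Config structure (R list, or a path to a YAML/JSON file):
#' \preformatted{
#' seed: 1                  # propagated to every stochastic component
#' outdir: "out"
#' phantom:                 # EITHER a phantom generation block ...
#'   trunk_radius: 18, branch_radii: [12, 12], ... (see make_pa_tree_spec)
#'   spacing: [1, 1, 1], noise_sd: 0
#' volume: "ctpa.nii.gz"    # ... OR an input volume file
#' seed_point: [x, y, z]    # world mm; defaults to the phantom trunk midpoint
#' roi: {min: [..], max: [..]}        # optional
#' segmentation: {hu_lo: -200, hu_hi: 500, connectivity: 26}
#' centerline: {smoothing_factor: 0.5, control_spacing: 1, ...}
#' measurement: {exclusion_margin: 5, diameter_offset: 15, ...}
#' cohort: {n_nonph: 18, n_ph: 41}    # optional statistics stage
#' }
#'
#' @param config nested list or path to a YAML/JSON config file.
#' @param resume if `TRUE`, stages whose outputs already exist in `outdir`
#'   are not recomputed (outputs are re-read instead).
#' @param verbose log per-stage summaries.
#' @return The manifest (invisibly also written to `outdir/manifest.json`).
#' @export
run_pipeline <- function(config, resume = FALSE, verbose = TRUE) {
  if (is.character(config)) config <- .read_config(config)
  .validate_run_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 0
  log <- function(...) if (verbose) message("[pamorph] ", ...)
  manifest <- list(package = "pamorph",
                   version = as.character(utils::packageVersion("pamorph")),
                   seed = seed, config_hash = .config_hash(config),
                   stages = list())
  paths <- list(volume = file.path(outdir, "volume.nii.gz"),
                mask = file.path(outdir, "mask.nii.gz"),
                truth = file.path(outdir, "truth.json"),
                centerline = file.path(outdir, "centerline.csv"),
                measurements = file.path(outdir, "measurements.csv"),
                cohort = file.path(outdir, "cohort.csv"))
  stage <- function(name, outputs, summary)
    manifest$stages[[name]] <<- list(
      outputs = as.list(tools::md5sum(outputs)), summary = summary)

  # ---- input stage ---------------------------------------------------------
  truth <- NULL
  if (!is.null(config$phantom)) {
    ph <- config$phantom
    spec <- do.call(make_pa_tree_spec,
                    c(ph[setdiff(names(ph), c("seed"))],
                      list(seed = ph$seed %||% seed)))
    if (resume && file.exists(paths$volume)) {
      log("input: reusing ", paths$volume)
      vol <- read_volume(paths$volume)
      truth <- .phantom_truth(spec)
    } else {
      rp <- rasterize_phantom(spec)
      vol <- rp$volume; truth <- rp$truth
      write_volume(vol, paths$volume)
      .write_truth_json(truth, spec, paths$truth)
      log("input: rasterized phantom, grid ",
          paste(dim(vol$voxels), collapse = "x"))
    }
    seed_point <- config$seed_point %||%
      as.numeric(curve_point(spec$tubes[[1]]$curve,
                             spec$tubes[[1]]$curve$length / 2))
    stage("input", c(paths$volume,
                     if (file.exists(paths$truth)) paths$truth),
          list(grid = dim(vol$voxels), spacing = vol$spacing))
  } else {
    vol <- read_volume(config$volume)
    seed_point <- as.numeric(config$seed_point)
    file.copy(config$volume, paths$volume, overwrite = TRUE)
    stage("input", paths$volume,
          list(grid = dim(vol$voxels), spacing = vol$spacing))
  }

  # ---- segmentation --------------------------------------------------------
  segcfg <- do.call(segmentation_config, config$segmentation %||% list())
  box <- if (!is.null(config$roi)) roi_box(config$roi$min, config$roi$max)
  if (resume && file.exists(paths$mask)) {
    log("segment: reusing ", paths$mask)
    mask <- read_mask(paths$mask)
  } else {
    mask <- segment_vessel(vol, seed_point, box, segcfg)
    write_volume(mask, paths$mask)
    log("segment: ", sum(mask$voxels), " voxels")
  }
  stage("segment", paths$mask,
        list(foreground_voxels = sum(mask_binary_array(mask)),
             hu_window = c(segcfg$hu_lo, segcfg$hu_hi)))

  # ---- centerline ----------------------------------------------------------
  clcfg <- do.call(centerline_config, config$centerline %||% list())
  if (resume && file.exists(paths$centerline)) {
    log("centerline: reusing ", paths$centerline)
    tree <- .tree_from_table(read.csv(paths$centerline))
  } else {
    skel <- skeletonize(mask)
    tree <- extract_tree(skel, clcfg, seed = seed_point)
    write_centerline(tree, paths$centerline)
    log("centerline: ", length(tree$branches), " branches")
  }
  stage("centerline", paths$centerline,
        list(branches = names(tree$branches),
             lengths_mm = vapply(tree$branches,
                                 function(b) max(b$arclengths), numeric(1)),
             bifurcation_mm = tree$bifurcation))

  # ---- measurement ---------------------------------------------------------
  mcfg <- do.call(measurement_config, config$measurement %||% list())
  meas_mask <- mask
  if (isTRUE(config$refine_partial_volume) && !is.null(config$phantom)) {
    meas_mask <- refine_mask_fraction(vol, mask,
                                      config$phantom$lumen_hu %||% 350,
                                      config$phantom$background_hu %||% -850)
  }
  if (resume && file.exists(paths$measurements)) {
    log("measure: reusing ", paths$measurements)
    mrow <- read.csv(paths$measurements)
    meas <- structure(as.list(setNames(as.numeric(mrow[1, ]),
                                       tolower(names(mrow)))),
                      class = "vessel_measurements")
  } else {
    meas <- measure_all(vol, meas_mask, tree, mcfg)
    write_measurements_csv(meas, paths$measurements)
    log("measure: D_MPA = ", round(meas$d_mpa, 2), " mm, V_MPA = ",
        round(meas$v_mpa, 1), " mm^3")
  }
  stage("measure", paths$measurements,
        list(measurements = unclass(meas)[!is.na(unlist(unclass(meas)))],
             extents = attr(meas, "extents")))

  # ---- statistics (optional) ----------------------------------------------
  if (!is.null(config$cohort)) {
    ccfg <- do.call(cohort_config,
                    c(config$cohort[setdiff(names(config$cohort), "seed")],
                      list(seed = config$cohort$seed %||% seed)))
    if (resume && file.exists(paths$cohort)) {
      log("stats: reusing ", paths$cohort)
      cohort <- read.csv(paths$cohort)
      cohort$group <- factor(cohort$group, levels = c("non-PH", "PH"))
      for (v in names(cohort))
        if (is.character(cohort[[v]]) && all(cohort[[v]] %in% c("TRUE", "FALSE")))
          cohort[[v]] <- cohort[[v]] == "TRUE"
    } else {
      cohort <- attach_categoricals(generate_cohort(ccfg),
                                    seed = ccfg$seed + 1)
      write.csv(cohort, paths$cohort, row.names = FALSE)
    }
    stats_files <- c(comparison = file.path(outdir, "group_comparison.csv"),
                     correlation = file.path(outdir, "correlation.csv"),
                     roc = file.path(outdir, "roc.csv"),
                     delong = file.path(outdir, "delong.csv"),
                     dca = file.path(outdir, "dca.csv"),
                     models = file.path(outdir, "models.json"))
    if (!(resume && all(file.exists(stats_files)))) {
      write.csv(compare_cohort(cohort), stats_files["comparison"], row.names = FALSE)
      write.csv(correlate_cohort(cohort), stats_files["correlation"], row.names = FALSE)
      write.csv(roc_table(cohort), stats_files["roc"], row.names = FALSE)
      write.csv(delong_table(cohort), stats_files["delong"], row.names = FALSE)
      dca <- do.call(rbind, lapply(c("V_MPA", "V_RPA"), function(v) {
        d <- decision_curve(cohort[[v]], cohort$group == "PH")
        d$marker <- v
        d
      }))
      write.csv(dca, stats_files["dca"], row.names = FALSE)
      models <- stepwise_pressures(cohort)
      jsonlite::write_json(lapply(models, unclass), stats_files["models"],
                           auto_unbox = TRUE, digits = NA)
      log("stats: cohort n = ", nrow(cohort))
    }
    stage("stats", c(paths$cohort, unname(stats_files)),
          list(n = nrow(cohort),
               n_ph = sum(cohort$group == "PH")))
  }

  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

.read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs require the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

.validate_run_config <- function(config) {
  if (is.null(config$outdir)) stop("config error: `outdir` is required")
  has_phantom <- !is.null(config$phantom)
  has_volume <- !is.null(config$volume)
  if (has_phantom == has_volume)
    stop("config error: exactly one input source required ",
         "(`phantom` block or `volume` path)")
  if (has_volume && is.null(config$seed_point))
    stop("config error: `seed_point` is required with a `volume` input")
  if (has_volume && !file.exists(config$volume))
    stop("config error: volume file not found: ", config$volume)
  invisible(TRUE)
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.write_truth_json <- function(truth, spec, path) {
  tubes <- lapply(seq_along(truth$tubes), function(i) {
    tt <- truth$tubes[[i]]
    s <- seq(0, tt$length, length.out = 51)
    list(length_mm = tt$length, volume_mm3 = tt$volume,
         arclength_mm = s, radius_mm = tt$radius(s),
         area_mm2 = tt$area(s), centerline_mm = tt$centerline(s))
  })
  jsonlite::write_json(list(tubes = tubes, trunk = truth$trunk,
                            children = truth$children,
                            bifurcation_mm = truth$bifurcation),
                       path, auto_unbox = TRUE, digits = NA)
}

# rebuild a centerline tree from the flat CSV written by write_centerline()
.tree_from_table <- function(tab) {
  branches <- lapply(split(tab, tab$branch_id), function(b) {
    b <- b[order(b$point_index), ]
    pts <- as.matrix(b[, c("x_mm", "y_mm", "z_mm")])
    dimnames(pts) <- NULL
    n <- nrow(pts)
    tan <- matrix(0, n, 3)
    tan[1, ] <- pts[2, ] - pts[1, ]
    tan[n, ] <- pts[n, ] - pts[n - 1, ]
    if (n > 2) tan[2:(n - 1), ] <- pts[3:n, ] - pts[1:(n - 2), ]
    tan <- tan / sqrt(rowSums(tan^2))
    structure(list(points = pts, tangents = tan, arclengths = b$arclength_mm),
              class = "centerline")
  })
  bif <- if (!is.null(branches$child_1)) branches$child_1$points[1, ]
  structure(list(branches = branches, bifurcation = bif),
            class = "centerline_tree")
}
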