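# End-to-end orchestration: scene (or real inputs) -> indices -> mask ->
# crowns -> DEM/CHM -> zonal statistics -> field validation, with every
# resolved parameter logged and all randomness fanned out from one seed.

#' Pipeline configuration
#'
#' Exactly one of `inputs` (paths to a real orthomosaic, DSM and field CSV)
#' or `scene` (overrides for [simulate_scene()]) must be given. The defaults
#' mirror the package's reference analysis: NGBDI masking with an automatic
#' (Otsu) threshold, one ground point per 25 m^2, and a 1 m validation
#' buffer.
#'
#' @param out_dir output directory (created if missing).
#' @param inputs `list(orthomosaic =, dsm =, field_csv =)` paths, or `NULL`.
#' @param scene named list of [simulate_scene()] overrides, or `NULL`; an
#'   empty list runs the default scene.
#' @param index colour index used for masking (default `"NGBDI"`).
#' @param threshold `"auto"` or a number.
#' @param min_patch_area_m2,closing_radius_px mask cleaning parameters.
#' @param simplify_tol_m polygon simplification tolerance; `NULL` = 2 x GSD.
#' @param ground_point_density DEM ground points per m^2.
#' @param buffer_radius_m validation buffer radius (m).
#' @param k_classes number of crown classes.
#' @param write_all_indices write all 12 index rasters (default `TRUE`).
#' @param seed master seed; stages use fixed offsets from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, inputs = NULL, scene = NULL,
                            index = "NGBDI", threshold = "auto",
                            min_patch_area_m2 = 1, closing_radius_px = 1L,
                            simplify_tol_m = NULL,
                            ground_point_density = 1 / 25,
                            buffer_radius_m = 1.0, k_classes = 3L,
                            write_all_indices = TRUE, seed = 1L) {
  if (is.null(inputs) == is.null(scene)) {
    stop("exactly one of `inputs` and `scene` must be given", call. = FALSE)
  }
  if (!is.null(inputs)) {
    need <- c("orthomosaic", "dsm", "field_csv")
    if (!all(need %in% names(inputs))) {
      stop("`inputs` needs elements ", paste(need, collapse = ", "),
           call. = FALSE)
    }
  }
  stopifnot(buffer_radius_m > 0, ground_point_density > 0,
            min_patch_area_m2 >= 0, closing_radius_px >= 0, k_classes >= 1)
  index <- match.arg(index, colour_index_names())
  structure(list(out_dir = out_dir, inputs = inputs, scene = scene,
                 index = index, threshold = threshold,
                 min_patch_area_m2 = min_patch_area_m2,
                 closing_radius_px = as.integer(closing_radius_px),
                 simplify_tol_m = simplify_tol_m,
                 ground_point_density = ground_point_density,
                 buffer_radius_m = buffer_radius_m,
                 k_classes = as.integer(k_classes),
                 write_all_indices = isTRUE(write_all_indices),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input acquisition (synthetic scene or files), band
#' normalisation, colour indices, vegetation mask (threshold + cleaning),
#' crown polygon extraction and classification, ground-point sampling, DEM
#' interpolation, CHM, per-crown zonal statistics, inventory summary, and
#' buffer-based field validation. All artefacts are written under
#' `config$out_dir`; a `run.log` records every resolved parameter. Identical
#' config + seed reproduce byte-identical CSV/JSON artefacts. A stage
#' failure aborts with the stage name and leaves a `FAILED` marker.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with all intermediate objects and artefact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(out, "FAILED"))
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  current_stage <- "setup"
  res <- tryCatch({
    stage <- function(name) current_stage <<- name

    stage("inputs")
    if (!is.null(config$scene)) {
      sim <- do.call(simulate_scene,
                     c(config$scene,
                       if (is.null(config$scene$seed)) list(seed = config$seed)))
      ortho <- sim$ortho; dsm <- sim$dsm; survey <- sim$survey
      write_raster(sim$terrain, file.path(out, "terrain.tif"))
      write_raster(dsm, file.path(out, "dsm.tif"))
      write_raster(ortho, file.path(out, "orthomosaic.tif"), dtype = "float32")
      utils::write.csv(as.data.frame(sim$truth$trees),
                       file.path(out, "truth_trees.csv"), row.names = FALSE,
                       quote = FALSE)
      write_field_csv(survey, file.path(out, "field_survey.csv"))
      for (p in names(sim$params)) {
        note("scene.%s = %s", p, paste(format(sim$params[[p]]), collapse = ", "))
      }
    } else {
      sim <- NULL
      ortho <- read_raster(config$inputs$orthomosaic)
      dsm <- read_raster(config$inputs$dsm)
      survey <- read_field_csv(config$inputs$field_csv)
      note("inputs.orthomosaic = %s", config$inputs$orthomosaic)
      note("inputs.dsm = %s", config$inputs$dsm)
      note("inputs.field_csv = %s", config$inputs$field_csv)
    }
    stop_if_misaligned(ortho$red, dsm, what = "orthomosaic and DSM")

    stage("normalise bands")
    bands <- normalize_bands(ortho)
    write_raster(list(bands$r, bands$g, bands$b),
                 file.path(out, "normalized_bands.tif"))

    stage("colour indices")
    indices <- compute_all_indices(bands)
    if (config$write_all_indices) {
      for (nm in names(indices)) {
        write_raster(indices[[nm]]$grid, file.path(out, paste0(nm, ".tif")))
      }
    }

    stage("vegetation mask")
    mask <- reclassify_index(indices[[config$index]], config$threshold)
    note("mask.index = %s", config$index)
    note("mask.threshold = %.10g (%s)", mask$threshold,
         if (identical(config$threshold, "auto")) "otsu-auto" else "fixed")
    mask <- clean_mask(mask, config$min_patch_area_m2, config$closing_radius_px)
    note("mask.min_patch_area_m2 = %g", config$min_patch_area_m2)
    note("mask.closing_radius_px = %d", config$closing_radius_px)
    mv <- mask$grid$values
    write_raster(mask$grid, file.path(out, "vegetation_mask.tif"),
                 dtype = if (anyNA(mv)) "float32" else "uint8")

    stage("crown polygons")
    tol <- config$simplify_tol_m
    if (is.null(tol)) tol <- 2 * mask$grid$px
    note("crowns.simplify_tol_m = %g", tol)
    crowns <- extract_crown_polygons(mask, tol)
    if (nrow(crowns) >= config$k_classes) {
      crowns <- classify_crowns(indices[[config$index]], crowns,
                                config$k_classes)
    }
    note("crowns.n = %d", nrow(crowns))
    write_crowns_geojson(crowns, file.path(out, "crowns.geojson"))

    stage("DEM / CHM")
    surfaces <- surface_set(dsm, mask,
                            ground_point_density = config$ground_point_density,
                            seed = config$seed + 5L)
    note("dem.ground_points = %d", nrow(surfaces$ground_points))
    note("dem.ground_point_density = %g", config$ground_point_density)
    note("chm.n_clamped = %d", attr(surfaces$chm, "n_clamped"))
    write_ground_points(surfaces$ground_points,
                        file.path(out, "ground_points.csv"))
    write_raster(surfaces$dem, file.path(out, "dem.tif"))
    write_raster(surfaces$chm, file.path(out, "chm.tif"))

    stage("zonal statistics")
    stats <- zonal_stats(surfaces$chm, crowns)
    write_stats_csv(stats, file.path(out, "tree_stats.csv"))
    inventory <- inventory_table(stats)
    write_stats_csv(inventory, file.path(out, "inventory.csv"))

    stage("field validation")
    note("validation.buffer_radius_m = %g", config$buffer_radius_m)
    pairs <- buffer_max_height(surfaces$chm, survey, config$buffer_radius_m)
    validation <- pearson_test(pairs)
    validation_report(validation, file.path(out, "validation.json"))
    note("validation.n = %d, r = %.6f, p = %.6g", validation$n,
         validation$pearson_r, validation$p_value)
    note("seed = %d", config$seed)

    list(sim = sim, bands = bands, indices = indices, mask = mask,
         crowns = crowns, surfaces = surfaces, stats = stats,
         inventory = inventory, pairs = pairs, validation = validation,
         out_dir = out)
  }, error = function(e) {
    writeLines(c(paste("stage:", current_stage), conditionMessage(e)),
               file.path(out, "FAILED"))
    stop("pipeline failed at stage '", current_stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  writeLines(log_lines, file.path(out, "run.log"))
  invisible(res)
}

#' Generate fixture scenes on disk
#'
#' `"tiny"` is a 20 x 20 m, 5-tree scene at 0.2 m GSD meant for fast tests;
#' `"default"` is the full 100 x 100 m reference scene. Writes terrain, DSM,
#' orthomosaic GeoTIFFs, truth and survey CSVs and a `scene.ini` config.
#' Regeneration with the same seed is file-identical.
#'
#' @param out_dir writable output directory.
#' @param size `"tiny"` or `"default"`.
#' @param seed master seed.
#' @return named list of file paths.
#' @export
make_fixtures <- function(out_dir, size = c("tiny", "default"), seed = 1L) {
  size <- match.arg(size)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  overrides <- if (size == "tiny") {
    list(extent = c(0, 0, 20, 20), gsd = 0.2, n_trees = 5,
         height_range = c(8, 15), min_spacing = 4,
         relief_amplitude = 1, correlation_length = 10,
         n_field_points = 5)
  } else {
    list()
  }
  sim <- do.call(simulate_scene, c(overrides, list(seed = seed)))
  paths <- list(
    terrain = file.path(out_dir, "terrain.tif"),
    dsm = file.path(out_dir, "dsm.tif"),
    orthomosaic = file.path(out_dir, "orthomosaic.tif"),
    truth = file.path(out_dir, "truth_trees.csv"),
    survey = file.path(out_dir, "field_survey.csv"),
    config = file.path(out_dir, "scene.ini")
  )
  write_raster(sim$terrain, paths$terrain)
  write_raster(sim$dsm, paths$dsm)
  write_raster(sim$ortho, paths$orthomosaic, dtype = "float32")
  utils::write.csv(as.data.frame(sim$truth$trees), paths$truth,
                   row.names = FALSE, quote = FALSE)
  write_field_csv(sim$survey, paths$survey)
  ini <- unlist(lapply(names(sim$params), function(p) {
    sprintf("%s = %s", p, paste(format(sim$params[[p]]), collapse = ","))
  }))
  writeLines(c("# forestchm scene configuration", ini), paths$config)
  invisible(paths)
}

#' Read a flat key-value scene/pipeline configuration
#'
#' INI-style `key = value` lines (`#` comments allowed). Comma-separated
#' values become numeric vectors where possible.
#'
#' @param path config file path.
#' @return named list of parsed values.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) next
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else val
  }
  out
}
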