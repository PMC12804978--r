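#' Analysis configuration
#'
#' The single parameter set driving the whole pipeline. Unknown keys are
#' rejected so a typo cannot silently fall back to a default. The full
#' configuration is serialized verbatim into analysis.json, which therefore
#' suffices to reproduce a run.
#'
#' @param wall_smoothing_sigma Gaussian sigma (px) for the wall channel.
#' @param wall_threshold_method "otsu" or "fixed".
#' @param wall_threshold_value threshold for the fixed method (NA otherwise).
#' @param invert_walls flip wall-channel contrast before thresholding.
#' @param prune_length_px skeleton spur-pruning length (px).
#' @param puncta_smoothing_sigma Gaussian sigma (px) for the puncta channel.
#' @param background_radius_px rolling-background disk radius (px).
#' @param min_peak_intensity punctum detection threshold (a.u.), or "auto".
#' @param min_separation_px minimum distance between retained maxima (px).
#' @param integration_radius_px punctum integration disk radius (px).
#' @param parent_search_tolerance_um maximum punctum-to-wall distance (um)
#'   before a punctum is orphaned.
#' @param heatmap_metric per-cell metric for the heat map output.
#' @param colormap colormap name for visual outputs.
#' @param pixel_size_override micrometres per pixel, overriding file
#'   metadata (NA to use metadata).
#' @return a named list of class `pdq_config`.
#' @export
analysisConfig <- function(wall_smoothing_sigma = 1,
                           wall_threshold_method = "otsu",
                           wall_threshold_value = NA_real_,
                           invert_walls = FALSE,
                           prune_length_px = 3,
                           puncta_smoothing_sigma = 1,
                           background_radius_px = 10,
                           min_peak_intensity = "auto",
                           min_separation_px = 2,
                           integration_radius_px = 3,
                           parent_search_tolerance_um = 0.5,
                           heatmap_metric = "periphery_callose_sum",
                           colormap = "viridis",
                           pixel_size_override = NA_real_) {
  cfg <- as.list(environment())
  structure(cfg, class = c("pdq_config", "list"))
}

#' Build a configuration from a named list
#'
#' Merges user values (e.g. parsed from a JSON config file) over the
#' defaults; unknown keys are an error.
#'
#' @param values named list of parameter overrides.
#' @return a `pdq_config` list.
#' @export
configFromList <- function(values) {
  defaults <- analysisConfig()
  unknown <- setdiff(names(values), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  for (nm in names(values)) defaults[[nm]] <- values[[nm]]
  defaults
}

withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage %s: %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Analyze a single two-channel image end to end
#'
#' Runs read, wall segmentation, punctum detection, relational graph
#' assembly, quantification and (optionally) output writing with one
#' configuration. Per-stage counts are logged to stderr; errors name their
#' stage.
#'
#' @param input a multi-page TIFF path or a [TissueImage-class].
#' @param config a `pdq_config` list from [analysisConfig()].
#' @param out_dir optional output directory; when given, all artifacts
#'   (CSVs, analysis.json, PNGs, heat map) are written there.
#' @param condition_label condition label recorded with the image (used
#'   when `input` is a path).
#' @return invisible list: `record`, `graph`, `image`, `cellTable`,
#'   `wallTable`, `files` (written paths, possibly empty).
#' @export
analyzeSingle <- function(input, config = analysisConfig(), out_dir = NULL,
                          condition_label = "unknown") {
  stopifnot(inherits(config, "pdq_config"))
  image <- withStage("read", {
    if (is(input, "TissueImage")) input else
      readTissueImage(input,
        pixel_size_override = if (is.na(config$pixel_size_override)) NULL
          else config$pixel_size_override,
        condition_label = condition_label)
  })
  ps <- pixelSize(image)
  skel <- withStage("walls", {
    mask <- preprocessWalls(wallChannel(image),
                            smoothing_sigma = config$wall_smoothing_sigma,
                            threshold_method = config$wall_threshold_method,
                            threshold_value =
                              if (is.na(config$wall_threshold_value)) NULL
                              else config$wall_threshold_value,
                            invert = config$invert_walls)
    skeletonizeWalls(mask, prune_length_px = config$prune_length_px)
  })
  message(sprintf("walls: %d skeleton px", sum(skeletonMask(skel))))
  pcn <- withStage("puncta", {
    det <- preprocessPuncta(punctaChannel(image),
                            smoothing_sigma = config$puncta_smoothing_sigma,
                            background_radius = config$background_radius_px)
    pk <- detectLocalMaxima(det, min_intensity = config$min_peak_intensity,
                            min_separation = config$min_separation_px)
    measureIntensity(punctaChannel(image), pk,
                     radius = config$integration_radius_px)
  })
  message(sprintf("puncta: %d detected", nrow(pcn)))
  graph <- withStage("graph", {
    jn <- findJunctions(skel)
    wl <- splitWalls(skel, jn, pixel_size = ps)
    cl <- labelCells(skel, pixel_size = ps)
    buildWallGraph(cl, wl, jn, pcn, skel, pixel_size = ps,
                   tolerance_um = config$parent_search_tolerance_um)
  })
  message(sprintf("graph: %d cells, %d walls, %d junctions, %d orphans",
                  nrow(cells(graph)), nrow(walls(graph)),
                  nrow(junctions(graph)), sum(puncta(graph)$wall_id == 0)))
  qt <- withStage("quantify", {
    wallTable <- perWallTable(graph, punctaChannel(image))
    cellTable <- perCellTable(graph, wallTable)
    list(wallTable = wallTable, cellTable = cellTable)
  })
  record <- buildAnalysisRecord(graph, qt$cellTable, qt$wallTable,
                                unclass(config), image)
  files <- character(0)
  if (!is.null(out_dir)) {
    files <- withStage("write", {
      fs <- writeOutputs(record, out_dir, image = image, graph = graph)
      if (nrow(qt$cellTable)) {
        hm <- file.path(out_dir, "cell_heatmap.png")
        renderCellHeatmap(graph, qt$cellTable, metric = config$heatmap_metric,
                          colormap = config$colormap, path = hm)
        fs <- c(fs, hm)
      }
      fs
    })
  }
  invisible(list(record = record, graph = graph, image = image,
                 cellTable = qt$cellTable, wallTable = qt$wallTable,
                 files = files))
}

#' Analyze a directory (or set) of images
#'
#' Runs [analyzeSingle()] per image into one subdirectory each; failures are
#' isolated per image and reported, not propagated. A pooled per-condition
#' summary (cell counts and per-cell callose means weighted by cell counts,
#' punctum totals and densities) is written to `pooled_summary.csv`.
#' Conditions come from an optional manifest (columns `filename`,
#' `condition`); unlisted files get condition "unknown".
#'
#' @param inputs a directory of TIFFs or a character vector of paths.
#' @param config a `pdq_config` list.
#' @param out_dir output root directory.
#' @param manifest optional data.frame or CSV path: filename, condition.
#' @return list: `results` (per successful image), `summary` (pooled
#'   data.frame), `failures` (named character of error messages).
#' @export
analyzeBatch <- function(inputs, config = analysisConfig(), out_dir,
                         manifest = NULL) {
  if (length(inputs) == 1 && dir.exists(inputs))
    inputs <- list.files(inputs, pattern = "\\.tiff?$", full.names = TRUE,
                         ignore.case = TRUE)
  if (!length(inputs)) stop("no input images")
  if (is.character(manifest) && length(manifest) == 1)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  condOf <- function(f) {
    if (is.null(manifest)) return("unknown")
    hit <- match(basename(f), manifest$filename)
    if (is.na(hit)) "unknown" else manifest$condition[hit]
  }
  results <- list()
  failures <- character(0)
  for (f in inputs) {
    nm <- sub("\\.[^.]+$", "", basename(f))
    res <- tryCatch(
      analyzeSingle(f, config,
                    out_dir = file.path(out_dir, nm),
                    condition_label = condOf(f)),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[nm] <- conditionMessage(res)
      message(sprintf("FAILED %s: %s", nm, conditionMessage(res)))
    } else {
      results[[nm]] <- res
    }
  }
  summary <- poolBatchSummary(results)
  if (!is.null(summary) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  if (!is.null(summary))
    utils::write.csv(summary, file.path(out_dir, "pooled_summary.csv"),
                     row.names = FALSE)
  list(results = results, summary = summary, failures = failures)
}

poolBatchSummary <- function(results) {
  if (!length(results)) return(NULL)
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(image = nm,
               condition = r$image@conditionLabel,
               n_cells = nrow(r$cellTable),
               mean_periphery_callose =
                 if (nrow(r$cellTable)) mean(r$cellTable$periphery_callose_sum)
                 else NA_real_,
               n_pd = nrow(puncta(r$graph)),
               total_wall_um = sum(r$wallTable$length_um))
  })
  per <- do.call(rbind, rows)
  agg <- lapply(split(per, per$condition), function(g) {
    data.frame(condition = g$condition[1],
               n_images = nrow(g),
               n_cells = sum(g$n_cells),
               mean_periphery_callose =
                 sum(g$mean_periphery_callose * g$n_cells, na.rm = TRUE) /
                 sum(g$n_cells),
               n_pd = sum(g$n_pd),
               pd_per_um = sum(g$n_pd) / sum(g$total_wall_um))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Simulate a tissue image to disk
#'
#' Convenience wrapper chaining [makeTessellation()], [placePuncta()] and
#' [renderTissue()], writing the rendered two-channel TIFF plus a
#' ground_truth.json side-car holding the exact geometry for direct
#' comparison with analysis output.
#'
#' @param path output TIFF path.
#' @param nx,ny,jitter,cell_pitch_um,pixel_size,seed tessellation
#'   parameters, see [makeTessellation()].
#' @param rate,min_gap_um punctum placement parameters, see [placePuncta()].
#' @param ... further render parameters passed to [makeTessellation()].
#' @return invisible list: `gt` (the [GroundTruth-class]), `image`, `files`.
#' @export
simulateTissue <- function(path, nx = 6, ny = 6, jitter = 0.2,
                           cell_pitch_um = 5, pixel_size = 0.2, seed = 1,
                           rate = 0.5, min_gap_um = 0, ...) {
  if (!dir.exists(dirname(path)))
    dir.create(dirname(path), recursive = TRUE)
  gt <- makeTessellation(nx, ny, jitter = jitter,
                         cell_pitch_um = cell_pitch_um,
                         pixel_size = pixel_size, seed = seed, ...)
  gt <- placePuncta(gt, rate = rate, min_gap_um = min_gap_um, seed = seed + 1)
  img <- renderTissue(gt, seed = seed + 2)
  writeTissueImage(img, path)
  side <- sub("\\.[^.]+$", "", path)
  gtPath <- paste0(side, "_ground_truth.json")
  writeGroundTruthJson(gt, gtPath)
  invisible(list(gt = gt, image = img, files = c(path, gtPath)))
}

#' Write ground truth as JSON
#'
#' Geometry converted to the analysis output conventions (0-based pixel
#' coordinates) so ground truth and analysis.json can be compared directly.
#'
#' @param gt a [GroundTruth-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGroundTruthJson <- function(gt, path) {
  ps <- pixelSize(gt)
  toPx <- function(um) um / ps - 0.5
  obj <- list(
    cells = data.frame(cell_id = gt@cells$cell_id,
                       seed_row = toPx(gt@cells$seed_y),
                       seed_col = toPx(gt@cells$seed_x)),
    walls = gt@walls,
    junctions = data.frame(junction_id = gt@junctions$junction_id,
                           row = toPx(gt@junctions$y),
                           col = toPx(gt@junctions$x)),
    puncta = data.frame(punctum_id = gt@puncta$punctum_id,
                        row = toPx(gt@puncta$y),
                        col = toPx(gt@puncta$x),
                        wall_id = gt@puncta$wall_id,
                        amplitude = gt@puncta$amplitude),
    pixel_size_um = ps,
    image_shape = gt@imageShape,
    render_params = gt@renderParams,
    seed = gt@seed)
  writeLines(jsonlite::toJSON(obj, dataframe = "columns", digits = I(17),
                              auto_unbox = TRUE, pretty = TRUE), path)
  invisible(path)
}
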