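# Output artifact writers. Conventions, stated in every header: coordinates
# are 0-based (row, col) pixel centers; lengths/areas are micrometres /
# square micrometres; sentinel "BORDER" marks a wall's missing second cell
# at the image border, "ORPHAN" a punctum beyond the parent-search
# tolerance.

CELLS_COLS <- c("cell_id", "centroid_row", "centroid_col", "area_um2",
                "n_walls", "periphery_callose_sum", "n_pd", "pd_per_um")
WALLS_COLS <- c("wall_id", "junction_id_a", "junction_id_b", "cell_id_1",
                "cell_id_2", "length_um", "mean_callose_intensity", "n_pd",
                "pd_total_intensity", "pd_per_um")
JUNCTIONS_COLS <- c("junction_id", "row", "col", "wall_ids")
PUNCTA_COLS <- c("punctum_id", "row", "col", "peak_intensity",
                 "integrated_intensity", "wall_id", "distance_to_wall_um")

# column types used to rebuild tables losslessly from JSON
RECORD_SCHEMAS <- list(
  cells = c(cell_id = "integer", centroid_row = "numeric",
            centroid_col = "numeric", area_um2 = "numeric",
            n_walls = "integer", periphery_callose_sum = "numeric",
            n_pd = "integer", pd_per_um = "numeric"),
  walls = c(wall_id = "integer", junction_id_a = "integer",
            junction_id_b = "integer", cell_id_1 = "character",
            cell_id_2 = "character", length_um = "numeric",
            mean_callose_intensity = "numeric", n_pd = "integer",
            pd_total_intensity = "numeric", pd_per_um = "numeric"),
  junctions = c(junction_id = "integer", row = "numeric", col = "numeric",
                wall_ids = "character"),
  puncta = c(punctum_id = "integer", row = "numeric", col = "numeric",
             peak_intensity = "numeric", integrated_intensity = "numeric",
             wall_id = "character", distance_to_wall_um = "numeric")
)

#' Build the analysis record from pipeline results
#'
#' Converts the relational graph and quantification tables into the fixed
#' output schema: 0-based pixel coordinates, micrometre units, sentinel
#' strings for border walls and orphan puncta.
#'
#' @param graph a validated [WallGraph-class].
#' @param cellTable output of [perCellTable()].
#' @param wallTable output of [perWallTable()].
#' @param config the full parameter list used.
#' @param image the analyzed [TissueImage-class].
#' @return an [AnalysisRecord-class].
#' @export
buildAnalysisRecord <- function(graph, cellTable, wallTable, config, image) {
  sent <- function(ids) ifelse(ids == 0, BORDER_SENTINEL, as.character(ids))
  cellsOut <- data.frame(
    cell_id = as.integer(cellTable$cell_id),
    centroid_row = cellTable$centroid_row - 1,
    centroid_col = cellTable$centroid_col - 1,
    area_um2 = cellTable$area_um2,
    n_walls = as.integer(cellTable$n_walls),
    periphery_callose_sum = cellTable$periphery_callose_sum,
    n_pd = as.integer(cellTable$n_pd),
    pd_per_um = cellTable$pd_per_um)
  wallsOut <- data.frame(
    wall_id = as.integer(wallTable$wall_id),
    junction_id_a = as.integer(wallTable$junction_id_a),
    junction_id_b = as.integer(wallTable$junction_id_b),
    cell_id_1 = sent(wallTable$cell_id_1),
    cell_id_2 = sent(wallTable$cell_id_2),
    length_um = wallTable$length_um,
    mean_callose_intensity = wallTable$mean_callose_intensity,
    n_pd = as.integer(wallTable$n_pd),
    pd_total_intensity = wallTable$pd_total_intensity,
    pd_per_um = wallTable$pd_per_um)
  jn <- junctions(graph)
  junctionsOut <- data.frame(
    junction_id = as.integer(jn$junction_id),
    row = jn$row - 1, col = jn$col - 1,
    wall_ids = vapply(
      if (nrow(jn)) jn$wall_ids else list(),
      function(v) paste(v, collapse = ";"), character(1)))
  pc <- puncta(graph)
  punctaOut <- data.frame(
    punctum_id = as.integer(pc$punctum_id),
    row = pc$row - 1, col = pc$col - 1,
    peak_intensity = pc$peak_intensity,
    integrated_intensity = pc$integrated_intensity,
    wall_id = ifelse(pc$wall_id == 0, ORPHAN_SENTINEL,
                     as.character(pc$wall_id)),
    distance_to_wall_um = pc$distance_um)
  new("AnalysisRecord",
      config = config,
      metadata = list(rows = nrow(wallChannel(image)),
                      cols = ncol(wallChannel(image)),
                      pixel_size_um = pixelSize(image),
                      source_id = image@sourceId,
                      condition_label = image@conditionLabel),
      cells = cellsOut, walls = wallsOut, junctions = junctionsOut,
      puncta = punctaOut,
      version = as.character(utils::packageVersion("pdquant")))
}

# typed empty table for one of the four record schemas
jsonToEmptyTable <- function(name) {
  schema <- RECORD_SCHEMAS[[name]]
  out <- lapply(unname(schema), function(tp) vector(tp, 0))
  names(out) <- names(schema)
  as.data.frame(out, stringsAsFactors = FALSE)
}

recordTables <- function(record)
  list(cells = record@cells, walls = record@walls,
       junctions = record@junctions, puncta = record@puncta)

checkRecord <- function(record) {
  tb <- recordTables(record)
  for (nm in names(RECORD_SCHEMAS)) {
    want <- names(RECORD_SCHEMAS[[nm]])
    if (!identical(names(tb[[nm]]), want))
      stop(sprintf("record table '%s' has wrong columns", nm))
  }
  w <- tb$walls; p <- tb$puncta; cl <- tb$cells
  refc <- setdiff(unique(c(w$cell_id_1, w$cell_id_2)), BORDER_SENTINEL)
  if (!all(refc %in% as.character(cl$cell_id)))
    stop("record integrity: wall references unknown cell id")
  refw <- setdiff(unique(p$wall_id), ORPHAN_SENTINEL)
  if (!all(refw %in% as.character(w$wall_id)))
    stop("record integrity: punctum references unknown wall id")
  invisible(TRUE)
}

#' Write all analysis outputs
#'
#' Writes the four CSV tables (fixed column order), the comprehensive
#' analysis.json (configuration, image metadata, all tables, software
#' version), one grayscale PNG per channel, and a composite overlay PNG with
#' the skeleton, junction and punctum markers. PNGs require `image` (and the
#' overlay additionally `graph`).
#'
#' @param record an [AnalysisRecord-class].
#' @param out_dir output directory (created if absent).
#' @param image optional [TissueImage-class] for the channel PNGs.
#' @param graph optional [WallGraph-class] for the overlay PNG.
#' @return character vector of written paths.
#' @export
writeOutputs <- function(record, out_dir, image = NULL, graph = NULL) {
  checkRecord(record)
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("output directory not writable")
  tb <- recordTables(record)
  paths <- character(0)
  for (nm in names(tb)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tb[[nm]], f, row.names = FALSE, na = "")
    paths <- c(paths, f)
  }
  jf <- file.path(out_dir, "analysis.json")
  writeAnalysisJson(record, jf)
  paths <- c(paths, jf)
  if (!is.null(image)) {
    toPng <- function(m, f) {
      rng <- range(m)
      g <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
      png::writePNG(g, f)
      f
    }
    paths <- c(paths,
               toPng(wallChannel(image), file.path(out_dir, "walls.png")),
               toPng(punctaChannel(image), file.path(out_dir, "puncta.png")))
    if (!is.null(graph)) {
      ov <- renderOverlay(image, graph)
      f <- file.path(out_dir, "overlay.png")
      png::writePNG(ov, f)
      paths <- c(paths, f)
    }
  }
  paths
}

#' Serialize an analysis record to JSON
#'
#' Top-level keys: config, metadata, cells, walls, junctions, puncta,
#' version. Numbers are written at full precision so the record round-trips
#' losslessly through [readAnalysisJson()].
#'
#' @param record an [AnalysisRecord-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeAnalysisJson <- function(record, path) {
  obj <- list(config = record@config, metadata = record@metadata,
              cells = record@cells, walls = record@walls,
              junctions = record@junctions, puncta = record@puncta,
              version = record@version)
  json <- jsonlite::toJSON(obj, dataframe = "columns", digits = I(17),
                           auto_unbox = TRUE, na = "null", null = "null",
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read an analysis record back from JSON
#'
#' Inverse of [writeAnalysisJson()]; rebuilds every table with its exact
#' column types.
#'
#' @param path analysis.json path.
#' @return an [AnalysisRecord-class].
#' @export
readAnalysisJson <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  coerce <- function(tab, schema) {
    out <- lapply(names(schema), function(cn) {
      v <- tab[[cn]]
      if (is.null(v) || (is.list(v) && !length(v)))
        v <- vector(schema[[cn]], 0)
      # explicit coercers: as(x, "numeric") would keep integers integer
      switch(schema[[cn]],
             integer = as.integer(v),
             numeric = as.numeric(v),
             character = as.character(v))
    })
    names(out) <- names(schema)
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  new("AnalysisRecord",
      config = obj$config,
      metadata = obj$metadata,
      cells = coerce(obj$cells, as.list(RECORD_SCHEMAS$cells)),
      walls = coerce(obj$walls, as.list(RECORD_SCHEMAS$walls)),
      junctions = coerce(obj$junctions, as.list(RECORD_SCHEMAS$junctions)),
      puncta = coerce(obj$puncta, as.list(RECORD_SCHEMAS$puncta)),
      version = obj$version)
}

#' Pack an output directory into a zip archive
#'
#' Archives every file in `out_dir` (paths stored relative to it) into a
#' single zip. Unpacking reproduces the files byte for byte.
#'
#' @param out_dir directory of analysis outputs.
#' @param zipfile archive path; defaults to `<out_dir>/analysis_outputs.zip`.
#' @return the zip path.
#' @export
packArchive <- function(out_dir, zipfile = NULL) {
  if (!dir.exists(out_dir)) stop("output directory does not exist")
  if (is.null(zipfile)) zipfile <- file.path(out_dir, "analysis_outputs.zip")
  files <- list.files(out_dir, recursive = TRUE)
  files <- setdiff(files, basename(zipfile))
  if (!length(files)) stop("empty directory: nothing to archive")
  zipAbs <- file.path(normalizePath(dirname(zipfile), mustWork = FALSE),
                      basename(zipfile))
  zip::zip(zipfile = zipAbs, files = files, root = out_dir, mode = "mirror")
  zipAbs
}
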