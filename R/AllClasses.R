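#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib pdquant, .registration = TRUE
NULL

BORDER_SENTINEL <- "BORDER"
ORPHAN_SENTINEL <- "ORPHAN"

#' Two-channel tissue image
#'
#' Container for one registered two-channel field of view: channel 1 stains
#' the cell walls, channel 2 the callose/plasmodesmata immunosignal. Both
#' channels are numeric matrices of identical dimensions with finite,
#' non-negative intensities in arbitrary units; the pixel size is isotropic
#' and given in micrometres per pixel.
#'
#' @slot wallChannel numeric matrix, wall-stain intensities.
#' @slot punctaChannel numeric matrix, callose/PD intensities, same shape.
#' @slot pixelSize numeric(1), micrometres per pixel, > 0.
#' @slot sourceId free-text provenance label.
#' @slot conditionLabel free-text experimental condition.
#'
#' @seealso [TissueImage()] for the constructor, [readTissueImage()] to load
#'   from a multi-page TIFF.
#' @export
setClass("TissueImage",
  representation(
    wallChannel = "matrix",
    punctaChannel = "matrix",
    pixelSize = "numeric",
    sourceId = "character",
    conditionLabel = "character"
  )
)

setValidity("TissueImage", function(object) {
  msg <- character()
  if (!identical(dim(object@wallChannel), dim(object@punctaChannel)))
    msg <- c(msg, "wall and puncta channels must share identical dimensions")
  if (length(object@pixelSize) != 1 || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  for (ch in c("wallChannel", "punctaChannel")) {
    v <- slot(object, ch)
    if (!all(is.finite(v)))
      msg <- c(msg, paste0(ch, " contains non-finite values"))
    else if (any(v < 0))
      msg <- c(msg, paste0(ch, " contains negative intensities"))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn TissueImage-class Construct a TissueImage from two matrices.
#' @param wallChannel,punctaChannel numeric matrices of identical shape.
#' @param pixelSize micrometres per pixel.
#' @param sourceId,conditionLabel free-text labels.
#' @export
TissueImage <- function(wallChannel, punctaChannel, pixelSize,
                        sourceId = "unknown", conditionLabel = "unknown") {
  new("TissueImage",
    wallChannel = wallChannel, punctaChannel = punctaChannel,
    pixelSize = as.numeric(pixelSize), sourceId = sourceId,
    conditionLabel = conditionLabel)
}

#' One-pixel-wide wall skeleton
#'
#' A topology-preserving thinning of the binary wall mask, together with the
#' per-pixel count of 8-connected skeleton neighbours (the degree map) used
#' for junction detection.
#'
#' @slot mask logical matrix of skeleton pixels.
#' @slot degree integer matrix, 8-neighbour count at skeleton pixels, 0
#'   elsewhere.
#' @export
setClass("WallSkeleton",
  representation(mask = "matrix", degree = "matrix"))

setValidity("WallSkeleton", function(object) {
  if (!identical(dim(object@mask), dim(object@degree)))
    return("mask and degree must share dimensions")
  TRUE
})

#' Relational cell-wall-junction-punctum graph
#'
#' The assembled relational model of one image: cells (wall-enclosed
#' regions), wall segments (skeleton chains between junctions), junction
#' points (branch-pixel clusters) and detected puncta, plus the association
#' maps linking them (punctum to parent wall, wall to its one or two
#' adjacent cells, junction to its connected walls). Internal coordinates
#' are 1-based pixel indices; lengths and distances are in micrometres.
#'
#' @slot cells data.frame: cell_id, centroid_row, centroid_col, area_px,
#'   area_um2, wall_ids (list column).
#' @slot walls data.frame: wall_id, junction_id_a, junction_id_b (NA for
#'   closed loops / dead ends), cell_id_1, cell_id_2 (0 = image border),
#'   length_um, n_px, closed.
#' @slot junctions data.frame: junction_id, row, col, wall_ids (list
#'   column), degenerate flag (fewer than 3 walls after pruning).
#' @slot puncta data.frame: punctum_id, row, col, peak_intensity,
#'   integrated_intensity, clipped, wall_id (0 = orphan), distance_um.
#' @slot wallPaths list of ordered n x 2 integer path matrices, one per wall.
#' @slot cellLabels integer matrix labelling cell regions (0 = background
#'   and walls).
#' @slot skeleton logical matrix, the wall skeleton the graph was built from.
#' @slot pixelSize micrometres per pixel.
#' @export
setClass("WallGraph",
  representation(
    cells = "data.frame",
    walls = "data.frame",
    junctions = "data.frame",
    puncta = "data.frame",
    wallPaths = "list",
    cellLabels = "matrix",
    skeleton = "matrix",
    pixelSize = "numeric"
  )
)

setValidity("WallGraph", function(object) {
  msg <- character()
  w <- object@walls
  cl <- object@cells
  jn <- object@junctions
  pc <- object@puncta
  if (nrow(w) != length(object@wallPaths))
    msg <- c(msg, "one path per wall required")
  if (nrow(w)) {
    interior <- w$cell_id_1 != 0 & w$cell_id_2 != 0
    if (any(interior & w$cell_id_1 == w$cell_id_2))
      msg <- c(msg, sprintf(
        "interior wall(s) %s do not separate two distinct cells",
        paste(w$wall_id[interior & w$cell_id_1 == w$cell_id_2], collapse = ",")))
    ref <- unique(c(w$cell_id_1, w$cell_id_2))
    ref <- ref[ref != 0]
    if (!all(ref %in% cl$cell_id))
      msg <- c(msg, "wall references unknown cell id")
  }
  if (nrow(pc)) {
    assigned <- pc$wall_id != 0
    if (!all(pc$wall_id[assigned] %in% w$wall_id))
      msg <- c(msg, "punctum references unknown wall id")
    if (any(is.na(pc$wall_id)))
      msg <- c(msg, "punctum with undefined parent (neither wall nor orphan)")
  }
  # mutual consistency of cell <-> wall maps
  if (nrow(cl) && nrow(w)) {
    for (i in seq_len(nrow(cl))) {
      wids <- cl$wall_ids[[i]]
      touches <- w$cell_id_1[match(wids, w$wall_id)] == cl$cell_id[i] |
        w$cell_id_2[match(wids, w$wall_id)] == cl$cell_id[i]
      if (!all(touches)) {
        msg <- c(msg, sprintf("cell %d lists wall(s) that do not list it back",
                              cl$cell_id[i]))
        break
      }
    }
  }
  if (nrow(jn) && nrow(w)) {
    for (i in seq_len(nrow(jn))) {
      wids <- jn$wall_ids[[i]]
      ok <- w$junction_id_a[match(wids, w$wall_id)] %in% jn$junction_id[i] |
        w$junction_id_b[match(wids, w$wall_id)] %in% jn$junction_id[i]
      if (length(wids) && !all(ok, na.rm = FALSE)) {
        msg <- c(msg, sprintf("junction %d lists wall(s) that do not list it back",
                              jn$junction_id[i]))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic tissue ground truth
#'
#' Exact geometry of a generated polygonal tessellation: cell seeds, wall
#' polylines, junction coordinates and punctum positions with their true
#' parent walls, plus the render parameters. Serves as the oracle for every
#' pipeline stage. All geometry is in micrometres in the image frame
#' (x = column direction, y = row direction, origin at the image corner).
#'
#' @slot cells data.frame: cell_id, seed_x, seed_y.
#' @slot walls data.frame: wall_id, junction_id_a, junction_id_b (NA for a
#'   closed loop), cell_id_1, cell_id_2 (0 = frame border), length_um.
#' @slot wallPolylines list of k x 2 matrices (x, y) in micrometres.
#' @slot junctions data.frame: junction_id, x, y.
#' @slot puncta data.frame: punctum_id, x, y, wall_id, amplitude.
#' @slot pixelSize micrometres per pixel.
#' @slot imageShape integer(2): rows, cols of the rendered frame.
#' @slot renderParams list: wall_width_px, psf_sigma_px, noise_sd,
#'   background, wall_amplitude, punctum_amplitude.
#' @slot seed integer seed the tessellation was drawn with.
#' @export
setClass("GroundTruth",
  representation(
    cells = "data.frame",
    walls = "data.frame",
    wallPolylines = "list",
    junctions = "data.frame",
    puncta = "data.frame",
    pixelSize = "numeric",
    imageShape = "integer",
    renderParams = "list",
    seed = "integer"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (nrow(object@walls) != length(object@wallPolylines))
    msg <- c(msg, "one polyline per wall required")
  if (nrow(object@puncta) &&
      !all(object@puncta$wall_id %in% object@walls$wall_id))
    msg <- c(msg, "punctum references unknown wall")
  if (length(msg)) msg else TRUE
})

#' Bud-break timing sample
#'
#' Days-to-bud-break for one genotype x temperature condition. `days` holds
#' only the plants that broke bud; `nTotal` is the number assayed, so
#' censored plants (never broke) are `nTotal - length(days)`.
#'
#' @slot label genotype/condition text.
#' @slot days positive numeric vector of days to bud break.
#' @slot nTotal integer, plants assayed.
#' @export
setClass("TimingSample",
  representation(label = "character", days = "numeric", nTotal = "integer"))

setValidity("TimingSample", function(object) {
  msg <- character()
  if (length(object@days) > object@nTotal)
    msg <- c(msg, "more bud-break events than plants assayed")
  if (length(object@days) && any(!is.finite(object@days) | object@days <= 0))
    msg <- c(msg, "days must be positive and finite")
  if (object@nTotal < 0) msg <- c(msg, "nTotal must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @describeIn TimingSample-class Constructor.
#' @param label condition label.
#' @param days days to bud break for plants that broke bud.
#' @param nTotal total plants assayed (defaults to `length(days)`).
#' @export
TimingSample <- function(label, days, nTotal = length(days)) {
  new("TimingSample", label = label, days = as.numeric(days),
      nTotal = as.integer(nTotal))
}

#' Complete analysis record
#'
#' Everything one run produces: the configuration used, image metadata, the
#' four result tables exactly as written to CSV (0-based pixel coordinates,
#' sentinel strings `"BORDER"` / `"ORPHAN"`), and the software version. The
#' record round-trips losslessly through the JSON writer/reader.
#'
#' @slot config named list, the full parameter set.
#' @slot metadata named list: dimensions, pixel size, source, condition.
#' @slot cells,walls,junctions,puncta data.frames in output schema.
#' @slot version character, package version.
#' @export
setClass("AnalysisRecord",
  representation(
    config = "list",
    metadata = "list",
    cells = "data.frame",
    walls = "data.frame",
    junctions = "data.frame",
    puncta = "data.frame",
    version = "character"
  )
)

setMethod("show", "TissueImage", function(object) {
  cat(sprintf(
    "TissueImage: %d x %d px, %.4g um/px, source '%s', condition '%s'\n",
    nrow(object@wallChannel), ncol(object@wallChannel), object@pixelSize,
    object@sourceId, object@conditionLabel))
})

setMethod("show", "WallSkeleton", function(object) {
  cat(sprintf("WallSkeleton: %d skeleton pixels in a %d x %d frame\n",
              sum(object@mask), nrow(object@mask), ncol(object@mask)))
})

setMethod("show", "WallGraph", function(object) {
  cat(sprintf(
    "WallGraph: %d cells, %d walls, %d junctions, %d puncta (%d orphan)\n",
    nrow(object@cells), nrow(object@walls), nrow(object@junctions),
    nrow(object@puncta), sum(object@puncta$wall_id == 0)))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d cells, %d walls, %d junctions, %d puncta, %d x %d px\n",
    nrow(object@cells), nrow(object@walls), nrow(object@junctions),
    nrow(object@puncta), object@imageShape[1], object@imageShape[2]))
})

setMethod("show", "TimingSample", function(object) {
  cat(sprintf("TimingSample '%s': %d/%d plants broke bud\n",
              object@label, length(object@days), object@nTotal))
})

setMethod("show", "AnalysisRecord", function(object) {
  cat(sprintf(
    "AnalysisRecord v%s: %d cells, %d walls, %d junctions, %d puncta\n",
    object@version, nrow(object@cells), nrow(object@walls),
    nrow(object@junctions), nrow(object@puncta)))
})
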