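#' Assign wall segments to their adjacent cells
#'
#' For every pixel of a wall path the cell labels among its 8-neighbours are
#' accumulated; the two labels with majority support are the wall's adjacent
#' cells. Walls touching only one interior cell (the rest being background)
#' get the image-border sentinel (cell id 0). A third label with substantial
#' support (at least 3 pixels and a quarter of the path) indicates a
#' segmentation failure and raises an integrity error; trace contamination
#' from pixels diagonally across a junction is tolerated.
#'
#' @param paths list of ordered wall pixel matrices (from [splitWalls()]).
#' @param labels integer cell-label matrix (from [labelCells()]).
#' @return data.frame: wall_id, cell_id_1, cell_id_2 (0 = border), with
#'   cell_id_1 <= cell_id_2 unless one is the border sentinel.
#' @export
assignWallsToCells <- function(paths, labels) {
  if (!length(paths))
    return(data.frame(wall_id = integer(0), cell_id_1 = integer(0),
                      cell_id_2 = integer(0)))
  off <- expand.grid(dr = -1:1, dc = -1:1)
  off <- off[!(off$dr == 0 & off$dc == 0), ]
  rows <- lapply(seq_along(paths), function(k) {
    p <- paths[[k]]
    cnt <- integer(0)
    for (i in seq_len(nrow(off))) {
      rr <- p[, 1] + off$dr[i]
      cc <- p[, 2] + off$dc[i]
      ok <- rr >= 1 & rr <= nrow(labels) & cc >= 1 & cc <= ncol(labels)
      lv <- labels[cbind(rr[ok], cc[ok])]
      lv <- lv[lv > 0]
      if (length(lv)) {
        t <- table(lv)
        for (nm in names(t)) cnt[nm] <- sum(cnt[nm], t[[nm]], na.rm = TRUE)
      }
    }
    if (!length(cnt)) return(data.frame(wall_id = k, cell_id_1 = 0L,
                                        cell_id_2 = 0L))
    cnt <- sort(cnt, decreasing = TRUE)
    ids <- as.integer(names(cnt))
    if (length(cnt) >= 3 && cnt[3] >= 3 && cnt[3] >= 0.25 * nrow(p))
      stop(sprintf(
        "integrity error: wall %d adjacent to %d cell labels (%s)",
        k, length(cnt), paste(ids, collapse = ",")))
    c1 <- ids[1]
    c2 <- if (length(ids) >= 2 && cnt[2] >= 0.25 * cnt[1]) ids[2] else 0L
    data.frame(wall_id = k, cell_id_1 = min(c1, if (c2 > 0) c2 else c1),
               cell_id_2 = if (c2 > 0) max(c1, c2) else 0L)
  })
  do.call(rbind, rows)
}

#' Assign puncta to their parent walls
#'
#' Each punctum is assigned to the wall whose nearest path pixel minimizes
#' the Euclidean distance; a punctum farther than `tolerance_um` from every
#' wall becomes an orphan (wall id 0). Exact ties between walls go to the
#' lower wall id.
#'
#' @param puncta data.frame with sub-pixel `row`, `col` columns.
#' @param paths list of wall pixel matrices.
#' @param tolerance_um parent-search tolerance in micrometres (> 0).
#' @param pixel_size micrometres per pixel.
#' @return the puncta data.frame with `wall_id` (0 = orphan) and
#'   `distance_um` columns added.
#' @export
assignPunctaToWalls <- function(puncta, paths, tolerance_um = 0.5,
                                pixel_size = 1) {
  stopifnot(tolerance_um > 0)
  n <- nrow(puncta)
  if (n == 0) {
    puncta$wall_id <- integer(0)
    puncta$distance_um <- numeric(0)
    return(puncta)
  }
  if (!length(paths)) {
    warning("no walls: all puncta orphaned")
    puncta$wall_id <- 0L
    puncta$distance_um <- NA_real_
    return(puncta)
  }
  wallpix <- do.call(rbind, paths)
  wallid <- rep(seq_along(paths), vapply(paths, nrow, integer(1)))
  res <- cpp_nearest_wallpix(cbind(puncta$row, puncta$col),
                             wallpix * 1.0, as.integer(wallid))
  dist_um <- res$dist_px * pixel_size
  assigned <- dist_um <= tolerance_um
  puncta$wall_id <- ifelse(assigned, res$wall_id, 0L)
  puncta$distance_um <- dist_um
  puncta
}

#' Connect junctions to their walls
#'
#' Inverts the wall endpoint map: each junction lists every wall segment
#' that terminates at it. Interior junctions of a tri-junction tessellation
#' carry at least three walls; junctions left with fewer after spur pruning
#' are retained but flagged as degenerate.
#'
#' @param junctions data.frame from [findJunctions()].
#' @param walls data.frame with `junction_id_a`, `junction_id_b` columns.
#' @return the junctions data.frame with `wall_ids` list column and
#'   `degenerate` flag added.
#' @export
assignJunctionWalls <- function(junctions, walls) {
  wl <- lapply(junctions$junction_id, function(j) {
    sort(walls$wall_id[
      (!is.na(walls$junction_id_a) & walls$junction_id_a == j) |
      (!is.na(walls$junction_id_b) & walls$junction_id_b == j)])
  })
  junctions$wall_ids <- wl
  junctions$degenerate <- lengths(wl) < 3
  if (any(junctions$degenerate))
    warning(sprintf("junction(s) %s connect fewer than 3 walls",
                    paste(junctions$junction_id[junctions$degenerate],
                          collapse = ",")))
  junctions
}

#' Assemble and validate the relational wall graph
#'
#' Runs the three association steps (wall to cells, punctum to wall,
#' junction to walls), attaches the cell to wall inverse map, and validates
#' every graph invariant: interior walls separate two distinct cells,
#' assigned plus orphaned puncta account for all detections, and the
#' association maps are mutual inverses. Any violation raises an integrity
#' error naming the offending ids.
#'
#' @param cellInfo output of [labelCells()].
#' @param wallInfo output of [splitWalls()].
#' @param junctions output of [findJunctions()].
#' @param puncta measured puncta data.frame (may have zero rows).
#' @param skel the [WallSkeleton-class] the components came from.
#' @param pixel_size micrometres per pixel.
#' @param tolerance_um parent-search tolerance in micrometres.
#' @return a validated [WallGraph-class].
#' @export
buildWallGraph <- function(cellInfo, wallInfo, junctions, puncta, skel,
                           pixel_size, tolerance_um = 0.5) {
  walls <- wallInfo$walls
  paths <- wallInfo$paths
  adj <- assignWallsToCells(paths, cellInfo$labels)
  walls$cell_id_1 <- adj$cell_id_1[match(walls$wall_id, adj$wall_id)]
  walls$cell_id_2 <- adj$cell_id_2[match(walls$wall_id, adj$wall_id)]
  if (nrow(puncta)) {
    puncta <- assignPunctaToWalls(puncta, paths, tolerance_um, pixel_size)
  } else {
    puncta$wall_id <- integer(0)
    puncta$distance_um <- numeric(0)
  }
  junctions <- assignJunctionWalls(junctions, walls)
  cells <- cellInfo$cells
  cells$wall_ids <- lapply(cells$cell_id, function(cid)
    sort(walls$wall_id[walls$cell_id_1 == cid | walls$cell_id_2 == cid]))
  if (nrow(cells) && any(lengths(cells$wall_ids) == 0))
    stop(sprintf("integrity error: cell(s) %s have no bounding wall",
                 paste(cells$cell_id[lengths(cells$wall_ids) == 0],
                       collapse = ",")))
  g <- new("WallGraph", cells = cells, walls = walls, junctions = junctions,
           puncta = puncta, wallPaths = paths, cellLabels = cellInfo$labels,
           skeleton = skel@mask, pixelSize = pixel_size)
  validObject(g)
  # conservation: every punctum is either assigned or an orphan
  n_assigned <- sum(g@puncta$wall_id > 0)
  n_orphan <- sum(g@puncta$wall_id == 0)
  if (n_assigned + n_orphan != nrow(g@puncta))
    stop("integrity error: punctum conservation violated")
  g
}
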