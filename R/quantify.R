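#' Per-wall quantification table
#'
#' One row per wall segment: its length, the number of assigned puncta, the
#' punctum density per micrometre of wall, the total integrated punctum
#' intensity, and the mean callose-channel intensity over the wall path
#' dilated by one pixel. Zero-length walls (single-pixel chains) get density
#' 0 and are flagged.
#'
#' @param graph a validated [WallGraph-class].
#' @param punctaChannel raw callose/PD channel matrix.
#' @return data.frame: wall_id, junction_id_a, junction_id_b, cell_id_1,
#'   cell_id_2, length_um, mean_callose_intensity, n_pd, pd_total_intensity,
#'   pd_per_um, zero_length.
#' @export
perWallTable <- function(graph, punctaChannel) {
  w <- walls(graph)
  pc <- puncta(graph)
  rows <- lapply(seq_len(nrow(w)), function(i) {
    wid <- w$wall_id[i]
    path <- graph@wallPaths[[i]]
    mask <- matrix(FALSE, nrow(punctaChannel), ncol(punctaChannel))
    mask[path] <- TRUE
    mask <- dilate8(mask)
    mean_cal <- mean(punctaChannel[mask])
    mine <- pc[pc$wall_id == wid, , drop = FALSE]
    len <- w$length_um[i]
    data.frame(
      wall_id = wid, junction_id_a = w$junction_id_a[i],
      junction_id_b = w$junction_id_b[i], cell_id_1 = w$cell_id_1[i],
      cell_id_2 = w$cell_id_2[i], length_um = len,
      mean_callose_intensity = mean_cal, n_pd = nrow(mine),
      pd_total_intensity = sum(mine$integrated_intensity),
      pd_per_um = if (len > 0) nrow(mine) / len else 0,
      zero_length = len <= 0)
  })
  if (!length(rows))
    return(data.frame(wall_id = integer(0), junction_id_a = integer(0),
                      junction_id_b = integer(0), cell_id_1 = integer(0),
                      cell_id_2 = integer(0), length_um = numeric(0),
                      mean_callose_intensity = numeric(0), n_pd = integer(0),
                      pd_total_intensity = numeric(0), pd_per_um = numeric(0),
                      zero_length = logical(0)))
  do.call(rbind, rows)
}

#' Per-cell quantification table
#'
#' One row per cell. The periphery callose sum is the sum over the cell's
#' bounding walls of their mean callose intensity (the per-cell read-out
#' used for spatial callose maps); punctum counts and periphery length are
#' summed the same way. A wall shared by two cells contributes fully to both
#' rows: a plasmodesma is a channel of both neighbours.
#'
#' @param graph a validated [WallGraph-class].
#' @param wallRows output of [perWallTable()] on the same graph.
#' @return data.frame: cell_id, centroid_row, centroid_col, area_um2,
#'   n_walls, periphery_length_um, periphery_callose_sum, n_pd, pd_per_um.
#' @export
perCellTable <- function(graph, wallRows) {
  cl <- cells(graph)
  if (nrow(cl) && any(lengths(cl$wall_ids) == 0))
    stop("integrity error: cell without walls")
  rows <- lapply(seq_len(nrow(cl)), function(i) {
    wids <- cl$wall_ids[[i]]
    wr <- wallRows[match(wids, wallRows$wall_id), , drop = FALSE]
    plen <- sum(wr$length_um)
    npd <- sum(wr$n_pd)
    data.frame(
      cell_id = cl$cell_id[i], centroid_row = cl$centroid_row[i],
      centroid_col = cl$centroid_col[i], area_um2 = cl$area_um2[i],
      n_walls = length(wids), periphery_length_um = plen,
      periphery_callose_sum = sum(wr$mean_callose_intensity),
      n_pd = npd, pd_per_um = if (plen > 0) npd / plen else 0)
  })
  if (!length(rows))
    return(data.frame(cell_id = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), area_um2 = numeric(0),
                      n_walls = integer(0), periphery_length_um = numeric(0),
                      periphery_callose_sum = numeric(0), n_pd = integer(0),
                      pd_per_um = numeric(0)))
  do.call(rbind, rows)
}

#' Immunogold particle density
#'
#' Normalizes a manual gold-particle count from electron microscopy to
#' particles per square micrometre. The standard normalization window
#' delineated around a plasmodesma is 0.025 square micrometres.
#'
#' @param count non-negative integer particle count.
#' @param window_area window area in square micrometres (> 0).
#' @return list: `particle_count`, `window_area_um2`,
#'   `density_per_um2` (= count / area).
#' @export
goldDensity <- function(count, window_area = 0.025) {
  if (length(count) != 1 || !is.finite(count) || count < 0 ||
      count != round(count))
    stop("count must be a single non-negative integer")
  if (length(window_area) != 1 || !is.finite(window_area) || window_area <= 0)
    stop("window_area must be a single positive number")
  list(particle_count = as.integer(count),
       window_area_um2 = window_area,
       density_per_um2 = count / window_area)
}

#' Per-interface plasmodesmata count table
#'
#' Ingests manual TEM counts of plasmodesmata per cell-to-cell interface and
#' aggregates them per cell (sum over every interface touching the cell).
#' Interfaces are unordered pairs; duplicates (in either order) and unknown
#' cell ids are errors.
#'
#' @param counts data.frame: cell_id_1, cell_id_2, pd_count.
#' @param cell_ids vector of known cell ids.
#' @return list with `interfaces` (normalized so cell_id_1 < cell_id_2) and
#'   `per_cell` (data.frame: cell_id, pd_total).
#' @export
interfaceTable <- function(counts, cell_ids) {
  stopifnot(all(c("cell_id_1", "cell_id_2", "pd_count") %in% names(counts)))
  if (any(counts$pd_count < 0)) stop("pd_count must be non-negative")
  unknown <- setdiff(unique(c(counts$cell_id_1, counts$cell_id_2)), cell_ids)
  if (length(unknown))
    stop(sprintf("unknown cell id(s): %s", paste(unknown, collapse = ",")))
  a <- pmin(counts$cell_id_1, counts$cell_id_2)
  b <- pmax(counts$cell_id_1, counts$cell_id_2)
  key <- paste(a, b, sep = "~")
  if (anyDuplicated(key))
    stop(sprintf("duplicate interface: %s", key[duplicated(key)][1]))
  interfaces <- data.frame(cell_id_1 = a, cell_id_2 = b,
                           pd_count = counts$pd_count)
  per_cell <- data.frame(cell_id = sort(unique(c(a, b))))
  per_cell$pd_total <- vapply(per_cell$cell_id, function(cid)
    sum(interfaces$pd_count[interfaces$cell_id_1 == cid |
                            interfaces$cell_id_2 == cid]), numeric(1))
  list(interfaces = interfaces, per_cell = per_cell)
}
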