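# Visual outputs. All renderers are pure reads of the analysis results:
# they never modify the record or graph.

colormapColors <- function(name, n = 256) {
  hex <- switch(name,
    viridis = viridisLite::viridis(n),
    magma = viridisLite::magma(n),
    plasma = viridisLite::plasma(n),
    cividis = viridisLite::cividis(n),
    stop(sprintf("unknown colormap '%s'", name)))
  t(grDevices::col2rgb(hex)) / 255
}

# map values to colormap rows; returns list(idx, limits, degenerate)
scaleToColormap <- function(vals, limits = NULL, n = 256) {
  if (is.null(limits)) limits <- range(vals)
  degenerate <- diff(limits) <= 0
  idx <- if (degenerate) rep(ceiling(n / 2), length(vals)) else
    pmin(n, pmax(1, 1 + floor((vals - limits[1]) / diff(limits) * (n - 1))))
  list(idx = idx, limits = limits, degenerate = degenerate)
}

appendLegend <- function(img, cmap, width = 12) {
  h <- dim(img)[1]
  strip <- array(0, dim = c(h, width, 3))
  idx <- pmin(nrow(cmap), pmax(1, round(seq(nrow(cmap), 1, length.out = h))))
  for (ch in 1:3) strip[, , ch] <- matrix(cmap[idx, ch], h, width)
  out <- array(0, dim = c(h, dim(img)[2] + 2 + width, 3))
  out[, seq_len(dim(img)[2]), ] <- img
  out[, dim(img)[2] + 2 + seq_len(width), ] <- strip
  out
}

#' Per-cell metric heat map
#'
#' Fills every cell region with the colormap value of its metric (e.g. the
#' periphery callose sum, the per-cell read-out used to map callose levels
#' across a meristem surface), draws the walls as dark boundaries, and
#' appends a legend bar (scale maximum at the top). Fixed limits allow a
#' shared scale across conditions.
#'
#' @param graph a [WallGraph-class].
#' @param table per-cell table covering every cell in the graph.
#' @param metric column of `table` to map.
#' @param limits NULL for the data range, or `c(lo, hi)` for a fixed scale.
#' @param colormap one of "viridis", "magma", "plasma", "cividis".
#' @param path optional PNG output path.
#' @return RGB array (rows x cols x 3) with attributes `limits` and
#'   `degenerate` (TRUE when the scale collapsed to a point), invisibly.
#' @export
renderCellHeatmap <- function(graph, table, metric = "periphery_callose_sum",
                              limits = NULL, colormap = "viridis",
                              path = NULL) {
  if (!metric %in% names(table))
    stop(sprintf("unknown metric '%s'", metric))
  if (!all(cells(graph)$cell_id %in% table$cell_id))
    stop("table does not cover all graph cells")
  cmap <- colormapColors(colormap)
  vals <- table[[metric]][match(cells(graph)$cell_id, table$cell_id)]
  sc <- scaleToColormap(vals, limits)
  lab <- cellLabels(graph)
  img <- array(0.08, dim = c(nrow(lab), ncol(lab), 3))
  for (k in seq_along(vals)) {
    sel <- lab == cells(graph)$cell_id[k]
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[sel] <- cmap[sc$idx[k], ch]
      img[, , ch] <- pl
    }
  }
  sk <- skeletonMask(graph)
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[sk] <- 0.02
    img[, , ch] <- pl
  }
  img <- appendLegend(img, cmap)
  attr(img, "limits") <- sc$limits
  attr(img, "degenerate") <- sc$degenerate
  if (!is.null(path)) png::writePNG(img, path)
  invisible(img)
}

#' Per-interface plasmodesmata count map
#'
#' Draws every cell-to-cell interface (shared wall) in the colormap value of
#' its manual plasmodesmata count, emulating the color maps built from TEM
#' interface counts. Interfaces whose cell pair shares no wall in the graph
#' are an error; walls without a count are drawn gray.
#'
#' @param graph a [WallGraph-class].
#' @param counts data.frame: cell_id_1, cell_id_2, pd_count (validated via
#'   [interfaceTable()]).
#' @param limits,colormap,path as in [renderCellHeatmap()].
#' @return RGB array with `limits` attribute, invisibly.
#' @export
renderInterfaceMap <- function(graph, counts, limits = NULL,
                               colormap = "viridis", path = NULL) {
  it <- interfaceTable(counts, cells(graph)$cell_id)
  w <- walls(graph)
  wallKey <- paste(pmin(w$cell_id_1, w$cell_id_2),
                   pmax(w$cell_id_1, w$cell_id_2))
  ifKey <- paste(it$interfaces$cell_id_1, it$interfaces$cell_id_2)
  missing <- !(ifKey %in% wallKey)
  if (any(missing))
    stop(sprintf("interface(s) with no shared wall in the graph: %s",
                 paste(ifKey[missing], collapse = "; ")))
  sc <- scaleToColormap(it$interfaces$pd_count, limits)
  cmap <- colormapColors(colormap)
  lab <- cellLabels(graph)
  img <- array(0.08, dim = c(nrow(lab), ncol(lab), 3))
  for (i in seq_len(nrow(w))) {
    mask <- matrix(FALSE, nrow(lab), ncol(lab))
    mask[graph@wallPaths[[i]]] <- TRUE
    mask <- dilate8(mask)
    hit <- match(wallKey[i], ifKey)
    col <- if (is.na(hit)) c(0.5, 0.5, 0.5) else cmap[sc$idx[hit], ]
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[mask] <- col[ch]
      img[, , ch] <- pl
    }
  }
  img <- appendLegend(img, cmap)
  attr(img, "limits") <- sc$limits
  if (!is.null(path)) png::writePNG(img, path)
  invisible(img)
}

#' Composite detection overlay
#'
#' Grayscale wall channel with the skeleton trace (green), junction markers
#' (yellow) and punctum markers (assigned red, orphan magenta) burned in,
#' for visual inspection of the detections. Output dimensions equal the
#' input image.
#'
#' @param image the analyzed [TissueImage-class].
#' @param graph the [WallGraph-class] computed from it.
#' @param path optional PNG output path.
#' @return RGB array (rows x cols x 3), invisibly.
#' @export
renderOverlay <- function(image, graph, path = NULL) {
  wc <- wallChannel(image)
  rng <- range(wc)
  g <- if (diff(rng) > 0) (wc - rng[1]) / diff(rng) else wc * 0
  img <- array(rep(g * 0.7, 3), dim = c(nrow(g), ncol(g), 3))
  paint <- function(img, mask, col) {
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[mask] <- col[ch]
      img[, , ch] <- pl
    }
    img
  }
  img <- paint(img, skeletonMask(graph), c(0, 0.8, 0))
  jn <- junctions(graph)
  if (nrow(jn)) {
    mask <- matrix(FALSE, nrow(g), ncol(g))
    for (px in jn$pixels) mask[px] <- TRUE
    img <- paint(img, dilate8(mask), c(1, 1, 0))
  }
  pc <- puncta(graph)
  for (i in seq_len(nrow(pc))) {
    r0 <- min(max(round(pc$row[i]), 1), nrow(g))
    c0 <- min(max(round(pc$col[i]), 1), ncol(g))
    mask <- matrix(FALSE, nrow(g), ncol(g))
    rr <- c(r0 - 1, r0, r0, r0, r0 + 1)
    cc <- c(c0, c0 - 1, c0, c0 + 1, c0)
    ok <- rr >= 1 & rr <= nrow(g) & cc >= 1 & cc <= ncol(g)
    mask[cbind(rr[ok], cc[ok])] <- TRUE
    col <- if (pc$wall_id[i] > 0) c(1, 0, 0) else c(1, 0, 1)
    img <- paint(img, mask, col)
  }
  if (!is.null(path)) png::writePNG(img, path)
  invisible(img)
}
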