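#' Binarize the wall channel
#'
#' Smooths the wall-stain channel with a Gaussian and thresholds it into a
#' binary wall mask. The threshold is computed from the smoothed image by
#' Otsu's method unless a fixed value is supplied. Images with inverted
#' contrast (dark walls on bright background) can be flipped first.
#'
#' @param channel numeric matrix, wall-stain intensities.
#' @param smoothing_sigma Gaussian sigma in pixels (>= 0; 0 disables).
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param threshold_value numeric threshold, required when
#'   `threshold_method = "fixed"`.
#' @param invert flip contrast before thresholding.
#' @return logical matrix; `TRUE` where walls are foreground.
#' @export
preprocessWalls <- function(channel, smoothing_sigma = 1,
                            threshold_method = c("otsu", "fixed"),
                            threshold_value = NULL, invert = FALSE) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(smoothing_sigma >= 0)
  if (diff(range(channel)) == 0)
    stop("no wall signal: channel has zero dynamic range")
  if (invert) channel <- max(channel) - channel
  sm <- gaussianBlur(channel, smoothing_sigma)
  th <- if (threshold_method == "fixed") {
    if (is.null(threshold_value)) stop("fixed threshold requires threshold_value")
    threshold_value
  } else {
    otsuThreshold(sm)
  }
  sm >= th
}

#' Skeletonize a wall mask
#'
#' Topology-preserving thinning of the binary wall mask to a one-pixel-wide
#' 8-connected skeleton, followed by removal of short spurs (dead-end
#' branches produced by thinning artifacts).
#'
#' @param mask logical wall mask.
#' @param prune_length_px spurs of at most this many pixels hanging off a
#'   branch point are removed (default 3; 0 disables).
#' @return a [WallSkeleton-class].
#' @export
skeletonizeWalls <- function(mask, prune_length_px = 3) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- mask > 0
  if (!any(mask)) stop("empty wall mask")
  skel <- cpp_thin(mask)
  if (prune_length_px > 0) skel <- pruneSpurs(skel, prune_length_px)
  new("WallSkeleton", mask = skel, degree = neighborCount8(skel))
}

# Remove dead-end chains of <= prune_px pixels that terminate at a branch
# pixel; genuine long dead ends are kept. One pass (no iterative erosion).
pruneSpurs <- function(skel, prune_px) {
  deg <- neighborCount8(skel)
  ends <- which(skel & deg == 1, arr.ind = TRUE)
  if (!nrow(ends)) return(skel)
  drop <- matrix(integer(0), 0, 2)
  for (i in seq_len(nrow(ends))) {
    chain <- matrix(ends[i, ], 1, 2)
    cur <- ends[i, ]
    prev <- c(NA_integer_, NA_integer_)
    reached_branch <- FALSE
    while (nrow(chain) <= prune_px) {
      nb <- neighborsOf(cur, dim(skel))
      nb <- nb[skel[nb], , drop = FALSE]
      if (nrow(chain) > 1)
        nb <- nb[!(nb[, 1] == prev[1] & nb[, 2] == prev[2]), , drop = FALSE]
      if (nrow(nb) == 0) break
      degs <- deg[nb]
      if (any(degs >= 3)) { reached_branch <- TRUE; break }
      if (nrow(nb) > 1) break  # not a simple chain; leave it alone
      prev <- cur
      cur <- nb[1, ]
      chain <- rbind(chain, cur)
    }
    if (reached_branch && nrow(chain) <= prune_px)
      drop <- rbind(drop, chain)
  }
  if (nrow(drop)) skel[drop] <- FALSE
  skel
}

# 8-neighbour coordinates of a pixel, clipped to the frame
neighborsOf <- function(px, dims) {
  g <- expand.grid(dr = -1:1, dc = -1:1)
  g <- g[!(g$dr == 0 & g$dc == 0), ]
  nb <- cbind(px[1] + g$dr, px[2] + g$dc)
  nb[nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 & nb[, 2] <= dims[2], ,
     drop = FALSE]
}

#' Find wall junction points
#'
#' Branch pixels of the skeleton (8-connected degree >= 3) are clustered by
#' 8-connectivity; each cluster is one junction, positioned at its pixel
#' centroid. Tri-junctions (three converging walls) are the generic case in
#' plant tissue; degree-4 crossings are admitted as single junctions.
#'
#' Thinning can split one biological junction into two branch-pixel clusters
#' a few pixels apart (typically at shallow wall angles); clusters joined by
#' a residual skeleton chain of at most `merge_chain_px` pixels whose
#' centroids lie within `merge_dist_px` are therefore merged, the chain
#' being absorbed into the junction. Genuine short walls connect clusters
#' farther apart than `merge_dist_px` and are never absorbed; below that
#' scale a separate wall is unresolvable anyway.
#'
#' @param skel a [WallSkeleton-class].
#' @param merge_chain_px absorb connecting chains of at most this many
#'   pixels between two branch clusters (default 5; 0 disables).
#' @param merge_dist_px merge clusters only when their centroids are within
#'   this distance in pixels (default 7).
#' @return data.frame with `junction_id`, `row`, `col` (1-based, possibly
#'   fractional centroids) and a `pixels` list column of cluster member
#'   coordinates. Ordered by centroid (row, col).
#' @export
findJunctions <- function(skel, merge_chain_px = 5, merge_dist_px = 7) {
  stopifnot(is(skel, "WallSkeleton"))
  branch <- skel@mask & skel@degree >= 3
  empty <- data.frame(junction_id = integer(0), row = numeric(0),
                      col = numeric(0))
  empty$pixels <- list()
  if (!any(branch)) return(empty)
  lab <- cpp_label_components(branch, 8L)
  ids <- sort(unique(lab[lab > 0]))
  groups <- lapply(ids, function(i) {
    px <- which(lab == i, arr.ind = TRUE)
    px[order(px[, 1], px[, 2]), , drop = FALSE]
  })
  if (merge_chain_px > 0 && length(groups) > 1) {
    chains <- cpp_label_components(skel@mask & !branch, 8L)
    parent <- seq_along(groups)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    touches <- function(px, chpx)
      any(outer(px[, 1], chpx[, 1], function(a, b) abs(a - b)) <= 1 &
          outer(px[, 2], chpx[, 2], function(a, b) abs(a - b)) <= 1)
    absorb <- list()
    for (ch in sort(unique(chains[chains > 0]))) {
      chpx <- which(chains == ch, arr.ind = TRUE)
      if (nrow(chpx) > merge_chain_px) next
      hit <- which(vapply(groups, touches, logical(1), chpx = chpx))
      if (length(hit) >= 2) {
        cents <- vapply(groups[hit], colMeans, numeric(2))
        maxd <- max(stats::dist(t(cents)))
        if (maxd > merge_dist_px) next
        roots <- unique(vapply(hit, find, integer(1)))
        for (r in roots[-1]) parent[r] <- roots[1]
        absorb[[length(absorb) + 1]] <- list(root = roots[1], px = chpx)
      }
    }
    roots <- vapply(seq_along(groups), find, integer(1))
    merged <- lapply(sort(unique(roots)), function(r) {
      px <- do.call(rbind, groups[roots == r])
      for (a in absorb) if (find(a$root) == find(r)) px <- rbind(px, a$px)
      px[order(px[, 1], px[, 2]), , drop = FALSE]
    })
    groups <- merged
  }
  cent <- t(vapply(groups, function(px)
    c(mean(px[, 1]), mean(px[, 2])), numeric(2)))
  ord <- order(cent[, 1], cent[, 2])
  out <- data.frame(junction_id = seq_along(groups),
                    row = cent[ord, 1], col = cent[ord, 2])
  out$pixels <- groups[ord]
  out
}

#' Cut the skeleton into wall segments
#'
#' Removing the junction clusters disconnects the skeleton; every remaining
#' 8-connected chain is one wall segment, re-attached to the junction(s) its
#' endpoints touch. A junction-free loop (e.g. an isolated cell outline)
#' becomes a single closed-loop segment with no endpoint junctions.
#'
#' @param skel a [WallSkeleton-class].
#' @param junctions output of [findJunctions()] on the same skeleton.
#' @param pixel_size micrometres per pixel, used for segment lengths.
#' @return list with `walls` (data.frame: wall_id, junction_id_a,
#'   junction_id_b, length_um, n_px, closed) and `paths` (list of ordered
#'   n x 2 pixel matrices).
#' @export
splitWalls <- function(skel, junctions, pixel_size = 1) {
  stopifnot(is(skel, "WallSkeleton"))
  m <- skel@mask
  jmask <- matrix(FALSE, nrow(m), ncol(m))
  for (px in junctions$pixels) jmask[px] <- TRUE
  residual <- m & !jmask
  emptyWalls <- data.frame(wall_id = integer(0), junction_id_a = integer(0),
                           junction_id_b = integer(0), length_um = numeric(0),
                           n_px = integer(0), closed = logical(0))
  if (!any(residual)) return(list(walls = emptyWalls, paths = list()))
  lab <- cpp_label_components(residual, 8L)
  ids <- sort(unique(lab[lab > 0]))
  paths <- lapply(ids, function(i)
    orderChain(which(lab == i, arr.ind = TRUE)))
  # deterministic wall order: by smallest (row, col) pixel of the path
  keypix <- t(vapply(paths, function(p) {
    p[order(p[, 1], p[, 2])[1], ]
  }, numeric(2)))
  ord <- order(keypix[, 1], keypix[, 2])
  paths <- paths[ord]
  jn_of <- function(px) {
    hits <- integer(0)
    for (j in seq_len(nrow(junctions))) {
      jp <- junctions$pixels[[j]]
      if (any(abs(jp[, 1] - px[1]) <= 1 & abs(jp[, 2] - px[2]) <= 1))
        hits <- c(hits, junctions$junction_id[j])
    }
    hits
  }
  rows <- lapply(seq_along(paths), function(k) {
    p <- attr(paths[[k]], "pixels")
    closed <- attr(paths[[k]], "closed")
    ja <- jb <- NA_integer_
    if (!closed) {
      a <- jn_of(p[1, ])
      b <- jn_of(p[nrow(p), ])
      if (nrow(p) == 1) {
        both <- sort(unique(c(a, b)))
        ja <- if (length(both) >= 1) both[1] else NA_integer_
        jb <- if (length(both) >= 2) both[2] else NA_integer_
      } else {
        ja <- if (length(a)) min(a) else NA_integer_
        jb <- if (length(b)) min(b) else NA_integer_
      }
    }
    data.frame(wall_id = k, junction_id_a = ja, junction_id_b = jb,
               length_um = measureLength(p, pixel_size), n_px = nrow(p),
               closed = closed)
  })
  walls <- do.call(rbind, rows)
  paths <- lapply(paths, function(p) {
    q <- attr(p, "pixels"); q
  })
  list(walls = walls, paths = paths)
}

# Order the pixels of one 8-connected chain into a path. Returns the pixel
# matrix with attributes `pixels` (ordered matrix) and `closed`.
orderChain <- function(px) {
  px <- px[order(px[, 1], px[, 2]), , drop = FALSE]
  n <- nrow(px)
  out <- px
  if (n > 2) {
    key <- px[, 1] * 1e6 + px[, 2]
    adj <- function(i) {
      hits <- which(abs(px[, 1] - px[i, 1]) <= 1 &
                    abs(px[, 2] - px[i, 2]) <= 1)
      hits[hits != i]
    }
    degs <- vapply(seq_len(n), function(i) length(adj(i)), integer(1))
    start <- if (any(degs == 1)) which(degs == 1)[1] else 1L
    visited <- logical(n)
    order_idx <- integer(n)
    cur <- start
    for (k in seq_len(n)) {
      order_idx[k] <- cur
      visited[cur] <- TRUE
      nb <- adj(cur)
      nb <- nb[!visited[nb]]
      if (!length(nb)) break
      # prefer orthogonal steps so staircase corners are traversed in order
      d <- abs(px[nb, 1] - px[cur, 1]) + abs(px[nb, 2] - px[cur, 2])
      cur <- nb[order(d, nb)][1]
    }
    if (any(order_idx == 0)) {
      # non-simple residue; fall back to raster order (should not occur on
      # cleaned skeletons, but never drop pixels silently)
      order_idx <- seq_len(n)
    }
    out <- px[order_idx, , drop = FALSE]
    closed <- !any(degs == 1)
  } else {
    closed <- FALSE
  }
  res <- out
  attr(res, "pixels") <- out
  attr(res, "closed") <- if (n <= 2) FALSE else closed
  res
}

#' Chain length of a wall path
#'
#' Sum of step lengths along an ordered pixel chain: `pixel_size` for
#' orthogonal steps and `sqrt(2) * pixel_size` for diagonal steps. A
#' single-pixel path has length 0 and carries a `zero_length` attribute.
#'
#' @param path ordered n x 2 pixel matrix.
#' @param pixel_size micrometres per pixel.
#' @return length in micrometres.
#' @export
measureLength <- function(path, pixel_size) {
  if (is.null(dim(path))) path <- matrix(path, ncol = 2)
  n <- nrow(path)
  if (n < 2) {
    len <- 0
    attr(len, "zero_length") <- TRUE
    return(len)
  }
  steps <- abs(diff(path))
  sum(ifelse(steps[, 1] & steps[, 2], sqrt(2), 1)) * pixel_size
}

#' Label cells as wall-enclosed regions
#'
#' Cells are the 4-connected components of the skeleton complement,
#' excluding every component that touches the image border (the background
#' and any clipped cells). 4-connectivity prevents regions from leaking
#' diagonally through a one-pixel wall.
#'
#' @param skel a [WallSkeleton-class].
#' @param pixel_size micrometres per pixel, for areas in square micrometres.
#' @return list with `labels` (integer matrix; 0 = walls/background) and
#'   `cells` (data.frame: cell_id, centroid_row, centroid_col, area_px,
#'   area_um2), ids ordered by first raster pixel.
#' @export
labelCells <- function(skel, pixel_size = 1) {
  stopifnot(is(skel, "WallSkeleton"))
  comp <- cpp_label_components(!skel@mask, 4L)
  border <- unique(c(comp[1, ], comp[nrow(comp), ], comp[, 1],
                     comp[, ncol(comp)]))
  border <- border[border > 0]
  keep <- setdiff(sort(unique(comp[comp > 0])), border)
  labels <- matrix(0L, nrow(comp), ncol(comp))
  rows <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    sel <- comp == keep[k]
    labels[sel] <- k
    px <- which(sel, arr.ind = TRUE)
    rows[[k]] <- data.frame(
      cell_id = k, centroid_row = mean(px[, 1]), centroid_col = mean(px[, 2]),
      area_px = nrow(px), area_um2 = nrow(px) * pixel_size^2)
  }
  cells <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = integer(0), centroid_row = numeric(0),
               centroid_col = numeric(0), area_px = integer(0),
               area_um2 = numeric(0))
  list(labels = labels, cells = cells)
}
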