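#' Generate a ground-truth tissue tessellation
#'
#' Builds a Voronoi tessellation of a jittered rectangular lattice of cell
#' seeds, clipped to the image frame, and derives the exact relational
#' ground truth: cells, wall polylines (Voronoi edges plus the frame
#' border), and junction points (vertices where at least three walls
#' converge). Zero jitter gives the exact square lattice, whose degree-4
#' crossings are the degenerate stress case; any positive jitter yields
#' generic tri-junctions.
#'
#' The generator enforces a resolution floor: interior Voronoi edges
#' shorter than 8 pixels (where jitter splits a lattice crossing into two
#' tri-junctions closer than any pixel pipeline can separate) are
#' contracted into single degree-4 junctions, and draws with
#' sub-resolution border edges, junction pairs, or wall angles below 40
#' degrees are redrawn deterministically from the seeded stream. If the
#' parameters cannot produce a resolvable tessellation the function errors.
#'
#' @param nx,ny number of cells across and down (>= 1).
#' @param jitter seed displacement as a fraction of the cell pitch, in
#'   `[0, 0.5)`.
#' @param cell_pitch_um lattice pitch in micrometres.
#' @param pixel_size micrometres per pixel of the rendered frame.
#' @param seed integer RNG seed; identical seeds give identical output.
#' @param margin_px background margin around the tessellation, pixels.
#' @param wall_width_px,psf_sigma_px,noise_sd,background render parameters
#'   stored with the ground truth: drawn wall thickness, Gaussian PSF sigma,
#'   additive Gaussian noise sd, constant background level.
#' @param wall_amplitude,punctum_amplitude rendered intensities (a.u.).
#' @return a [GroundTruth-class] with no puncta (see [placePuncta()]).
#' @export
makeTessellation <- function(nx, ny, jitter = 0.2, cell_pitch_um = 5,
                             pixel_size = 0.2, seed = 1, margin_px = 5,
                             wall_width_px = 3, psf_sigma_px = 1,
                             noise_sd = 0, background = 5,
                             wall_amplitude = 100, punctum_amplitude = 100) {
  stopifnot(nx >= 1, ny >= 1, jitter >= 0, jitter < 0.5, cell_pitch_um > 0,
            pixel_size > 0)
  pitch_px <- cell_pitch_um / pixel_size
  # resolution floor: walls/junction separations below 8 px are contracted
  # (below ~2 wall widths + junction cluster extent nothing is recoverable)
  min_sep_um <- 8 * pixel_size
  if (pitch_px < 6)
    stop("unresolvable tessellation: cell pitch below 6 pixels")
  W <- nx * cell_pitch_um
  H <- ny * cell_pitch_um
  set.seed(as.integer(seed))
  geom <- NULL
  for (attempt in seq_len(if (jitter == 0) 1L else 200L)) {
    sx <- rep((seq_len(nx) - 0.5) * cell_pitch_um, times = ny)
    sy <- rep((seq_len(ny) - 0.5) * cell_pitch_um, each = nx)
    if (jitter > 0) {
      sx <- sx + stats::runif(nx * ny, -jitter, jitter) * cell_pitch_um
      sy <- sy + stats::runif(nx * ny, -jitter, jitter) * cell_pitch_um
    }
    segs <- if (jitter == 0) latticeSegments(nx, ny, cell_pitch_um) else
      contractShortEdges(voronoiSegments(sx, sy, W, H), min_sep_um, W, H)
    g <- tryCatch(assembleGeomGraph(segs), error = function(e) NULL)
    if (!is.null(g) && geomResolvable(g, min_sep_um)) {
      geom <- list(g = g, sx = sx, sy = sy)
      break
    }
  }
  if (is.null(geom))
    stop("unresolvable tessellation: no draw with resolvable wall separations for these parameters")
  margin_um <- margin_px * pixel_size
  g <- geom$g
  g$junctions$x <- g$junctions$x + margin_um
  g$junctions$y <- g$junctions$y + margin_um
  g$polylines <- lapply(g$polylines, function(p) {
    p[, 1] <- p[, 1] + margin_um
    p[, 2] <- p[, 2] + margin_um
    p
  })
  shape <- c(ceiling(H / pixel_size) + 2L * margin_px,
             ceiling(W / pixel_size) + 2L * margin_px)
  cellsDf <- data.frame(cell_id = seq_len(nx * ny),
                        seed_x = geom$sx + margin_um,
                        seed_y = geom$sy + margin_um)
  pnc <- data.frame(punctum_id = integer(0), x = numeric(0), y = numeric(0),
                    wall_id = integer(0), amplitude = numeric(0))
  new("GroundTruth",
      cells = cellsDf, walls = g$walls, wallPolylines = g$polylines,
      junctions = g$junctions, puncta = pnc, pixelSize = pixel_size,
      imageShape = as.integer(shape),
      renderParams = list(wall_width_px = wall_width_px,
                          psf_sigma_px = psf_sigma_px, noise_sd = noise_sd,
                          background = background,
                          wall_amplitude = wall_amplitude,
                          punctum_amplitude = punctum_amplitude),
      seed = as.integer(seed))
}

# Exact square-lattice wall segments (unit edges with their flanking cells).
latticeSegments <- function(nx, ny, pitch) {
  cid <- function(ix, iy) (iy - 1L) * nx + ix
  rows <- list()
  k <- 0
  for (i in 0:nx) {       # vertical edges at x = i * pitch
    for (j in 0:(ny - 1)) {
      left <- if (i >= 1) cid(i, j + 1L) else 0L
      right <- if (i < nx) cid(i + 1L, j + 1L) else 0L
      k <- k + 1
      rows[[k]] <- c(i * pitch, j * pitch, i * pitch, (j + 1) * pitch,
                     left, right)
    }
  }
  for (j in 0:ny) {       # horizontal edges at y = j * pitch
    for (i in 0:(nx - 1)) {
      up <- if (j >= 1) cid(i + 1L, j) else 0L
      down <- if (j < ny) cid(i + 1L, j + 1L) else 0L
      k <- k + 1
      rows[[k]] <- c(i * pitch, j * pitch, (i + 1) * pitch, j * pitch,
                     up, down)
    }
  }
  m <- do.call(rbind, rows)
  data.frame(x1 = m[, 1], y1 = m[, 2], x2 = m[, 3], y2 = m[, 4],
             c1 = as.integer(m[, 5]), c2 = as.integer(m[, 6]))
}

# Voronoi wall segments from deldir, plus the frame-border segments split at
# the points where tessellation edges meet the frame.
voronoiSegments <- function(sx, sy, W, H) {
  dd <- deldir::deldir(sx, sy, rw = c(0, W, 0, H), suppressMsge = TRUE)
  ds <- dd$dirsgs
  len <- sqrt((ds$x2 - ds$x1)^2 + (ds$y2 - ds$y1)^2)
  ds <- ds[len > 1e-9, , drop = FALSE]
  interior <- data.frame(x1 = ds$x1, y1 = ds$y1, x2 = ds$x2, y2 = ds$y2,
                         c1 = as.integer(ds$ind1), c2 = as.integer(ds$ind2))
  eps <- 1e-7
  pts <- rbind(cbind(ds$x1, ds$y1), cbind(ds$x2, ds$y2))
  borderRows <- list()
  sides <- list(
    list(fixed = "y", at = 0, lo = 0, hi = W),   # top
    list(fixed = "y", at = H, lo = 0, hi = W),   # bottom
    list(fixed = "x", at = 0, lo = 0, hi = H),   # left
    list(fixed = "x", at = W, lo = 0, hi = H))   # right
  for (s in sides) {
    if (s$fixed == "y") {
      on <- abs(pts[, 2] - s$at) < eps
      coords <- sort(unique(c(s$lo, s$hi, pts[on, 1])))
      for (i in seq_len(length(coords) - 1)) {
        mx <- (coords[i] + coords[i + 1]) / 2
        cell <- which.min((sx - mx)^2 + (sy - s$at)^2)
        borderRows[[length(borderRows) + 1]] <-
          data.frame(x1 = coords[i], y1 = s$at, x2 = coords[i + 1], y2 = s$at,
                     c1 = as.integer(cell), c2 = 0L)
      }
    } else {
      on <- abs(pts[, 1] - s$at) < eps
      coords <- sort(unique(c(s$lo, s$hi, pts[on, 2])))
      for (i in seq_len(length(coords) - 1)) {
        my <- (coords[i] + coords[i + 1]) / 2
        cell <- which.min((sx - s$at)^2 + (sy - my)^2)
        borderRows[[length(borderRows) + 1]] <-
          data.frame(x1 = s$at, y1 = coords[i], x2 = s$at, y2 = coords[i + 1],
                     c1 = as.integer(cell), c2 = 0L)
      }
    }
  }
  rbind(interior, do.call(rbind, borderRows))
}

# Contract tessellation edges shorter than the resolution limit by merging
# their endpoints into one vertex: small jitter splits every lattice
# crossing into two tri-junctions joined by an arbitrarily short Voronoi
# edge, which no pixel-level pipeline can resolve. Contraction turns such
# near-degenerate vertex pairs into single (degree-4) junctions, keeping the
# stated ground truth consistent with what the render can represent.
# Vertices on the frame boundary stay on it; frame corners never move.
contractShortEdges <- function(segs, min_len, W, H) {
  eps <- 1e-7
  isCorner <- function(x, y)
    (abs(x) < eps | abs(x - W) < eps) & (abs(y) < eps | abs(y - H) < eps)
  onBoundary <- function(x, y)
    abs(x) < eps | abs(x - W) < eps | abs(y) < eps | abs(y - H) < eps
  repeat {
    len <- sqrt((segs$x2 - segs$x1)^2 + (segs$y2 - segs$y1)^2)
    short <- which(len < min_len)
    # never contract along the frame: merging two border junctions bends
    # the incoming walls into near-tangential approaches the renderer
    # cannot resolve; such draws are rejected upstream instead
    short <- short[!(onBoundary(segs$x1[short], segs$y1[short]) &
                     onBoundary(segs$x2[short], segs$y2[short]))]
    if (!length(short)) break
    e <- short[which.min(len[short])]
    u <- c(segs$x1[e], segs$y1[e])
    v <- c(segs$x2[e], segs$y2[e])
    tgt <- if (isCorner(u[1], u[2])) u
      else if (isCorner(v[1], v[2])) v
      else if (onBoundary(u[1], u[2]) && !onBoundary(v[1], v[2])) u
      else if (onBoundary(v[1], v[2]) && !onBoundary(u[1], u[2])) v
      else if (onBoundary(u[1], u[2])) u
      else (u + v) / 2
    moveTo <- function(xs, ys) {
      hitU <- abs(xs - u[1]) < eps & abs(ys - u[2]) < eps
      hitV <- abs(xs - v[1]) < eps & abs(ys - v[2]) < eps
      xs[hitU | hitV] <- tgt[1]
      ys[hitU | hitV] <- tgt[2]
      list(x = xs, y = ys)
    }
    p1 <- moveTo(segs$x1, segs$y1)
    p2 <- moveTo(segs$x2, segs$y2)
    segs$x1 <- p1$x; segs$y1 <- p1$y
    segs$x2 <- p2$x; segs$y2 <- p2$y
    keep <- sqrt((segs$x2 - segs$x1)^2 + (segs$y2 - segs$y1)^2) > eps
    segs <- segs[keep, , drop = FALSE]
  }
  segs
}

# Merge raw segments into wall polylines: nodes of degree != 2 (junctions,
# dead ends) terminate walls; chains through degree-2 nodes (frame corners,
# collinear splits) are concatenated; leftover pure cycles become
# closed-loop walls.
assembleGeomGraph <- function(segs) {
  key <- function(x, y) paste(round(x, 7), round(y, 7))
  k1 <- key(segs$x1, segs$y1)
  k2 <- key(segs$x2, segs$y2)
  nodes <- unique(c(k1, k2))
  n1 <- match(k1, nodes)
  n2 <- match(k2, nodes)
  nn <- length(nodes)
  xy <- do.call(rbind, strsplit(nodes, " "))
  nodeXY <- cbind(as.numeric(xy[, 1]), as.numeric(xy[, 2]))
  deg <- tabulate(c(n1, n2), nn)
  ne <- nrow(segs)
  inc <- vector("list", nn)
  for (e in seq_len(ne)) {
    inc[[n1[e]]] <- c(inc[[n1[e]]], e)
    inc[[n2[e]]] <- c(inc[[n2[e]]], e)
  }
  used <- logical(ne)
  pairKey <- paste(pmin(segs$c1, segs$c2), pmax(segs$c1, segs$c2))
  wallsList <- list()
  walk <- function(e, from) {
    # follow edge e starting at node `from` through degree-2 nodes
    chainNodes <- from
    cur <- e
    at <- from
    repeat {
      used[cur] <<- TRUE
      nxt <- if (n1[cur] == at) n2[cur] else n1[cur]
      chainNodes <- c(chainNodes, nxt)
      if (deg[nxt] != 2 || nxt == from) break
      cand <- inc[[nxt]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      if (pairKey[cand[1]] != pairKey[e])
        stop("tessellation assembly: inconsistent cell pair across degree-2 node")
      cur <- cand[1]
      at <- nxt
    }
    chainNodes
  }
  # walls starting at terminal (degree != 2) nodes
  term <- which(deg != 2)
  for (v in term) {
    for (e in inc[[v]]) {
      if (used[e]) next
      chain <- walk(e, v)
      wallsList[[length(wallsList) + 1]] <-
        list(nodes = chain, c1 = segs$c1[e], c2 = segs$c2[e])
    }
  }
  # remaining edges form pure cycles (e.g. a 1x1 tessellation's border)
  for (e in seq_len(ne)) {
    if (used[e]) next
    chain <- walk(e, n1[e])
    wallsList[[length(wallsList) + 1]] <-
      list(nodes = chain, c1 = segs$c1[e], c2 = segs$c2[e], closed = TRUE)
  }
  jnodes <- which(deg >= 3)
  jid <- integer(nn)
  ord <- jnodes[order(nodeXY[jnodes, 2], nodeXY[jnodes, 1])]  # by (y, x)
  jid[ord] <- seq_along(ord)
  junctions <- data.frame(junction_id = seq_along(ord),
                          x = nodeXY[ord, 1], y = nodeXY[ord, 2])
  polylines <- lapply(wallsList, function(wl)
    cbind(x = nodeXY[wl$nodes, 1], y = nodeXY[wl$nodes, 2]))
  lens <- vapply(polylines, function(p)
    sum(sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)), numeric(1))
  startKey <- vapply(polylines, function(p) {
    i <- order(p[, 2], p[, 1])[1]
    p[i, 2] * 1e9 + p[i, 1]
  }, numeric(1))
  ord_w <- order(startKey)
  wallsList <- wallsList[ord_w]
  polylines <- polylines[ord_w]
  lens <- lens[ord_w]
  walls <- do.call(rbind, lapply(seq_along(wallsList), function(i) {
    wl <- wallsList[[i]]
    closed <- isTRUE(wl$closed)
    ja <- if (closed) NA_integer_ else jid[wl$nodes[1]]
    jb <- if (closed) NA_integer_ else jid[wl$nodes[length(wl$nodes)]]
    ja <- if (!is.na(ja) && ja == 0) NA_integer_ else ja
    jb <- if (!is.na(jb) && jb == 0) NA_integer_ else jb
    pos <- c(wl$c1, wl$c2)
    pos <- sort(pos[pos > 0])
    data.frame(wall_id = i, junction_id_a = ja, junction_id_b = jb,
               cell_id_1 = if (length(pos) >= 1) pos[1] else 0L,
               cell_id_2 = if (length(pos) >= 2) pos[2] else 0L,
               length_um = lens[i])
  }))
  list(walls = walls, polylines = polylines, junctions = junctions)
}

# resolvability check: wall lengths and pairwise junction distances at
# least min_sep, and every pair of walls meeting at a junction separated by
# at least min_angle degrees (default 40: nearly parallel walls merge when drawn at
# finite width, displacing or splitting the junction in any pixel pipeline)
geomResolvable <- function(g, min_sep, min_angle = 40) {
  if (nrow(g$walls) && any(g$walls$length_um < min_sep)) return(FALSE)
  j <- g$junctions
  if (nrow(j) >= 2) {
    d <- stats::dist(cbind(j$x, j$y))
    if (min(d) < min_sep) return(FALSE)
  }
  if (nrow(j)) {
    w <- g$walls
    for (k in seq_len(nrow(j))) {
      dirs <- list()
      # approach direction measured over the first micrometre of wall, not
      # the first polyline segment (contraction can leave short bent stubs)
      probe <- 1
      for (i in seq_len(nrow(w))) {
        p <- g$polylines[[i]]
        len <- w$length_um[i]
        if (!is.na(w$junction_id_a[i]) && w$junction_id_a[i] == j$junction_id[k])
          dirs[[length(dirs) + 1]] <-
            interpolatePolyline(p, min(probe, len))[1, ] - p[1, ]
        if (!is.na(w$junction_id_b[i]) && w$junction_id_b[i] == j$junction_id[k])
          dirs[[length(dirs) + 1]] <-
            interpolatePolyline(p, max(len - probe, 0))[1, ] - p[nrow(p), ]
      }
      if (length(dirs) < 2) next
      ang <- vapply(dirs, function(v) atan2(v[2], v[1]), numeric(1))
      for (a in seq_along(ang)) for (b in seq_along(ang)) {
        if (a >= b) next
        dd <- abs(ang[a] - ang[b]) %% (2 * pi)
        dd <- min(dd, 2 * pi - dd)
        if (dd < min_angle * pi / 180) return(FALSE)
      }
    }
  }
  TRUE
}

#' Place puncta along ground-truth walls
#'
#' Positions puncta along each wall polyline by a homogeneous Poisson
#' process of the given rate per micrometre of wall, optionally thinned so
#' consecutive puncta on a wall are at least `min_gap_um` apart. The true
#' parent wall of every punctum is recorded; by construction each punctum
#' lies exactly on its parent polyline.
#'
#' @param gt a [GroundTruth-class].
#' @param rate expected puncta per micrometre of wall (>= 0).
#' @param min_gap_um minimum along-wall gap between consecutive puncta
#'   (0 disables thinning, keeping the process exactly Poisson).
#' @param seed integer RNG seed.
#' @return the [GroundTruth-class] with its `puncta` slot filled.
#' @export
placePuncta <- function(gt, rate, min_gap_um = 0, seed = 1) {
  stopifnot(is(gt, "GroundTruth"), rate >= 0, min_gap_um >= 0)
  set.seed(as.integer(seed))
  amp <- gt@renderParams$punctum_amplitude
  rows <- list()
  for (i in seq_len(nrow(gt@walls))) {
    len <- gt@walls$length_um[i]
    n <- stats::rpois(1, rate * len)
    if (n == 0) next
    s <- sort(stats::runif(n, 0, len))
    xy <- interpolatePolyline(gt@wallPolylines[[i]], s)
    rows[[length(rows) + 1]] <- data.frame(
      x = xy[, 1], y = xy[, 2], wall_id = gt@walls$wall_id[i],
      amplitude = amp)
  }
  pnc <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x = numeric(0), y = numeric(0), wall_id = integer(0),
               amplitude = numeric(0))
  if (min_gap_um > 0 && nrow(pnc) > 1) {
    # greedy Euclidean thinning across all walls (spots on different walls
    # can collide near junctions), deterministic in generation order
    keep <- logical(nrow(pnc))
    for (k in seq_len(nrow(pnc))) {
      if (!any(keep)) { keep[k] <- TRUE; next }
      d2 <- (pnc$x[keep] - pnc$x[k])^2 + (pnc$y[keep] - pnc$y[k])^2
      keep[k] <- all(d2 >= min_gap_um^2)
    }
    pnc <- pnc[keep, , drop = FALSE]
  }
  pnc <- pnc[order(pnc$y, pnc$x), , drop = FALSE]
  pnc <- cbind(punctum_id = seq_len(nrow(pnc)), pnc)
  rownames(pnc) <- NULL
  gt@puncta <- pnc
  validObject(gt)
  gt
}

# point(s) at arclength s along a polyline
interpolatePolyline <- function(p, s) {
  seglen <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  s <- pmin(pmax(s, 0), total)
  out <- matrix(0, length(s), 2)
  for (i in seq_along(s)) {
    k <- findInterval(s[i], cum, rightmost.closed = TRUE)
    k <- min(k, length(seglen))
    f <- if (seglen[k] > 0) (s[i] - cum[k]) / seglen[k] else 0
    out[i, ] <- p[k, ] + f * (p[k + 1, ] - p[k, ])
  }
  out
}

#' Render a ground truth into a two-channel image
#'
#' The wall channel draws every wall polyline at the stored wall width,
#' blurs it with the Gaussian PSF, and adds the constant background and
#' additive Gaussian noise. The puncta channel places a Gaussian spot of the
#' stored amplitude at every punctum position over the same background and
#' noise. Both channels are clipped at zero.
#'
#' @param gt a [GroundTruth-class] (with or without puncta).
#' @param seed optional RNG seed for the noise draw; irrelevant when
#'   `noise_sd` is 0.
#' @return a [TissueImage-class].
#' @export
renderTissue <- function(gt, seed = NULL) {
  stopifnot(is(gt, "GroundTruth"))
  rp <- gt@renderParams
  ps <- gt@pixelSize
  nr <- gt@imageShape[1]
  nc <- gt@imageShape[2]
  mask <- matrix(FALSE, nr, nc)
  for (p in gt@wallPolylines) {
    for (k in seq_len(nrow(p) - 1)) {
      seg <- p[k:(k + 1), , drop = FALSE]
      L <- sqrt(sum((seg[2, ] - seg[1, ])^2))
      nstep <- max(2L, ceiling(L / (0.25 * ps)))
      t <- seq(0, 1, length.out = nstep)
      xs <- seg[1, 1] + t * (seg[2, 1] - seg[1, 1])
      ys <- seg[1, 2] + t * (seg[2, 2] - seg[1, 2])
      rr <- pmin(pmax(round(ys / ps + 0.5), 1), nr)
      cc <- pmin(pmax(round(xs / ps + 0.5), 1), nc)
      mask[cbind(rr, cc)] <- TRUE
    }
  }
  wrad <- max(0L, as.integer(floor((rp$wall_width_px - 1) / 2)))
  if (wrad > 0) mask <- cpp_dilate_mask(mask, wrad)
  wall <- mask * rp$wall_amplitude
  if (rp$psf_sigma_px > 0) wall <- gaussianBlur(wall, rp$psf_sigma_px)
  spots <- matrix(0, nr, nc)
  if (nrow(gt@puncta)) {
    sg <- rp$psf_sigma_px
    for (i in seq_len(nrow(gt@puncta))) {
      r0 <- gt@puncta$y[i] / ps + 0.5
      c0 <- gt@puncta$x[i] / ps + 0.5
      a <- gt@puncta$amplitude[i]
      if (sg <= 0) {
        rr <- pmin(pmax(round(r0), 1), nr)
        cc <- pmin(pmax(round(c0), 1), nc)
        spots[rr, cc] <- spots[rr, cc] + a
      } else {
        half <- ceiling(4 * sg)
        rs <- max(1, floor(r0) - half):min(nr, ceiling(r0) + half)
        cs <- max(1, floor(c0) - half):min(nc, ceiling(c0) + half)
        d2 <- outer((rs - r0)^2, (cs - c0)^2, "+")
        spots[rs, cs] <- spots[rs, cs] + a * exp(-d2 / (2 * sg^2))
      }
    }
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  addNoise <- function(img) {
    img <- img + rp$background
    if (rp$noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, rp$noise_sd)
    pmax(img, 0)
  }
  TissueImage(wallChannel = addNoise(wall), punctaChannel = addNoise(spots),
              pixelSize = ps,
              sourceId = sprintf("synthetic-seed%d", gt@seed),
              conditionLabel = "synthetic")
}
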