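# Shared fixtures, built in code and memoized per test run.

.fixture_cache <- new.env(parent = emptyenv())

# ground truth + zero-noise render of an nx x ny tessellation
latticeFixture <- function(nx = 2, ny = 2, jitter = 0, seed = 1, rate = 0,
                           min_gap_um = 0.8, noise_sd = 0, ...) {
  key <- paste(nx, ny, jitter, seed, rate, min_gap_um, noise_sd, ...)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  gt <- makeTessellation(nx, ny, jitter = jitter, cell_pitch_um = 5,
                         pixel_size = 0.2, seed = seed, noise_sd = noise_sd,
                         ...)
  if (rate > 0)
    gt <- placePuncta(gt, rate = rate, min_gap_um = min_gap_um,
                      seed = seed + 1000)
  img <- renderTissue(gt, seed = seed + 2000)
  fx <- list(gt = gt, img = img)
  .fixture_cache[[key]] <- fx
  fx
}

# full segmentation of a fixture image
segmentFixture <- function(fx) {
  skel <- skeletonizeWalls(preprocessWalls(wallChannel(fx$img)))
  jn <- findJunctions(skel)
  wl <- splitWalls(skel, jn, pixel_size = pixelSize(fx$img))
  cl <- labelCells(skel, pixel_size = pixelSize(fx$img))
  list(skel = skel, jn = jn, wl = wl, cl = cl)
}

# ground-truth puncta as a detections table (pixel coordinates), for
# exercising the quantification chain independently of the detector
gtDetections <- function(gt) {
  pnc <- puncta(gt)
  ps <- pixelSize(gt)
  data.frame(punctum_id = seq_len(nrow(pnc)),
             row = pnc$y / ps + 0.5, col = pnc$x / ps + 0.5,
             det_intensity = pnc$amplitude,
             peak_intensity = pnc$amplitude,
             integrated_intensity = pnc$amplitude,
             clipped = FALSE)
}

# micrometre ground-truth coordinates to 1-based pixel coordinates
gtPx <- function(gt, um_xy) {
  cbind(um_xy[, 2] / pixelSize(gt) + 0.5, um_xy[, 1] / pixelSize(gt) + 0.5)
}

# independent flood-fill component counter (4-connectivity), pure R
floodComponents4 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    nr <- nrow(mask)
    while (length(queue)) {
      i <- queue[[1]]
      queue <- queue[-1]
      r <- (i - 1L) %% nr + 1L
      c <- (i - 1L) %/% nr + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        r2 <- r + d[1]
        c2 <- c + d[2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > ncol(mask)) next
        j <- (c2 - 1L) * nr + r2
        if (mask[j] && lab[j] == 0L) {
          lab[j] <- comp
          queue <- c(queue, j)
        }
      }
    }
  }
  list(n = comp, labels = lab)
}

# a single Gaussian spot image
gaussianSpotImage <- function(nr = 41, nc = 41, r0 = 21, c0 = 21,
                              amplitude = 100, sigma = 1.5, background = 0) {
  d2 <- outer((seq_len(nr) - r0)^2, (seq_len(nc) - c0)^2, "+")
  amplitude * exp(-d2 / (2 * sigma^2)) + background
}

# manual WallGraph with one horizontal wall and n assigned puncta
toyWallGraph <- function(n_puncta = 4, wall_px = 11, pixel_size = 0.2) {
  nr <- 9L
  nc <- as.integer(wall_px + 4)
  path <- cbind(rep(5L, wall_px), seq_len(wall_px) + 2L)
  skel <- matrix(FALSE, nr, nc)
  skel[path] <- TRUE
  labels <- matrix(0L, nr, nc)
  cells <- data.frame(cell_id = 1L, centroid_row = 3, centroid_col = 8,
                      area_px = 10L, area_um2 = 10 * pixel_size^2)
  cells$wall_ids <- list(1L)
  walls <- data.frame(wall_id = 1L, junction_id_a = NA_integer_,
                      junction_id_b = NA_integer_, length_um =
                        (wall_px - 1) * pixel_size, n_px = wall_px,
                      closed = FALSE, cell_id_1 = 1L, cell_id_2 = 0L)
  junctions <- data.frame(junction_id = integer(0), row = numeric(0),
                          col = numeric(0))
  junctions$pixels <- list()
  junctions$wall_ids <- list()
  junctions$degenerate <- logical(0)
  puncta <- if (n_puncta > 0) {
    pr <- seq_len(n_puncta)
    data.frame(punctum_id = pr, row = 5, col = 3 + pr,
               det_intensity = 10, peak_intensity = 10,
               integrated_intensity = 50, clipped = FALSE,
               wall_id = 1L, distance_um = 0)
  } else {
    data.frame(punctum_id = integer(0), row = numeric(0), col = numeric(0),
               det_intensity = numeric(0), peak_intensity = numeric(0),
               integrated_intensity = numeric(0), clipped = logical(0),
               wall_id = integer(0), distance_um = numeric(0))
  }
  new("WallGraph", cells = cells, walls = walls, junctions = junctions,
      puncta = puncta,
      wallPaths = list(path), cellLabels = labels, skeleton = skel,
      pixelSize = pixel_size)
}
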