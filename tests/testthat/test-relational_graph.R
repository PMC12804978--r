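test_that("walls map to their flanking cells, with the border sentinel", {
  fx <- latticeFixture(2, 1, jitter = 0, seed = 1)
  seg <- segmentFixture(fx)
  adj <- assignWallsToCells(seg$wl$paths, seg$cl$labels)
  interior <- adj[adj$cell_id_2 != 0, ]
  border <- adj[adj$cell_id_2 == 0, ]
  expect_equal(nrow(interior), 1)  # the single shared wall
  expect_setequal(unlist(interior[, c("cell_id_1", "cell_id_2")]), c(1, 2))
  expect_true(all(border$cell_id_1 %in% c(1, 2)))
})

test_that("the 2x2 lattice has 4 interior and 4 border walls", {
  fx <- latticeFixture(2, 2, jitter = 0, seed = 1)
  seg <- segmentFixture(fx)
  adj <- assignWallsToCells(seg$wl$paths, seg$cl$labels)
  expect_equal(sum(adj$cell_id_2 != 0), 4)
  expect_equal(sum(adj$cell_id_2 == 0), 4)
  # every interior wall separates two distinct cells
  expect_true(all(adj$cell_id_1[adj$cell_id_2 != 0] !=
                  adj$cell_id_2[adj$cell_id_2 != 0]))
})

test_that("junction-wall maps invert the wall endpoint map", {
  fx <- latticeFixture(2, 2, jitter = 0, seed = 1)
  seg <- segmentFixture(fx)
  jn <- assignJunctionWalls(seg$jn, seg$wl$walls)
  expect_equal(sort(lengths(jn$wall_ids)), c(3, 3, 3, 3, 4))
  # exact inverse both ways
  for (k in seq_len(nrow(jn))) {
    for (w in jn$wall_ids[[k]]) {
      row <- seg$wl$walls[seg$wl$walls$wall_id == w, ]
      expect_true(jn$junction_id[k] %in%
                    c(row$junction_id_a, row$junction_id_b))
    }
  }
  for (i in seq_len(nrow(seg$wl$walls))) {
    for (j in stats::na.omit(c(seg$wl$walls$junction_id_a[i],
                               seg$wl$walls$junction_id_b[i]))) {
      expect_true(seg$wl$walls$wall_id[i] %in%
                    jn$wall_ids[[which(jn$junction_id == j)]])
    }
  }
})

test_that("puncta are assigned by distance with a tolerance cutoff", {
  fx <- latticeFixture(2, 2, jitter = 0, seed = 1)
  seg <- segmentFixture(fx)
  onwall <- seg$wl$paths[[1]][3, ]
  p <- data.frame(punctum_id = 1:2,
                  row = c(onwall[1], 18), col = c(onwall[2], 18),
                  det_intensity = 10)
  # punctum 2 sits at a cell center, ~2.4 um from the nearest wall
  out <- assignPunctaToWalls(p, seg$wl$paths, tolerance_um = 0.5,
                             pixel_size = 0.2)
  expect_equal(out$wall_id[1], 1L)
  expect_equal(out$distance_um[1], 0)
  expect_equal(out$wall_id[2], 0L)
  out2 <- assignPunctaToWalls(p, seg$wl$paths, tolerance_um = 5,
                              pixel_size = 0.2)
  expect_gt(out2$wall_id[2], 0)
})

test_that("assignment matches an exhaustive nearest-wall search", {
  fx <- latticeFixture(4, 4, jitter = 0.3, seed = 7)
  seg <- segmentFixture(fx)
  set.seed(99)
  n <- 100
  p <- data.frame(punctum_id = seq_len(n),
                  row = runif(n, 2, nrow(wallChannel(fx$img)) - 1),
                  col = runif(n, 2, ncol(wallChannel(fx$img)) - 1),
                  det_intensity = 1)
  got <- assignPunctaToWalls(p, seg$wl$paths, tolerance_um = 1,
                             pixel_size = 0.2)
  # O(N * M) brute force in plain R, ties to the lower wall id
  for (i in seq_len(n)) {
    best_d <- Inf
    best_w <- 0L
    for (w in seq_along(seg$wl$paths)) {
      px <- seg$wl$paths[[w]]
      d <- min(sqrt((px[, 1] - p$row[i])^2 + (px[, 2] - p$col[i])^2))
      if (d < best_d - 1e-12) {
        best_d <- d
        best_w <- w
      }
    }
    d_um <- best_d * 0.2
    expect_equal(got$distance_um[i], d_um, tolerance = 1e-12)
    expect_equal(got$wall_id[i], if (d_um <= 1) best_w else 0L)
  }
})

test_that("conservation: assigned plus orphans account for every punctum", {
  fx <- latticeFixture(3, 3, jitter = 0.2, seed = 4, rate = 0.6)
  res <- analyzeSingle(fx$img, analysisConfig())
  pc <- puncta(res$graph)
  expect_equal(sum(pc$wall_id > 0) + sum(pc$wall_id == 0), nrow(pc))
  expect_equal(sum(res$wallTable$n_pd) + sum(pc$wall_id == 0), nrow(pc))
})

test_that("the assembled graph validates and matches ground truth", {
  fx <- latticeFixture(2, 2, jitter = 0, seed = 1, rate = 0.4)
  res <- analyzeSingle(fx$img, analysisConfig())
  g <- res$graph
  expect_s4_class(g, "WallGraph")
  expect_equal(nrow(cells(g)), 4)
  expect_equal(nrow(walls(g)), 8)
  expect_equal(nrow(junctions(g)), 5)
  expect_equal(nrow(puncta(g)), nrow(puncta(fx$gt)))
  expect_equal(sum(puncta(g)$wall_id == 0), 0)
  # punctum -> wall parentage agrees with ground truth via the cell pairs of
  # the parent wall, outside a 2 px junction exclusion zone
  labels <- cellLabels(g)
  seedpx <- round(gtPx(fx$gt, as.matrix(cells(fx$gt)[, c("seed_x", "seed_y")])))
  gt2rec <- labels[seedpx]
  jnpx <- gtPx(fx$gt, as.matrix(junctions(fx$gt)[, c("x", "y")]))
  truth <- gtPx(fx$gt, as.matrix(puncta(fx$gt)[, c("x", "y")]))
  pc <- puncta(g)
  w <- walls(g)
  gw <- walls(fx$gt)
  for (i in seq_len(nrow(pc))) {
    D <- sqrt((truth[, 1] - pc$row[i])^2 + (truth[, 2] - pc$col[i])^2)
    k <- which.min(D)
    expect_lt(D[k], 2)
    dj <- min(sqrt((jnpx[, 1] - pc$row[i])^2 + (jnpx[, 2] - pc$col[i])^2))
    if (dj < 2) next  # junction exclusion zone
    truewall <- gw[gw$wall_id == puncta(fx$gt)$wall_id[k], ]
    truepair <- sort(c(
      if (truewall$cell_id_1 > 0) gt2rec[truewall$cell_id_1] else 0L,
      if (truewall$cell_id_2 > 0) gt2rec[truewall$cell_id_2] else 0L))
    recwall <- w[w$wall_id == pc$wall_id[i], ]
    recpair <- sort(c(recwall$cell_id_1, recwall$cell_id_2))
    expect_equal(recpair, truepair)
  }
})

test_that("a punctum placed in a cell interior is orphaned", {
  fx <- latticeFixture(2, 2, jitter = 0, seed = 1)
  seg <- segmentFixture(fx)
  p <- data.frame(punctum_id = 1L, row = 18, col = 18, det_intensity = 5,
                  peak_intensity = 5, integrated_intensity = 5,
                  clipped = FALSE)
  g <- buildWallGraph(seg$cl, seg$wl, seg$jn, p, seg$skel, 0.2,
                      tolerance_um = 0.5)
  expect_equal(puncta(g)$wall_id, 0L)
})

test_that("missing walls orphan every punctum with a warning", {
  p <- data.frame(punctum_id = 1L, row = 3, col = 3, det_intensity = 1)
  expect_warning(out <- assignPunctaToWalls(p, list(), tolerance_um = 0.5),
                 "orphaned")
  expect_equal(out$wall_id, 0L)
})
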