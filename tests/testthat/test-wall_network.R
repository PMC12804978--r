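test_that("thinning reduces a thick bar to a single simple chain", {
  m <- matrix(FALSE, 20, 40)
  m[8:12, 5:35] <- TRUE
  skel <- skeletonizeWalls(m)
  expect_true(any(skeletonMask(skel)))
  expect_true(all(degreeMap(skel)[skeletonMask(skel)] <= 2))
  comp <- floodComponents4(pdquant:::dilate8(skeletonMask(skel)))
  expect_equal(comp$n, 1)
})

test_that("thinning preserves the topology of a thick ring", {
  m <- matrix(FALSE, 41, 41)
  d <- sqrt(outer((1:41 - 21)^2, (1:41 - 21)^2, "+"))
  m[d >= 10 & d <= 14] <- TRUE
  skel <- skeletonizeWalls(m)
  expect_true(all(degreeMap(skel)[skeletonMask(skel)] == 2))
  expect_equal(nrow(findJunctions(skel)), 0)
  wl <- splitWalls(skel, findJunctions(skel), pixel_size = 0.1)
  expect_equal(nrow(wl$walls), 1)
  expect_true(wl$walls$closed)
  expect_true(is.na(wl$walls$junction_id_a))
  cl <- labelCells(skel, pixel_size = 0.1)
  expect_equal(nrow(cl$cells), 1)
})

test_that("a plus-sign skeleton yields one junction and four walls", {
  m <- matrix(FALSE, 21, 21)
  m[11, 3:19] <- TRUE
  m[3:19, 11] <- TRUE
  skel <- new("WallSkeleton", mask = m, degree = pdquant:::neighborCount8(m))
  jn <- findJunctions(skel)
  expect_equal(nrow(jn), 1)
  expect_equal(c(jn$row, jn$col), c(11, 11))
  wl <- splitWalls(skel, jn, pixel_size = 1)
  expect_equal(nrow(wl$walls), 4)
  expect_true(all(wl$walls$junction_id_a == 1 | wl$walls$junction_id_b == 1))
})

test_that("open shapes enclose no cells", {
  m <- matrix(FALSE, 30, 30)
  m[5:25, 5] <- TRUE
  m[25, 5:25] <- TRUE
  m[5:25, 25] <- TRUE  # "U"
  skel <- skeletonizeWalls(m)
  expect_equal(nrow(labelCells(skel)$cells), 0)
})

test_that("2x2 lattice render recovers 4 cells, 8 walls, 5 junctions", {
  fx <- latticeFixture(2, 2, jitter = 0, seed = 1)
  seg <- segmentFixture(fx)
  # independent flood-fill oracle on the skeleton complement
  comp <- floodComponents4(!skeletonMask(seg$skel))
  expect_equal(comp$n, 5)  # 4 cells + border background
  expect_equal(nrow(seg$cl$cells), 4)
  expect_equal(nrow(seg$wl$walls), 8)
  expect_equal(nrow(seg$jn), 5)
  # Euler relation V - E + F = 2 with the outer face
  expect_equal(nrow(seg$jn) - nrow(seg$wl$walls) + nrow(seg$cl$cells) + 1, 2)
})

test_that("wall mask covers the true wall center-lines on noise-free renders", {
  fx <- latticeFixture(3, 3, jitter = 0.2, seed = 5)
  mask <- preprocessWalls(wallChannel(fx$img))
  ps <- pixelSize(fx$gt)
  for (p in fx$gt@wallPolylines) {
    for (k in seq_len(nrow(p) - 1)) {
      t <- seq(0, 1, length.out = 20)
      xs <- p[k, 1] + t * (p[k + 1, 1] - p[k, 1])
      ys <- p[k, 2] + t * (p[k + 1, 2] - p[k, 2])
      rr <- pmin(pmax(round(ys / ps + 0.5), 1), nrow(mask))
      cc <- pmin(pmax(round(xs / ps + 0.5), 1), ncol(mask))
      expect_true(all(mask[cbind(rr, cc)]))
    }
  }
})

test_that("preprocessing rejects degenerate input and honors inversion", {
  expect_error(preprocessWalls(matrix(0, 10, 10)), "no wall signal")
  expect_error(preprocessWalls(matrix(7, 10, 10)), "no wall signal")
  fx <- latticeFixture(2, 2, jitter = 0, seed = 1)
  wc <- wallChannel(fx$img)
  straight <- preprocessWalls(wc)
  flipped <- preprocessWalls(max(wc) - wc, invert = TRUE)
  expect_identical(straight, flipped)
})

test_that("fixed thresholding overrides the automatic one", {
  fx <- latticeFixture(2, 2, jitter = 0, seed = 1)
  wc <- wallChannel(fx$img)
  m <- preprocessWalls(wc, smoothing_sigma = 0, threshold_method = "fixed",
                       threshold_value = 50)
  expect_identical(m, wc >= 50)
  expect_error(preprocessWalls(wc, threshold_method = "fixed"),
               "threshold_value")
})

test_that("chain lengths follow the orthogonal/diagonal step rule", {
  horiz <- cbind(rep(3, 11), 1:11)
  expect_equal(measureLength(horiz, 0.1), 1.0)
  diag <- cbind(1:11, 1:11)
  expect_equal(measureLength(diag, 0.1), 10 * sqrt(2) * 0.1)
  # L-shape: 5 across + 5 down sharing the corner pixel = 8 unit steps
  ell <- rbind(cbind(rep(1, 5), 1:5), cbind(2:5, rep(5, 4)))
  expect_equal(measureLength(ell, 0.1), 0.8)
  single <- measureLength(cbind(4, 4), 0.1)
  expect_equal(as.numeric(single), 0)
  expect_true(attr(single, "zero_length"))
})

test_that("Euler relation holds across tessellation sizes and jitters", {
  for (cfg in list(c(3, 0), c(3, 0.2), c(5, 0.4))) {
    fx <- latticeFixture(cfg[1], cfg[1], jitter = cfg[2], seed = 2)
    seg <- segmentFixture(fx)
    expect_equal(nrow(seg$jn) - nrow(seg$wl$walls) + nrow(seg$cl$cells) + 1, 2,
                 info = sprintf("n=%d jitter=%.1f", cfg[1], cfg[2]))
    expect_equal(nrow(seg$cl$cells), nrow(cells(fx$gt)))
  }
})

test_that("skeleton pixel count tracks the true center-line length", {
  fx <- latticeFixture(4, 4, jitter = 0.2, seed = 3)
  seg <- segmentFixture(fx)
  true_px <- sum(walls(fx$gt)$length_um) / pixelSize(fx$gt)
  got_px <- sum(skeletonMask(seg$skel))
  expect_lt(abs(got_px - true_px) / true_px, 0.1)
})
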