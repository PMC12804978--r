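test_that("square-lattice ground truth has the exact planar graph", {
  gt <- makeTessellation(2, 2, jitter = 0, cell_pitch_um = 5,
                         pixel_size = 0.2, seed = 1)
  expect_equal(nrow(cells(gt)), 4)
  expect_equal(nrow(walls(gt)), 8)
  expect_equal(nrow(junctions(gt)), 5)
  expect_equal(nrow(junctions(gt)) - nrow(walls(gt)) + nrow(cells(gt)) + 1, 2)
  # interior walls are pitch long, merged border walls twice that
  expect_setequal(round(walls(gt)$length_um, 6), c(5, 10))
  # center junction degree 4, border junctions degree 3
  deg <- table(c(walls(gt)$junction_id_a, walls(gt)$junction_id_b))
  expect_setequal(as.integer(deg), c(3, 3, 3, 3, 4))
})

test_that("a single cell is one closed-loop wall with no junctions", {
  gt <- makeTessellation(1, 1, jitter = 0, seed = 1)
  expect_equal(nrow(cells(gt)), 1)
  expect_equal(nrow(walls(gt)), 1)
  expect_equal(nrow(junctions(gt)), 0)
  expect_true(is.na(walls(gt)$junction_id_a))
  expect_equal(walls(gt)$length_um, 4 * 5)
})

test_that("identical seeds reproduce ground truth and renders bit for bit", {
  a <- makeTessellation(3, 3, jitter = 0.3, seed = 42)
  b <- makeTessellation(3, 3, jitter = 0.3, seed = 42)
  expect_identical(cells(a), cells(b))
  expect_identical(walls(a), walls(b))
  expect_identical(junctions(a), junctions(b))
  a <- placePuncta(a, rate = 0.5, seed = 7)
  b <- placePuncta(b, rate = 0.5, seed = 7)
  expect_identical(puncta(a), puncta(b))
  ia <- renderTissue(a, seed = 5)
  ib <- renderTissue(b, seed = 5)
  expect_identical(wallChannel(ia), wallChannel(ib))
  expect_identical(punctaChannel(ia), punctaChannel(ib))
  c <- makeTessellation(3, 3, jitter = 0.3, seed = 43)
  expect_false(identical(cells(a)$seed_x, cells(c)$seed_x))
})

test_that("puncta follow a Poisson process on the wall length", {
  gt <- makeTessellation(6, 6, jitter = 0.2, seed = 3)
  L <- sum(walls(gt)$length_um)
  lambda <- 0.5
  counts <- vapply(1:6, function(s)
    nrow(puncta(placePuncta(gt, rate = lambda, seed = s))), numeric(1))
  expect_lt(abs(mean(counts) - lambda * L), 3 * sqrt(lambda * L / 6))
  expect_equal(nrow(puncta(placePuncta(gt, rate = 0, seed = 1))), 0)
})

test_that("every punctum lies exactly on its parent polyline", {
  gt <- placePuncta(makeTessellation(4, 4, jitter = 0.3, seed = 9),
                    rate = 0.6, seed = 2)
  pnc <- puncta(gt)
  segdist <- function(p, a, b) {
    ab <- b - a
    t <- sum((p - a) * ab) / max(sum(ab^2), 1e-12)
    t <- min(max(t, 0), 1)
    sqrt(sum((a + t * ab - p)^2))
  }
  for (i in seq_len(nrow(pnc))) {
    poly <- gt@wallPolylines[[pnc$wall_id[i]]]
    d <- min(vapply(seq_len(nrow(poly) - 1), function(k)
      segdist(c(pnc$x[i], pnc$y[i]), poly[k, ], poly[k + 1, ]), numeric(1)))
    expect_lt(d, 1e-9)
  }
})

test_that("min-gap thinning enforces the stated spacing", {
  gt <- placePuncta(makeTessellation(4, 4, jitter = 0.2, seed = 5),
                    rate = 2, min_gap_um = 0.8, seed = 6)
  pnc <- puncta(gt)
  d <- as.matrix(stats::dist(cbind(pnc$x, pnc$y)))
  diag(d) <- Inf
  expect_gte(min(d), 0.8)
})

test_that("renders degrade gracefully and honor the stated amplitudes", {
  gt <- makeTessellation(2, 2, jitter = 0, seed = 1, psf_sigma_px = 0,
                         noise_sd = 0, background = 0)
  img <- renderTissue(gt)
  ps <- pixelSize(gt)
  # with no PSF and no noise the wall channel is exactly the drawn mask
  expect_setequal(unique(as.numeric(wallChannel(img))), c(0, 100))
  jn <- junctions(gt)
  px <- round(cbind(jn$y / ps + 0.5, jn$x / ps + 0.5))
  expect_true(all(wallChannel(img)[px] == 100))

  gt2 <- placePuncta(makeTessellation(2, 2, jitter = 0, seed = 1),
                     rate = 0.3, min_gap_um = 1, seed = 4)
  img2 <- renderTissue(gt2)
  pnc <- puncta(gt2)
  for (i in seq_len(nrow(pnc))) {
    r0 <- round(pnc$y[i] / ps + 0.5)
    c0 <- round(pnc$x[i] / ps + 0.5)
    # background 5, amplitude 100, sub-pixel offset allows a modest drop
    expect_gt(punctaChannel(img2)[r0, c0], 5 + 100 * exp(-0.5))
  }
})

test_that("recovery metrics do not improve as noise increases", {
  recallAt <- function(noise_sd) {
    gt <- makeTessellation(4, 4, jitter = 0.2, seed = 8, noise_sd = noise_sd)
    gt <- placePuncta(gt, rate = 0.5, min_gap_um = 0.8, seed = 9)
    img <- renderTissue(gt, seed = 10)
    det <- preprocessPuncta(punctaChannel(img), 1, 10)
    pk <- detectLocalMaxima(det, "auto", 2)
    truth <- gtPx(gt, as.matrix(puncta(gt)[, c("x", "y")]))
    if (!nrow(pk)) return(0)
    D <- sqrt(outer(pk$row, truth[, 1], "-")^2 +
              outer(pk$col, truth[, 2], "-")^2)
    mean(apply(D, 2, min) <= 2)
  }
  ladder <- vapply(c(0, 10, 40), recallAt, numeric(1))
  expect_true(all(diff(ladder) <= 1e-9))
  expect_equal(ladder[1], 1)
})

test_that("impossible tessellation parameters raise the stated error", {
  expect_error(makeTessellation(2, 2, jitter = 0, cell_pitch_um = 0.5,
                                pixel_size = 0.2),
               "unresolvable tessellation")
})

test_that("the ground-truth JSON side-car mirrors the geometry", {
  gt <- placePuncta(makeTessellation(2, 2, jitter = 0, seed = 1),
                    rate = 0.4, seed = 2)
  f <- tempfile(fileext = ".json")
  writeGroundTruthJson(gt, f)
  obj <- jsonlite::fromJSON(f)
  expect_length(obj$cells$cell_id, 4)
  expect_length(obj$walls$wall_id, 8)
  expect_equal(obj$pixel_size_um, 0.2)
  expect_equal(obj$seed, 1)
  expect_length(obj$puncta$punctum_id, nrow(puncta(gt)))
  expect_equal(obj$puncta$wall_id, puncta(gt)$wall_id)
})
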