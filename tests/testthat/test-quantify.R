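test_that("per-wall density is puncta per micrometre of wall", {
  g <- toyWallGraph(n_puncta = 4, wall_px = 11, pixel_size = 0.2)
  ch <- matrix(1, 9, 15)
  tab <- perWallTable(g, ch)
  expect_equal(tab$length_um, 2.0)
  expect_equal(tab$n_pd, 4L)
  expect_equal(tab$pd_per_um, 2.0)
  expect_equal(tab$pd_total_intensity, 4 * 50)
  expect_equal(tab$mean_callose_intensity, 1)
  # empty wall
  g0 <- toyWallGraph(n_puncta = 0)
  tab0 <- perWallTable(g0, ch)
  expect_equal(tab0$n_pd, 0L)
  expect_equal(tab0$pd_per_um, 0)
  expect_equal(tab0$pd_total_intensity, 0)
})

test_that("per-cell periphery sums its walls' means exactly", {
  fx <- latticeFixture(2, 2, jitter = 0, seed = 1, rate = 0.4)
  res <- analyzeSingle(fx$img, analysisConfig())
  wt <- res$wallTable
  ct <- res$cellTable
  for (i in seq_len(nrow(ct))) {
    wids <- cells(res$graph)$wall_ids[[i]]
    expect_identical(ct$periphery_callose_sum[i],
                     sum(wt$mean_callose_intensity[match(wids, wt$wall_id)]))
    expect_identical(ct$n_pd[i], sum(wt$n_pd[match(wids, wt$wall_id)]))
  }
  # a shared wall contributes fully to both neighbours
  shared <- wt[wt$cell_id_1 != 0 & wt$cell_id_2 != 0, ][1, ]
  for (cid in c(shared$cell_id_1, shared$cell_id_2)) {
    expect_true(shared$wall_id %in%
                  cells(res$graph)$wall_ids[[which(ct$cell_id == cid)]])
  }
})

test_that("uniform callose on k walls sums to k times the level", {
  fx <- latticeFixture(2, 2, jitter = 0, seed = 1)
  seg <- segmentFixture(fx)
  g <- buildWallGraph(seg$cl, seg$wl, seg$jn,
                      data.frame(punctum_id = integer(0), row = numeric(0),
                                 col = numeric(0), det_intensity = numeric(0),
                                 peak_intensity = numeric(0),
                                 integrated_intensity = numeric(0),
                                 clipped = logical(0)),
                      seg$skel, 0.2)
  cc <- 7.25
  flat <- matrix(cc, nrow(cellLabels(g)), ncol(cellLabels(g)))
  wt <- perWallTable(g, flat)
  ct <- perCellTable(g, wt)
  expect_equal(ct$periphery_callose_sum, ct$n_walls * cc)
})

test_that("punctum double-counting over cells follows the sharing rule", {
  fx <- latticeFixture(3, 3, jitter = 0.2, seed = 6, rate = 0.6)
  res <- analyzeSingle(fx$img, analysisConfig())
  wt <- res$wallTable
  ct <- res$cellTable
  interior_pd <- sum(wt$n_pd[wt$cell_id_1 != 0 & wt$cell_id_2 != 0])
  border_pd <- sum(wt$n_pd[wt$cell_id_1 == 0 | wt$cell_id_2 == 0])
  expect_equal(sum(ct$n_pd), 2 * interior_pd + border_pd)
})

test_that("per-cell tables are invariant under id renumbering", {
  fx <- latticeFixture(2, 2, jitter = 0, seed = 1, rate = 0.4)
  res <- analyzeSingle(fx$img, analysisConfig())
  ct <- res$cellTable
  perm <- sample(nrow(ct))
  expect_setequal(ct$periphery_callose_sum,
                  ct$periphery_callose_sum[perm])
})

test_that("gold density normalizes counts to the standard window", {
  expect_equal(goldDensity(0)$density_per_um2, 0)
  g <- goldDensity(5, 0.025)
  expect_equal(g$density_per_um2, 200)
  expect_equal(g$particle_count, 5L)
  expect_equal(goldDensity(10, 0.05)$density_per_um2,
               goldDensity(5, 0.025)$density_per_um2)
  expect_error(goldDensity(-1), "non-negative")
  expect_error(goldDensity(3, 0), "positive")
  expect_error(goldDensity(2.5), "integer")
})

test_that("interface tables aggregate per cell and reject bad input", {
  counts <- data.frame(cell_id_1 = c("A", "B"), cell_id_2 = c("B", "C"),
                       pd_count = c(3, 2))
  out <- interfaceTable(counts, c("A", "B", "C"))
  expect_equal(out$per_cell$pd_total[out$per_cell$cell_id == "B"], 5)
  expect_equal(out$per_cell$pd_total[out$per_cell$cell_id == "A"], 3)
  dup <- data.frame(cell_id_1 = c("A", "B"), cell_id_2 = c("B", "A"),
                    pd_count = c(1, 2))
  expect_error(interfaceTable(dup, c("A", "B")), "duplicate interface")
  expect_error(interfaceTable(counts, c("A", "B")), "unknown cell")
  # star of k unit interfaces around one hub
  k <- 6
  star <- data.frame(cell_id_1 = "hub", cell_id_2 = paste0("s", 1:k),
                     pd_count = 1)
  hub <- interfaceTable(star, c("hub", paste0("s", 1:k)))$per_cell
  expect_equal(hub$pd_total[hub$cell_id == "hub"], k)
})

test_that("density recovery at rate 0.5 per um stays within Poisson error", {
  # quantification chain fed with the exact punctum positions: an unthinned
  # Poisson process puts pairs below the detector's resolution limit, so
  # detector completeness is a separate claim tested at resolvable spacing
  tot_pd <- 0
  tot_len <- 0
  for (s in 1:3) {
    fx <- latticeFixture(5, 5, jitter = 0.2, seed = s, rate = 0.5,
                         min_gap_um = 0)
    seg <- segmentFixture(fx)
    g <- buildWallGraph(seg$cl, seg$wl, seg$jn, gtDetections(fx$gt),
                        seg$skel, 0.2, tolerance_um = 0.5)
    wt <- perWallTable(g, punctaChannel(fx$img))
    tot_pd <- tot_pd + sum(wt$n_pd)
    tot_len <- tot_len + sum(wt$length_um)
  }
  lambda_hat <- tot_pd / tot_len
  expect_lt(abs(lambda_hat - 0.5), 3 * sqrt(tot_pd) / tot_len)
})
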