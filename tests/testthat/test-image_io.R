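test_that("TIFF metadata passes through with override precedence", {
  img <- TissueImage(matrix(runif(64 * 64, 0, 50), 64),
                     matrix(runif(64 * 64, 0, 20), 64), 0.1, "src", "cond")
  f <- tempfile(fileext = ".tiff")
  writeTissueImage(img, f)
  back <- readTissueImage(f)
  expect_equal(pixelSize(back), 0.1)
  expect_equal(dim(wallChannel(back)), c(64L, 64L))
  expect_lt(max(abs(wallChannel(back) - wallChannel(img))), 1e-4)
  expect_lt(max(abs(punctaChannel(back) - punctaChannel(img))), 1e-4)
  over <- readTissueImage(f, pixel_size_override = 0.2)
  expect_equal(pixelSize(over), 0.2)
})

test_that("malformed inputs fail loudly, never silently", {
  expect_error(readTissueImage(tempfile()), "not found")
  one <- tempfile(fileext = ".tiff")
  pdquant:::writeTiffPages(one, list(matrix(1, 8, 8)), 0.1)
  expect_error(readTissueImage(one), "puncta channel missing")
  mismatch <- tempfile(fileext = ".tiff")
  pdquant:::writeTiffPages(mismatch, list(matrix(1, 8, 8), matrix(1, 8, 9)),
                           0.1)
  expect_error(readTissueImage(mismatch), "shapes differ")
  junk <- tempfile(fileext = ".tiff")
  writeLines("not a tiff at all", junk)
  expect_error(readTissueImage(junk), "TIFF")
})

test_that("a full record writes the fixed artifact set", {
  fx <- latticeFixture(2, 2, jitter = 0, seed = 1)
  out <- file.path(tempfile(), "run")
  res <- analyzeSingle(fx$img, analysisConfig(), out_dir = out)
  csvs <- c("cells.csv", "walls.csv", "junctions.csv", "puncta.csv")
  expect_true(all(file.exists(file.path(out, csvs))))
  expect_true(file.exists(file.path(out, "analysis.json")))
  pngs <- c("walls.png", "puncta.png", "overlay.png")
  expect_true(all(file.exists(file.path(out, pngs))))
  # a record with zero puncta still writes puncta.csv with the header only
  ptab <- read.csv(file.path(out, "puncta.csv"))
  expect_identical(names(ptab), pdquant:::PUNCTA_COLS)
  expect_equal(nrow(ptab), 0)
  wtab <- read.csv(file.path(out, "walls.csv"),
                   colClasses = c(cell_id_2 = "character"))
  expect_identical(names(wtab), pdquant:::WALLS_COLS)
  expect_true("BORDER" %in% wtab$cell_id_2)
  ctab <- read.csv(file.path(out, "cells.csv"))
  expect_identical(names(ctab), pdquant:::CELLS_COLS)
  expect_equal(nrow(ctab), 4)
})

test_that("an empty record writes valid, empty artifacts", {
  rec <- new("AnalysisRecord",
             config = list(note = "empty"),
             metadata = list(rows = 0L, cols = 0L, pixel_size_um = 1,
                             source_id = "none", condition_label = "none"),
             cells = pdquant:::jsonToEmptyTable("cells"),
             walls = pdquant:::jsonToEmptyTable("walls"),
             junctions = pdquant:::jsonToEmptyTable("junctions"),
             puncta = pdquant:::jsonToEmptyTable("puncta"),
             version = "0.0.0")
  out <- tempfile()
  paths <- writeOutputs(rec, out)
  expect_true(all(file.exists(paths)))
  back <- readAnalysisJson(file.path(out, "analysis.json"))
  expect_equal(nrow(back@cells), 0)
  expect_identical(names(back@walls), names(rec@walls))
})

test_that("analysis.json round-trips the record losslessly", {
  fx <- latticeFixture(2, 2, jitter = 0, seed = 1, rate = 0.4)
  out <- tempfile()
  res <- analyzeSingle(fx$img, analysisConfig(), out_dir = out)
  back <- readAnalysisJson(file.path(out, "analysis.json"))
  expect_identical(res$record@cells, back@cells)
  expect_identical(res$record@walls, back@walls)
  expect_identical(res$record@junctions, back@junctions)
  expect_identical(res$record@puncta, back@puncta)
  expect_identical(res$record@version, back@version)
  expect_equal(res$record@metadata, back@metadata)
  # sentinels and referential integrity in the written tables
  expect_true(all(setdiff(unique(back@puncta$wall_id), "ORPHAN") %in%
                    as.character(back@walls$wall_id)))
  expect_true(all(setdiff(unique(c(back@walls$cell_id_1,
                                   back@walls$cell_id_2)), "BORDER") %in%
                    as.character(back@cells$cell_id)))
})

test_that("archives contain every output and unpack byte-identically", {
  fx <- latticeFixture(2, 2, jitter = 0, seed = 1)
  out <- tempfile()
  analyzeSingle(fx$img, analysisConfig(), out_dir = out)
  n_files <- length(list.files(out, recursive = TRUE))
  z <- packArchive(out)
  listing <- zip::zip_list(z)
  expect_equal(nrow(listing), n_files)
  unpack <- tempfile()
  zip::unzip(z, exdir = unpack)
  for (f in listing$filename) {
    expect_identical(readBin(file.path(unpack, f), "raw", 1e7),
                     readBin(file.path(out, f), "raw", 1e7),
                     info = f)
  }
  expect_error(packArchive(tempfile()), "does not exist")
  empty <- tempfile()
  dir.create(empty)
  expect_error(packArchive(empty), "empty directory")
})
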