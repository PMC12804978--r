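# Minimal baseline TIFF codec: uncompressed, single-sample (grayscale),
# multi-page, little-endian. Supports 8/16-bit unsigned and 32-bit IEEE
# float pages. This is deliberately the smallest subset of TIFF the package
# needs for two-channel microscopy frames; no installed R package reads
# TIFF in this environment. Pixel size is carried in the ImageDescription
# ("pixel_size_um=<value>") and redundantly in XResolution/ResolutionUnit.

TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L)

#' Write a two-channel image to a multi-page TIFF
#'
#' Writes the wall channel as page 1 and the puncta channel as page 2
#' (32-bit float, uncompressed, little-endian) with the pixel size recorded
#' in the ImageDescription tag (`pixel_size_um=...`) and in
#' XResolution/ResolutionUnit.
#'
#' @param image a [TissueImage-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeTissueImage <- function(image, path) {
  stopifnot(is(image, "TissueImage"))
  writeTiffPages(path, list(wallChannel(image), punctaChannel(image)),
                 pixelSize(image))
  invisible(path)
}

# low-level multi-page float32 TIFF writer
writeTiffPages <- function(path, pages, pixel_size_um) {
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- sprintf("pdquant\npixel_size_um=%.12g\n", pixel_size_um)
  descRaw <- c(charToRaw(desc), as.raw(0))
  if (length(descRaw) %% 2 == 1) descRaw <- c(descRaw, as.raw(0))
  # XResolution as pixels per cm, rational
  xden <- max(1, round(pixel_size_um * 1e5))
  xnum <- 1e9
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeChar("II", con, nchars = 2, eos = NULL)
  w16(42)
  # layout per page: [pixel data][desc][rational block][IFD]
  nEntries <- 12L
  ifdSize <- 2 + nEntries * 12 + 4
  offset <- 8
  meta <- list()
  for (p in seq_along(pages)) {
    m <- pages[[p]]
    nbytes <- length(m) * 4
    dataOff <- offset
    descOff <- dataOff + nbytes
    ratOff <- descOff + length(descRaw)
    ifdOff <- ratOff + 8
    meta[[p]] <- list(dataOff = dataOff, descOff = descOff, ratOff = ratOff,
                      ifdOff = ifdOff)
    offset <- ifdOff + ifdSize
  }
  w32(meta[[1]]$ifdOff)
  entry <- function(tag, type, count, value) {
    w16(tag); w16(type); w32(count)
    if (type == 3 && count == 1) { w16(value); w16(0) } else w32(value)
  }
  for (p in seq_along(pages)) {
    m <- pages[[p]]
    h <- nrow(m); w <- ncol(m)
    # pixel data, row-major
    writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
    writeBin(descRaw, con)
    w32(xnum); w32(xden)
    w16(nEntries)
    entry(256, 4, 1, w)                      # ImageWidth
    entry(257, 4, 1, h)                      # ImageLength
    entry(258, 3, 1, 32)                     # BitsPerSample
    entry(259, 3, 1, 1)                      # Compression: none
    entry(262, 3, 1, 1)                      # Photometric: BlackIsZero
    entry(270, 2, length(descRaw), meta[[p]]$descOff)  # ImageDescription
    entry(273, 4, 1, meta[[p]]$dataOff)      # StripOffsets
    entry(277, 3, 1, 1)                      # SamplesPerPixel
    entry(278, 4, 1, h)                      # RowsPerStrip
    entry(279, 4, 1, h * w * 4)              # StripByteCounts
    entry(282, 5, 1, meta[[p]]$ratOff)       # XResolution
    entry(339, 3, 1, 3)                      # SampleFormat: IEEE float
    w32(if (p < length(pages)) meta[[p + 1]]$ifdOff else 0)
  }
  invisible(path)
}

# low-level TIFF reader: returns list(pages = list of matrices,
# pixel_size_um = numeric or NA)
readTiffPages <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file: too short")
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big"
    else stop("not a TIFF file: bad byte-order mark")
  rd <- function(off, n, size, what = "integer", signed = TRUE) {
    readBin(raw[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = signed)
  }
  magic <- rd(2, 1, 2, signed = FALSE)
  if (magic != 42) stop("not a TIFF file: bad magic number")
  ifdOff <- rd(4, 1, 4)
  pages <- list()
  pixel_size <- NA_real_
  while (ifdOff != 0) {
    n <- rd(ifdOff, 1, 2, signed = FALSE)
    tags <- list()
    for (i in seq_len(n)) {
      e <- ifdOff + 2 + (i - 1) * 12
      tag <- rd(e, 1, 2, signed = FALSE)
      type <- rd(e + 2, 1, 2, signed = FALSE)
      count <- rd(e + 4, 1, 4)
      tsize <- TIFF_TYPE_SIZE[as.character(type)]
      if (is.na(tsize)) next
      inline <- count * tsize <= 4
      valOff <- if (inline) e + 8 else rd(e + 8, 1, 4)
      val <- switch(as.character(type),
        `1` = rd(valOff, count, 1, signed = FALSE),
        `2` = rawToChar(raw[(valOff + 1):(valOff + count)][
          raw[(valOff + 1):(valOff + count)] != as.raw(0)]),
        `3` = rd(valOff, count, 2, signed = FALSE),
        `4` = rd(valOff, count, 4),
        `5` = rd(valOff, 2 * count, 4))
      tags[[as.character(tag)]] <- val
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stop(sprintf("TIFF tag %d missing", tag))
        default
      } else v
    }
    w <- need(256); h <- need(257)
    bits <- need(258, 1)[1]
    if (need(259, 1) != 1) stop("unsupported TIFF: compressed data")
    if (need(277, 1) != 1) stop("unsupported TIFF: multi-sample pixels")
    fmt <- need(339, 1)[1]
    offs <- need(273)
    counts <- need(279, h * w * bits / 8)
    vals <- numeric(0)
    for (s in seq_along(offs)) {
      npx <- counts[s] / (bits / 8)
      vals <- c(vals, switch(as.character(bits),
        `8` = rd(offs[s], npx, 1, signed = FALSE),
        `16` = rd(offs[s], npx, 2, signed = FALSE),
        `32` = {
          if (fmt != 3) stop("unsupported TIFF: 32-bit integer samples")
          rd(offs[s], npx, 4, what = "numeric")
        },
        stop(sprintf("unsupported TIFF: %d bits per sample", bits))))
    }
    pages[[length(pages) + 1]] <- matrix(vals, nrow = h, ncol = w,
                                         byrow = TRUE)
    if (is.na(pixel_size)) {
      d <- tags[["270"]]
      if (!is.null(d)) {
        m <- regmatches(d, regexec("pixel_size_um=([0-9.eE+-]+)", d))[[1]]
        if (length(m) == 2) pixel_size <- as.numeric(m[2])
      }
      if (is.na(pixel_size) && !is.null(tags[["282"]])) {
        xr <- tags[["282"]]
        unit <- if (!is.null(tags[["296"]])) tags[["296"]][1] else 2
        unit_um <- if (unit == 3) 1e4 else if (unit == 2) 25400 else NA
        if (!is.na(unit_um) && xr[1] > 0)
          pixel_size <- unit_um * xr[2] / xr[1]
      }
    }
    ifdOff <- rd(ifdOff + 2 + n * 12, 1, 4)
  }
  list(pages = pages, pixel_size_um = pixel_size)
}

#' Read a two-channel tissue image from a multi-page TIFF
#'
#' Page 1 is taken as the wall-stain channel and page 2 as the callose/PD
#' channel (inputs with the opposite order must be re-ordered by the
#' caller). The pixel size comes from the file metadata unless overridden;
#' a file with no pixel-size metadata and no override is an error, never a
#' silent default.
#'
#' @param path multi-page TIFF path (>= 2 grayscale pages).
#' @param pixel_size_override optional micrometres per pixel, takes
#'   precedence over file metadata.
#' @param source_id,condition_label provenance labels (source defaults to
#'   the file name).
#' @return a [TissueImage-class].
#' @export
readTissueImage <- function(path, pixel_size_override = NULL,
                            source_id = basename(path),
                            condition_label = "unknown") {
  tf <- readTiffPages(path)
  if (length(tf$pages) < 2)
    stop("puncta channel missing: file has fewer than 2 pages")
  if (!identical(dim(tf$pages[[1]]), dim(tf$pages[[2]])))
    stop("channel shapes differ between pages")
  ps <- if (!is.null(pixel_size_override)) pixel_size_override else
    tf$pixel_size_um
  if (is.na(ps) || is.null(ps))
    stop("no pixel size in file metadata; pass pixel_size_override")
  TissueImage(wallChannel = tf$pages[[1]], punctaChannel = tf$pages[[2]],
              pixelSize = ps, sourceId = source_id,
              conditionLabel = condition_label)
}
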