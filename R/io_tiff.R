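# Minimal baseline-TIFF codec.
#
# The grading stack ships no TIFF package for R, so the package carries its
# own reader/writer for the subset it needs: uncompressed grayscale rasters
# (8/16-bit unsigned, 32-bit float), little- or big-endian, single or
# multiple strips, multi-page files (explicit page selection), and enough of
# multi-sample (RGB) parsing to honour the "choose a channel" contract.
# Images are exchanged as numeric matrices: img[row, col], row 1 = top.

TIFF_TAGS <- c(
  ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
  Compression = 259L, Photometric = 262L, StripOffsets = 273L,
  SamplesPerPixel = 277L, RowsPerStrip = 278L, StripByteCounts = 279L,
  PlanarConfig = 284L, SampleFormat = 339L
)

tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                    `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L,
                    `11` = 4L, `12` = 8L)

read_uint <- function(raw, size, endian) {
  v <- readBin(raw, "integer", n = length(raw) %/% size, size = size,
               signed = size == 4L, endian = endian)
  if (size == 4L) v[v < 0] <- v[v < 0] + 4294967296
  if (size < 4L) v <- v %% (2^(8 * size))
  as.numeric(v)
}

read_ifd_entries <- function(con, raw, offset, endian) {
  n <- read_uint(raw[offset + 1:2], 2L, endian)
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    e0 <- offset + 2L + (i - 1L) * 12L
    tag <- read_uint(raw[e0 + 1:2], 2L, endian)
    typ <- read_uint(raw[e0 + 3:4], 2L, endian)
    cnt <- read_uint(raw[e0 + 5:8], 4L, endian)
    sz <- tiff_type_size[[as.character(typ)]]
    nbytes <- sz * cnt
    if (nbytes <= 4) {
      valraw <- raw[e0 + 9:(8 + max(nbytes, 1))]
    } else {
      voff <- read_uint(raw[e0 + 9:12], 4L, endian)
      valraw <- raw[voff + seq_len(nbytes)]
    }
    val <- switch(as.character(typ),
      `3` = read_uint(valraw, 2L, endian),
      `4` = read_uint(valraw, 4L, endian),
      `1` = read_uint(valraw, 1L, endian),
      NULL)
    entries[[i]] <- list(tag = tag, value = val)
  }
  next_off <- read_uint(raw[offset + 2L + n * 12L + 1:4], 4L, endian)
  list(entries = entries, next_offset = next_off)
}

ifd_value <- function(ifd, tagname, default = NULL) {
  tag <- TIFF_TAGS[[tagname]]
  for (e in ifd$entries) if (e$tag == tag) return(e$value)
  default
}

#' Read a grayscale TIFF image
#'
#' Accepts uncompressed baseline TIFF: 8- or 16-bit unsigned integer or
#' 32-bit IEEE float samples. Integer data are promoted to double without
#' any rescaling, so raw camera counts survive the round trip.
#'
#' @param path file path.
#' @param page 1-based page index; required when the file holds more than
#'   one image (directory).
#' @param channel 1-based sample index; required for multi-sample (e.g.
#'   RGB) files.
#' @return numeric matrix `img[row, col]`, row 1 at the top of the image.
#' @export
read_image <- function(path, page = NULL, channel = NULL) {
  if (!file.exists(path)) stop_fq("image file '%s' not found", path)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop_fq("'%s' is not a TIFF file (too short)", path)
  byte_order <- rawToChar(raw[1:2])
  endian <- switch(byte_order, II = "little", MM = "big",
                   stop_fq("'%s' is not a TIFF file (bad byte order mark)", path))
  if (read_uint(raw[3:4], 2L, endian) != 42)
    stop_fq("'%s' is not a TIFF file (magic != 42)", path)

  # walk the IFD chain
  offsets <- c()
  off <- read_uint(raw[5:8], 4L, endian)
  while (off != 0) {
    offsets <- c(offsets, off)
    ifd <- read_ifd_entries(NULL, raw, off, endian)
    off <- ifd$next_offset
    if (length(offsets) > 1e4) stop_fq("corrupt TIFF: IFD chain loop")
  }
  if (length(offsets) > 1L && is.null(page))
    stop_fq("'%s' has %d pages; pass `page` to select one",
            path, length(offsets))
  if (is.null(page)) page <- 1L
  if (page < 1L || page > length(offsets))
    stop_fq("page %d out of range (file has %d)", page, length(offsets))
  ifd <- read_ifd_entries(NULL, raw, offsets[page], endian)

  width <- ifd_value(ifd, "ImageWidth")
  height <- ifd_value(ifd, "ImageLength")
  bits <- ifd_value(ifd, "BitsPerSample", 1)
  comp <- ifd_value(ifd, "Compression", 1)
  spp <- ifd_value(ifd, "SamplesPerPixel", 1)
  fmt <- ifd_value(ifd, "SampleFormat", 1)[1]
  photometric <- ifd_value(ifd, "Photometric", 1)
  if (comp != 1) stop_fq("unsupported TIFF compression scheme %d", comp)
  if (spp > 1 && is.null(channel))
    stop_fq("'%s' has %d samples per pixel; pass `channel` to select one",
            path, spp)
  if (is.null(channel)) channel <- 1L
  if (channel < 1L || channel > spp)
    stop_fq("channel %d out of range (%d samples per pixel)", channel, spp)
  if (spp > 1 && ifd_value(ifd, "PlanarConfig", 1) != 1)
    stop_fq("unsupported planar configuration")
  bits <- bits[1]
  if (!(bits %in% c(8, 16, 32)))
    stop_fq("unsupported bit depth %d", bits)
  if (bits == 32 && fmt != 3)
    stop_fq("32-bit TIFF supported only for float samples (SampleFormat 3)")

  strip_off <- ifd_value(ifd, "StripOffsets")
  strip_cnt <- ifd_value(ifd, "StripByteCounts")
  data <- raw(0)
  for (i in seq_along(strip_off))
    data <- c(data, raw[strip_off[i] + seq_len(strip_cnt[i])])

  npix <- width * height * spp
  vals <- if (bits == 32) {
    readBin(data, "double", n = npix, size = 4L, endian = endian)
  } else {
    read_uint(data, bits %/% 8L, endian)
  }
  if (length(vals) < npix) stop_fq("truncated TIFF pixel data")
  vals <- vals[seq.int(channel, npix, by = spp)]
  img <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)
  if (photometric == 0) img <- max(img) - img  # white-is-zero
  img
}

#' Write a grayscale TIFF image
#'
#' Writes a single-strip uncompressed little-endian TIFF. Integer modes
#' store values verbatim (callers must keep them inside the sample range);
#' `bits = "float32"` stores IEEE floats. A list of matrices writes a
#' multi-page file; a 3-column-array (h x w x 3) writes interleaved RGB
#' (used only to exercise reader contracts).
#'
#' @param img numeric matrix, list of matrices (pages), or h x w x 3 array.
#' @param path output path.
#' @param bits one of 8, 16 or "float32".
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bits = 16) {
  pages <- if (is.list(img)) img else list(img)
  # assemble in memory: simpler to compute IFD offsets

  put16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
  put32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")
  out <- c(charToRaw("II"), put16(42), put32(8))
  pos <- 8L

  encode_page <- function(m, pos) {
    samples <- if (length(dim(m)) == 3L) dim(m)[3] else 1L
    h <- dim(m)[1]; w <- dim(m)[2]
    float_mode <- identical(bits, "float32")
    bps <- if (float_mode) 32L else as.integer(bits)
    if (samples == 1L) {
      v <- as.numeric(t(m))
    } else {
      v <- as.numeric(aperm(m, c(3, 2, 1)))  # interleave samples
    }
    pix <- if (float_mode) {
      writeBin(v, raw(), size = 4L, endian = "little")
    } else {
      maxv <- 2^bps - 1
      if (any(v < 0 | v > maxv))
        stop_fq("pixel values outside [0, %d]; rescale before writing", maxv)
      iv <- as.integer(round(v))
      iv <- as.integer(ifelse(iv >= 2^(bps - 1), iv - 2^bps, iv))  # two's complement
      writeBin(iv, raw(), size = bps %/% 8L, endian = "little")
    }
    tags <- list(
      list(256L, 4L, 1L, w), list(257L, 4L, 1L, h),
      list(258L, 3L, 1L, bps), list(259L, 3L, 1L, 1L),
      list(262L, 3L, 1L, 1L), list(273L, 4L, 1L, NA),  # offset patched below
      list(277L, 3L, 1L, samples), list(278L, 4L, 1L, h),
      list(279L, 4L, 1L, length(pix)), list(284L, 3L, 1L, 1L),
      list(339L, 3L, 1L, if (float_mode) 3L else 1L)
    )
    ifd_len <- 2L + 12L * length(tags) + 4L
    data_off <- pos + ifd_len
    ifd <- put16(length(tags))
    for (tg in tags) {
      val <- if (is.na(tg[[4]])) data_off else tg[[4]]
      valraw <- if (tg[[2]] == 3L) c(put16(val), put16(0)) else put32(val)
      ifd <- c(ifd, put16(tg[[1]]), put16(tg[[2]]), put32(tg[[3]]), valraw)
    }
    list(ifd = ifd, pix = pix, next_field_at = pos + 2L + 12L * length(tags),
         end = data_off + length(pix))
  }

  for (i in seq_along(pages)) {
    pg <- encode_page(pages[[i]], pos)
    next_off <- if (i < length(pages)) pg$end else 0L
    ifd <- c(pg$ifd, put32(next_off))
    out <- c(out, ifd, pg$pix)
    pos <- pg$end
  }
  writeBin(out, path)
  invisible(path)
}
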