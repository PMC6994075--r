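#' Read a single-worm micrograph
#'
#' Reads PNG, JPEG, TIFF (uncompressed baseline) or ASCII PGM/PPM/PBM
#' rasters into a calibrated image.  PNG and JPEG are handled by the
#' \pkg{png} and \pkg{jpeg} packages; TIFF support is a small built-in
#' baseline reader (8-bit, uncompressed, grey or RGB) sufficient for the
#' masks and `edge.tif` files this package writes.
#'
#' @param path file to read.
#' @param scale physical length per pixel (required; micrographs must be
#'   spatially calibrated for the outputs to be in physical units).
#' @return a [worm_image].
#' @export
read_worm_image <- function(path, scale) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    tif  = ,
    tiff = read_tiff_simple(path),
    pgm  = ,
    ppm  = ,
    pbm  = read_pnm_ascii(path),
    stop("unsupported image format: .", ext)
  )
  if (length(dim(px)) == 3L && dim(px)[3] == 4L) px <- px[, , 1:3]  # drop alpha
  if (length(dim(px)) == 3L && dim(px)[3] == 2L) px <- px[, , 1L]   # grey+alpha
  worm_image(px, scale, source = basename(path))
}

#' Read a pre-binarized mask from disk
#'
#' Accepts any format [read_worm_image] reads.  Pixels are thresholded at
#' mid-grey; the conventional polarity (worm dark on light background) is
#' detected with the minority-area rule, so either polarity on disk works.
#'
#' @inheritParams read_worm_image
#' @return a [worm_mask].
#' @export
read_mask <- function(path, scale) {
  img <- read_worm_image(path, scale)
  px <- img$pixels
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  dark <- px < 0.5
  fg <- if (sum(dark) <= length(dark) / 2) dark else !dark
  worm_mask(fg, scale, provenance = paste0("read:", basename(path)))
}

#' Write a binary mask (or any boolean raster) to disk
#'
#' Emits the conventional display polarity: worm black (0) on white (255).
#' Format follows the file extension: PNG, uncompressed 8-bit TIFF, or
#' ASCII PGM.
#'
#' @param mask a [worm_mask] or a logical matrix (TRUE = object).
#' @param path output file; extension selects the format.
#' @param invert if TRUE write object-white-on-black instead (used for
#'   skeleton/outline debug rasters, where the line is the object).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, invert = FALSE) {
  px <- if (inherits(mask, "worm_mask")) mask$pixels else mask
  stopifnot(is.logical(px), is.matrix(px))
  g <- matrix(1, nrow(px), ncol(px))
  g[px] <- 0                       # object black on white
  if (invert) g <- 1 - g
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(g, path),
    tif  = ,
    tiff = write_tiff_simple(g, path),
    pgm  = write_pgm_ascii(g, path),
    stop("unsupported output format: .", ext)
  )
  invisible(path)
}

## ---- minimal baseline TIFF (uncompressed, 8-bit, grey/RGB) ----------------

read_tiff_simple <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L) stop("not a TIFF file: ", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file: ", path))
  int_at <- function(off, size, n = 1L)   # size-4 reads are signed (R has
    readBin(raw[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            signed = size >= 4L, endian = endian)  # no uint32; files < 2 GiB)
  if (int_at(2L, 2L) != 42L) stop("not a TIFF file: ", path)
  ifd <- int_at(4L, 4L)
  n_entries <- int_at(ifd, 2L)
  tags <- list()
  for (i in seq_len(n_entries)) {
    e <- ifd + 2L + (i - 1L) * 12L
    tag <- int_at(e, 2L); typ <- int_at(e + 2L, 2L); cnt <- int_at(e + 4L, 4L)
    sz <- c(1L, 1L, 2L, 4L, 8L)[typ]
    if (is.na(sz)) next
    val_off <- if (sz * cnt <= 4L) e + 8L else int_at(e + 8L, 4L)
    vals <- if (typ == 3L) int_at(val_off, 2L, cnt)
            else if (typ %in% c(1L, 4L)) int_at(val_off, if (typ == 1L) 1L else 4L, cnt)
            else NULL
    if (!is.null(vals)) tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF tag ", tag, " missing in ", path)
      default
    } else v
  }
  w <- need(256L); h <- need(257L)
  bps <- need(258L, 8L); comp <- need(259L, 1L); spp <- need(277L, 1L)
  if (comp != 1L) stop("only uncompressed TIFF is supported (compression=", comp, ")")
  if (any(bps != 8L)) stop("only 8-bit TIFF is supported")
  if (!spp %in% c(1L, 3L)) stop("unsupported TIFF samples per pixel: ", spp)
  offs <- need(273L); counts <- need(279L, w * h * spp)
  rps <- need(278L, h)
  data <- raw(0)
  for (i in seq_along(offs))
    data <- c(data, raw[(offs[i] + 1L):(offs[i] + counts[i])])
  vals <- as.integer(data[seq_len(w * h * spp)]) / 255
  photometric <- need(262L, 1L)
  if (spp == 1L) {
    m <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    if (photometric == 0L) m <- 1 - m   # WhiteIsZero
    m
  } else {
    a <- array(0, c(h, w, 3L))
    for (k in 1:3)
      a[, , k] <- matrix(vals[seq(k, length(vals), by = 3L)], h, w, byrow = TRUE)
    a
  }
}

write_tiff_simple <- function(g, path) {
  stopifnot(is.matrix(g))
  h <- nrow(g); w <- ncol(g)
  bytes <- as.raw(pmin(255L, pmax(0L, as.integer(round(t(g) * 255)))))
  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  entry <- function(tag, typ, cnt, val) { u16(tag); u16(typ); u32(cnt); u32(val) }
  writeBin(charToRaw("II"), con); u16(42L); u32(8L)   # header, IFD at byte 8
  n_ent <- 8L
  data_off <- 8L + 2L + n_ent * 12L + 4L
  u16(n_ent)
  entry(256L, 3L, 1L, w)            # ImageWidth
  entry(257L, 3L, 1L, h)            # ImageLength
  entry(258L, 3L, 1L, 8L)           # BitsPerSample
  entry(259L, 3L, 1L, 1L)           # Compression: none
  entry(262L, 3L, 1L, 1L)           # Photometric: BlackIsZero
  entry(273L, 4L, 1L, data_off)     # StripOffsets
  entry(278L, 3L, 1L, h)            # RowsPerStrip
  entry(279L, 4L, 1L, w * h)        # StripByteCounts
  u32(0L)                           # no next IFD
  writeBin(bytes, con)
  invisible(path)
}

## ---- ASCII netpbm ---------------------------------------------------------

read_pnm_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- sub("#.*$", "", txt)
  toks <- unlist(strsplit(paste(txt, collapse = " "), "[[:space:]]+"))
  toks <- toks[nzchar(toks)]
  magic <- toks[1]
  if (!magic %in% c("P1", "P2", "P3")) stop("only ASCII PNM supported: ", magic)
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  if (magic == "P1") {
    v <- as.numeric(toks[-(1:3)])
    return(matrix(1 - v[seq_len(w * h)], h, w, byrow = TRUE))  # P1: 1 = black
  }
  maxv <- as.numeric(toks[4])
  v <- as.numeric(toks[-(1:4)]) / maxv
  if (magic == "P2") return(matrix(v[seq_len(w * h)], h, w, byrow = TRUE))
  a <- array(0, c(h, w, 3L))
  for (k in 1:3) a[, , k] <- matrix(v[seq(k, 3L * w * h, by = 3L)], h, w, byrow = TRUE)
  a
}

write_pgm_ascii <- function(g, path) {
  h <- nrow(g); w <- ncol(g)
  vals <- as.integer(round(t(g) * 255))
  rows <- vapply(seq_len(h), function(r)
    paste(vals[((r - 1L) * w + 1L):(r * w)], collapse = " "), character(1))
  writeLines(c("P2", paste(w, h), "255", rows), path)
  invisible(path)
}
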