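#' Calibrated single-worm image
#'
#' A light-weight container for a raster of intensities together with its
#' spatial calibration.  Pixel values are stored on the unit interval
#' (integer rasters are rescaled by their bit depth on read).  The raster is
#' a numeric matrix (greyscale) or an \code{height x width x 3} array (RGB);
#' the origin is the top-left pixel, rows run down, columns run right.
#' Sub-pixel coordinates used elsewhere in the package are
#' \code{(x = column, y = row)} with integer values at pixel centres.
#'
#' @param pixels numeric matrix or 3-channel array with values in
#'   \code{[0, 1]}.
#' @param scale physical length per pixel (e.g. mm/px); must be > 0.
#' @param source optional file name the image came from.
#' @return an object of class \code{worm_image}.
#' @export
worm_image <- function(pixels, scale, source = NA_character_) {
  if (!is.numeric(pixels)) stop("pixels must be numeric")
  d <- dim(pixels)
  if (is.null(d) || !(length(d) == 2L || (length(d) == 3L && d[3] %in% c(1L, 3L))))
    stop("pixels must be a matrix or an array with 1 or 3 channels, got ",
         if (is.null(d)) "a vector" else paste0(length(d), "-d array with ",
                                                d[length(d)], " channels"))
  if (length(d) == 3L && d[3] == 1L) { pixels <- pixels[, , 1L]; d <- dim(pixels) }
  if (d[1] < 8L || d[2] < 8L)
    stop("image must be at least 8x8 pixels, got ", d[1], "x", d[2])
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("scale must be a single positive number (physical length per pixel)")
  structure(list(pixels = pixels, scale = scale, source = source),
            class = "worm_image")
}

#' @export
print.worm_image <- function(x, ...) {
  d <- dim(x$pixels)
  nc <- if (length(d) == 3L) d[3] else 1L
  cat(sprintf("<worm_image> %d x %d px, %d channel%s, scale %g units/px\n",
              d[2], d[1], nc, if (nc > 1) "s" else "", x$scale))
  invisible(x)
}

n_channels <- function(img) {
  d <- dim(img$pixels)
  if (length(d) == 3L) d[3] else 1L
}

#' Binary worm mask
#'
#' Boolean raster with the worm as foreground (\code{TRUE}).  Writers emit
#' the conventional display polarity (worm black on white background); the
#' internal representation is polarity-free.  A finished mask holds exactly
#' one 8-connected foreground component that does not touch the image
#' border.
#'
#' @param pixels logical matrix, \code{TRUE} on the worm.
#' @param scale physical length per pixel, inherited from the source image.
#' @param provenance character vector of operations applied so far.
#' @return an object of class \code{worm_mask}.
#' @export
worm_mask <- function(pixels, scale, provenance = character()) {
  if (is.numeric(pixels)) pixels <- pixels > 0.5
  if (!is.logical(pixels) || !is.matrix(pixels)) stop("pixels must be a logical matrix")
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("scale must be a single positive number")
  pixels[is.na(pixels)] <- FALSE
  structure(list(pixels = pixels, scale = scale, provenance = provenance),
            class = "worm_mask")
}

#' @export
print.worm_mask <- function(x, ...) {
  cat(sprintf("<worm_mask> %d x %d px, %d foreground px, scale %g units/px\n",
              ncol(x$pixels), nrow(x$pixels), sum(x$pixels), x$scale))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

with_step <- function(mask, pixels, step) {
  worm_mask(pixels, mask$scale, c(mask$provenance, step))
}

#' Validate the single-worm mask invariants
#'
#' Checks that a mask has exactly one 8-connected foreground component, that
#' the foreground does not touch the border, and that it meets the minimum
#' area.  Called by the pipeline after preprocessing; exported because the
#' synthetic generator and tests use it too.
#'
#' @param mask a \code{worm_mask}.
#' @param min_area_px minimum foreground pixel count (default 200).
#' @return the mask, invisibly; errors on violation.
#' @export
validate_mask <- function(mask, min_area_px = 200L) {
  px <- mask$pixels
  a <- sum(px)
  if (a < min_area_px)
    stop("foreground area ", a, " px below minimum ", min_area_px, " px")
  if (any(px[1, ]) || any(px[nrow(px), ]) || any(px[, 1]) || any(px[, ncol(px)]))
    stop("foreground touches the image border; expand the canvas first")
  lab <- label_components(px)
  if (lab$n != 1L)
    stop("mask has ", lab$n, " foreground components; expected exactly 1")
  invisible(mask)
}
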