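#' Select the highest-contrast colour channel
#'
#' Colour micrographs are split into red, green and blue components and the
#' channel with the greatest contrast is kept; contrast is measured as the
#' standard deviation of pixel intensities.  Greyscale images pass through
#' unchanged.
#'
#' @param img a [worm_image] with 1 or 3 channels.
#' @return a single-channel [worm_image].
#' @export
select_channel <- function(img) {
  nc <- n_channels(img)
  if (nc == 1L) return(img)
  if (nc != 3L) stop("unsupported channel count: ", nc)
  sds <- vapply(1:3, function(k) stats::sd(img$pixels[, , k]), numeric(1))
  if (all(sds == 0)) stop("no contrast: all channels are constant")
  worm_image(img$pixels[, , which.max(sds)], img$scale, img$source)
}

otsu_threshold <- function(v, nbins = 256L) {
  counts <- tabulate(pmin(nbins, floor(v * nbins) + 1L), nbins)
  p <- counts / sum(counts)
  mids <- (seq_len(nbins) - 0.5) / nbins
  w1 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  between <- (mu_t * w1 - mu)^2 / (w1 * (1 - w1))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

isodata_threshold <- function(v, nbins = 256L) {
  t <- mean(range(v))
  for (i in 1:100) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t) < 1 / (2 * nbins)) { t <- t_new; break }
    t <- t_new
  }
  t
}

#' Binarize a single-channel image into a worm mask
#'
#' Applies a percentile contrast stretch (saturating `saturate` of the
#' pixels in each tail, default 0.35\%, the conventional default of
#' enhance-contrast tools) followed by a global automatic threshold.  The
#' side of the threshold covering the minority of the image area becomes
#' the foreground, so a dark worm on a bright field and its inverted
#' counterpart give the same mask.
#'
#' @param img single-channel [worm_image].
#' @param method `"otsu"` (default) or `"isodata"`.
#' @param saturate fraction of pixels clipped per tail by the stretch.
#' @return a [worm_mask] (worm = TRUE).
#' @export
binarize <- function(img, method = c("otsu", "isodata"), saturate = 0.0035) {
  method <- match.arg(method)
  if (n_channels(img) != 1L) stop("binarize needs a single-channel image")
  v <- as.vector(img$pixels)
  rng <- range(v)
  if (diff(rng) == 0) stop("no contrast: image is constant")
  q <- stats::quantile(v, c(saturate, 1 - saturate), names = FALSE)
  if (q[2] <= q[1]) q <- rng
  v <- pmin(1, pmax(0, (v - q[1]) / (q[2] - q[1])))
  t <- switch(method, otsu = otsu_threshold(v), isodata = isodata_threshold(v))
  dark <- matrix(v <= t, nrow(img$pixels), ncol(img$pixels))
  fg <- if (sum(dark) <= length(dark) / 2) dark else !dark
  if (!any(fg)) stop("no object found after thresholding")
  worm_mask(fg, img$scale,
            provenance = c(sprintf("stretch:%g", saturate),
                           sprintf("threshold:%s", method)))
}

#' Fill interior holes of a mask
#'
#' Every background region not connected to the image border becomes
#' foreground (flood fill from the border, complement).
#'
#' @param mask a [worm_mask].
#' @return the hole-free mask.
#' @export
fill_holes <- function(mask) {
  outside <- border_background(mask$pixels)
  with_step(mask, mask$pixels | !outside, "fill_holes")
}

#' Morphological cleanup: closing, opening, largest component
#'
#' Closing (dilate then erode, 3x3 8-connected element) smooths ragged
#' edges; opening (erode then dilate) removes small artefacts such as eggs.
#' Afterwards only the largest 8-connected component is kept, guaranteeing
#' the one-worm invariant; ties are broken by the topmost, then leftmost,
#' component centroid.
#'
#' @param mask a [worm_mask].
#' @param close_iters,open_iters number of closing / opening passes (>= 0).
#' @return the cleaned mask.
#' @export
morphological_cleanup <- function(mask, close_iters = 1L, open_iters = 0L) {
  stopifnot(close_iters >= 0L, open_iters >= 0L)
  px <- mask$pixels
  for (i in seq_len(close_iters)) px <- erode3(dilate3(px))
  for (i in seq_len(open_iters))  px <- dilate3(erode3(px))
  if (!any(px)) stop("object eliminated by cleanup")
  lab <- label_components(px)
  if (lab$n > 1L) {
    best <- which(lab$sizes == max(lab$sizes))
    if (length(best) > 1L) {
      cen <- t(vapply(best, function(k) {
        idx <- which(lab$labels == k, arr.ind = TRUE)
        c(mean(idx[, 1]), mean(idx[, 2]))          # (row, col) centroid
      }, numeric(2)))
      best <- best[order(cen[, 1], cen[, 2])][1L]  # topmost, then leftmost
    }
    px <- lab$labels == best
  }
  with_step(mask, px,
            sprintf("cleanup:close=%d,open=%d", close_iters, open_iters))
}

mask_orientation <- function(px) {
  idx <- which(px, arr.ind = TRUE)
  y <- idx[, 1]; x <- idx[, 2]
  mu20 <- stats::var(x) * (length(x) - 1) / length(x)
  mu02 <- stats::var(y) * (length(y) - 1) / length(y)
  mu11 <- mean(x * y) - mean(x) * mean(y)
  0.5 * atan2(2 * mu11, mu20 - mu02)
}

#' Rotate the worm horizontal on an expanded canvas
#'
#' Expands the canvas by `pad` pixels on all sides and rotates the mask so
#' the principal axis of the foreground's second central moments is
#' horizontal (the worm's longest dimension ends up left-right).  The
#' rotated raster is re-thresholded at 0.5 to stay binary.  If rotation
#' would clip the foreground against the border the canvas is re-padded and
#' the rotation retried, up to `max_pad`.
#'
#' @param mask single-component [worm_mask].
#' @param pad canvas margin in pixels; the default 60 px exceeds the 40 px
#'   reach of the perpendicular profile lines used downstream.
#' @return the rotated mask, bounding box at least as wide as tall.
#' @export
orient_horizontal <- function(mask, pad = 60L) {
  theta <- mask_orientation(mask$pixels)
  tr <- trim_to_bbox(mask$pixels)
  # a square canvas as large as the bounding-box diagonal cannot clip any
  # rotation about its centre
  side <- ceiling(sqrt(nrow(tr)^2 + ncol(tr)^2)) + 4L
  px <- matrix(FALSE, side, side)
  r0 <- (side - nrow(tr)) %/% 2L
  c0 <- (side - ncol(tr)) %/% 2L
  px[r0 + seq_len(nrow(tr)), c0 + seq_len(ncol(tr))] <- tr
  rot <- rotate_mask_raster(px, theta)
  bb <- fg_bbox(rot)
  if (bb["rmax"] - bb["rmin"] > bb["cmax"] - bb["cmin"])
    rot <- rotate_mask_raster(px, theta + pi / 2)
  if (any(rot[1, ]) || any(rot[nrow(rot), ]) ||
      any(rot[, 1]) || any(rot[, ncol(rot)]))
    stop("rotation clips foreground against the canvas border")
  rot <- pad_raster(trim_to_bbox(rot, margin = 0L), pad)
  lab <- label_components(rot)
  if (lab$n > 1L) rot <- lab$labels == which.max(lab$sizes)
  with_step(mask, rot, sprintf("orient:pad=%d", pad))
}

trim_to_bbox <- function(px, margin = 2L) {
  bb <- fg_bbox(px)
  rs <- max(1L, bb["rmin"] - margin):min(nrow(px), bb["rmax"] + margin)
  cs <- max(1L, bb["cmin"] - margin):min(ncol(px), bb["cmax"] + margin)
  px[rs, cs, drop = FALSE]
}

#' Full preprocessing chain: micrograph to clean horizontal mask
#'
#' Channel selection, contrast stretch + threshold, hole filling,
#' morphological cleanup and horizontal orientation, in that order.
#'
#' @param img a [worm_image] (colour or greyscale).
#' @param threshold_method passed to [binarize].
#' @param close_iters,open_iters passed to [morphological_cleanup].
#' @param pad_px canvas margin for [orient_horizontal].
#' @param min_area_px minimum acceptable worm area, see [validate_mask].
#' @return a validated, horizontal [worm_mask].
#' @export
preprocess_image <- function(img, threshold_method = "otsu",
                             close_iters = 1L, open_iters = 0L,
                             pad_px = 60L, min_area_px = 200L) {
  mask <- binarize(select_channel(img), method = threshold_method)
  mask <- fill_holes(mask)
  mask <- morphological_cleanup(mask, close_iters, open_iters)
  mask <- orient_horizontal(mask, pad = pad_px)
  validate_mask(mask, min_area_px)
}

#' Preprocess an already-binary mask
#'
#' For inputs that are binary on disk: fills holes, keeps the largest
#' component and orients the worm horizontal.
#'
#' @inheritParams preprocess_image
#' @param mask a [worm_mask].
#' @return a validated, horizontal [worm_mask].
#' @export
preprocess_mask <- function(mask, pad_px = 60L, min_area_px = 200L) {
  mask <- fill_holes(mask)
  mask <- morphological_cleanup(mask, 0L, 0L)
  mask <- orient_horizontal(mask, pad = pad_px)
  validate_mask(mask, min_area_px)
}
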