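# Per-column weighted centroid of the first above-threshold run in V
# (rows = samples along each ray at offsets tt, columns = rays); NA where
# a ray never meets the outline.
first_run_centroid <- function(V, tt, threshold = 0.2) {
  nt <- nrow(V); nray <- ncol(V)
  A <- V > threshold
  any_hit <- colSums(A) > 0
  f <- max.col(t(A), ties.method = "first")       # first above per ray
  ri <- row(V)
  fm <- matrix(f, nt, nray, byrow = TRUE)
  after <- ri >= fm
  below_after <- !A & after
  e <- max.col(t(below_after), ties.method = "first")  # run end (exclusive)
  e[colSums(below_after) == 0] <- nt + 1L
  run <- after & ri < matrix(e, nt, nray, byrow = TRUE)
  wt <- V * run
  cen <- colSums(wt * tt) / colSums(wt)
  cen[!any_hit] <- NA_real_
  cen
}

#' Width (diameter) profile along the spine
#'
#' At every point of the extended spine a probe line is drawn normal to
#' the midline and moved through the one-pixel outline of the worm; the
#' first outline crossing on each side of the spine (sub-pixel, by linear
#' interpolation) gives the two edge points, and their distance is the
#' worm's diameter at that arc-length position.  Crossings beyond the
#' first on a side are ignored, which guards against the probe re-entering
#' the far limb of a curled worm.  The two appended tip points get width 0
#' by construction (the outline converges there), closing the solid for
#' the volume and surface integration.
#'
#' Missing widths (no crossing within `probe_half` on a side) are linearly
#' interpolated from their neighbours; if more than `max_missing_frac` of
#' the interior points are missing the measurement fails.
#'
#' @param path an extended [spine_path].
#' @param edge outline raster from [outline].
#' @param probe_half probe half-length in px; must exceed the worm's
#'   maximum radius ("slightly longer" than the tracing profile).
#' @param max_missing_frac tolerated fraction of interpolated widths.
#' @param edge_offset sub-pixel correction, px, added outward at each
#'   crossing: the one-pixel outline is made of foreground pixels, whose
#'   centres sit half a pixel inside the worm's continuous boundary, so
#'   the default 0.5 places the measured edge on the boundary itself
#'   (without it every diameter is biased ~1 px low).
#' @return a `width_profile`: list with `s_px`, `width_px`, physical `s`
#'   and `width`, `edge_left`, `edge_right`, `missing`, `scale`.
#' @export
measure_widths <- function(path, edge, probe_half = 30,
                           max_missing_frac = 0.05, edge_offset = 0.5) {
  if (!isTRUE(path$extended))
    stop("measure_widths needs an extended spine path (see extend_ends)")
  pts <- path$points
  phi <- path$tangent_angle
  n <- nrow(pts)
  interior_idx <- if (n > 2L) 2:(n - 1L) else integer(0)
  # one batched bilinear evaluation for every probe sample of every ray:
  # rays are the two half-normals (left +, right -) at each interior point
  nvx <- cos(phi[interior_idx] + pi / 2)
  nvy <- sin(phi[interior_idx] + pi / 2)
  tt <- seq(0.25, probe_half, by = 0.25)
  nt <- length(tt)
  cx <- c(pts[interior_idx, 1], pts[interior_idx, 1])
  cy <- c(pts[interior_idx, 2], pts[interior_idx, 2])
  dxs <- c(nvx, -nvx); dys <- c(nvy, -nvy)
  nray <- length(cx)
  X <- rep(cx, each = nt) + tt * rep(dxs, each = nt)
  Y <- rep(cy, each = nt) + tt * rep(dys, each = nt)
  V <- matrix(bilinear_sample(edge + 0, X, Y), nt, nray)
  tcross <- first_run_centroid(V, tt)
  tL <- tcross[seq_along(interior_idx)]
  tR <- tcross[seq_along(interior_idx) + length(interior_idx)]

  width_px <- numeric(n)
  eL <- matrix(NA_real_, n, 2L)
  eR <- matrix(NA_real_, n, 2L)
  missing <- logical(n)
  width_px[c(1L, n)] <- 0                  # tips: width 0 by construction
  eL[1L, ] <- eR[1L, ] <- pts[1L, ]
  eL[n, ] <- eR[n, ] <- pts[n, ]
  bad <- is.na(tL) | is.na(tR)
  missing[interior_idx] <- bad
  okL <- tL + edge_offset; okR <- tR + edge_offset
  width_px[interior_idx] <- okL + okR
  eL[interior_idx, ] <- pts[interior_idx, ] + okL * cbind(nvx, nvy)
  eR[interior_idx, ] <- pts[interior_idx, ] - okR * cbind(nvx, nvy)
  interior <- n - 2L
  if (sum(missing) > max_missing_frac * interior)
    stop("radii failure: ", sum(missing), " of ", interior,
         " widths missing (> ", 100 * max_missing_frac, "%)")
  if (any(missing))
    width_px[missing] <- stats::approx(path$arc_length[!missing],
                                       width_px[!missing],
                                       xout = path$arc_length[missing],
                                       rule = 2)$y
  structure(list(s_px = path$arc_length, width_px = width_px,
                 s = path$arc_length * path$scale,
                 width = width_px * path$scale,
                 edge_left = eL, edge_right = eR,
                 missing = missing, scale = path$scale),
            class = "width_profile")
}

#' @export
print.width_profile <- function(x, ...) {
  cat(sprintf(
    "<width_profile> %d samples over %.4g units; max width %.4g units (%d interpolated)\n",
    length(x$s), max(x$s), max(x$width), sum(x$missing)))
  invisible(x)
}

#' Convert a width profile to a series of truncated cones
#'
#' Each consecutive pair of width samples defines one frustum: radii are
#' the half-widths at the two faces and the height is the arc-length
#' spacing, all in physical units via the calibration scale.
#'
#' @param wp a `width_profile` from [measure_widths].
#' @return data.frame with columns `r1`, `r2`, `h` (one row per frustum).
#' @export
to_frustum_series <- function(wp) {
  n <- length(wp$s)
  if (n < 2L) stop("need at least 2 width samples")
  if (any(diff(wp$s) <= 0)) stop("arc-length positions must be increasing")
  data.frame(r1 = wp$width[-n] / 2,
             r2 = wp$width[-1L] / 2,
             h  = diff(wp$s))
}

#' Write the per-worm position/width table
#'
#' Two tab-separated columns, position along the worm and width at that
#' point, in physical units (the units are stated in the header; the
#' header can be dropped for drop-in compatibility with headerless
#' consumers).
#'
#' @param wp a `width_profile`.
#' @param path output text file.
#' @param units unit label for the header.
#' @param header include the header row?
#' @return `path`, invisibly.
#' @export
write_width_table <- function(wp, path, units = "mm", header = TRUE) {
  lines <- sprintf("%.3f\t%.3f", wp$s, wp$width)
  if (header)
    lines <- c(sprintf("Position (%s)\tWidth (%s)", units, units), lines)
  writeLines(lines, path)
  invisible(path)
}
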