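#' Volume of a truncated cone
#'
#' \deqn{V = \frac{1}{3}\pi (r_1^2 + r_1 r_2 + r_2^2) h}
#' With \eqn{r_1 = r_2 = r} this reduces to the cylinder \eqn{\pi r^2 h};
#' with \eqn{r_2 = 0} to the cone \eqn{\frac{1}{3}\pi r_1^2 h}.
#' Vectorized over its arguments.
#'
#' @param r1,r2 radii at the two faces (>= 0).
#' @param h axial height (> 0).
#' @return volume, in `units(r)^3`.
#' @export
frustum_volume <- function(r1, r2, h) {
  stopifnot(all(r1 >= 0), all(r2 >= 0), all(h > 0))
  pi / 3 * (r1^2 + r1 * r2 + r2^2) * h
}

#' Lateral surface area of a truncated cone
#'
#' \deqn{S = \pi (r_1 + r_2) \sqrt{(r_1 - r_2)^2 + h^2}}
#' i.e. \eqn{\pi (r_1 + r_2) \ell} with \eqn{\ell} the slant length.  With
#' \eqn{r_1 = r_2 = r} this is the open cylinder \eqn{2\pi r h}.
#'
#' @inheritParams frustum_volume
#' @param h axial height (>= 0 allowed here; h = 0 gives the flat annulus
#'   limit).
#' @return lateral area, in `units(r)^2`.
#' @export
frustum_lateral_area <- function(r1, r2, h) {
  stopifnot(all(r1 >= 0), all(r2 >= 0), all(h >= 0))
  pi * (r1 + r2) * sqrt((r1 - r2)^2 + h^2)
}

#' Length, volume and surface area of a measured worm
#'
#' Length is the arc length of the extended spine; volume and surface
#' area come from summing [frustum_volume] and [frustum_lateral_area] over
#' the truncated-cone series of the width profile.  All values are in
#' physical units via the calibration scale (length scales linearly with
#' the scale, area quadratically, volume cubically).
#'
#' @param wp a `width_profile`.
#' @param spine the matching extended [spine_path].
#' @param worm_id identifier recorded in the result (e.g. file name).
#' @param with_curvature also compute the per-point curvature series.
#' @return a `morphometrics` object: list with `length`, `volume`,
#'   `surface_area`, optional `curvature`, `n_samples`, `worm_id`.
#' @export
total_morphometrics <- function(wp, spine, worm_id = NA_character_,
                                with_curvature = FALSE) {
  if (!isTRUE(all.equal(wp$s_px, spine$arc_length)))
    stop("width profile and spine path do not match")
  fr <- to_frustum_series(wp)
  len <- spine_length(spine)
  vol <- sum(frustum_volume(fr$r1, fr$r2, fr$h))
  area <- sum(frustum_lateral_area(fr$r1, fr$r2, fr$h))
  stopifnot(len > 0, vol > 0, area > 0)
  res <- list(length = len, volume = vol, surface_area = area,
              n_samples = length(wp$s), worm_id = worm_id)
  if (with_curvature) res$curvature <- curvature(spine)
  structure(res, class = "morphometrics")
}

#' @export
print.morphometrics <- function(x, ...) {
  cat(sprintf("<morphometrics> %s\n  length %.3f, volume %.5f, surface area %.4f\n",
              if (is.na(x$worm_id)) "" else x$worm_id,
              x$length, x$volume, x$surface_area))
  invisible(x)
}

#' Curvature along the spine
#'
#' \eqn{k = d\phi/ds}: the change of the midline's (unwrapped) tangent
#' angle per unit arc length, computed by central differences in the
#' interior and one-sided differences at the ends.  Units are radians per
#' physical length unit.
#'
#' @param spine a [spine_path] with at least 3 points.
#' @param smooth_sd optional Gaussian smoothing of the tangent-angle
#'   series before differencing, in samples (0 = off, the default; no
#'   hidden smoothing).
#' @return numeric vector of k, one per spine point.
#' @export
curvature <- function(spine, smooth_sd = 0) {
  phi <- spine$tangent_angle
  s <- spine$arc_length * spine$scale
  n <- length(phi)
  if (n < 3L) stop("curvature needs at least 3 spine points")
  if (smooth_sd > 0) {
    half <- ceiling(3 * smooth_sd)
    kern <- stats::dnorm(-half:half, sd = smooth_sd)
    kern <- kern / sum(kern)
    padded <- c(rep(phi[1], half), phi, rep(phi[n], half))
    phi <- stats::filter(padded, kern, sides = 2)[(half + 1L):(half + n)]
  }
  k <- numeric(n)
  k[2:(n - 1L)] <- (phi[3:n] - phi[1:(n - 2L)]) / (s[3:n] - s[1:(n - 2L)])
  k[1] <- (phi[2] - phi[1]) / (s[2] - s[1])
  k[n] <- (phi[n] - phi[n - 1L]) / (s[n] - s[n - 1L])
  k
}

#' Straightened silhouette of the worm
#'
#' Rebuilds the worm's silhouette on a straight horizontal axis from the
#' (arc position, width) pairs: column `j` of the output corresponds to
#' arc position `s = j` px and a pixel is foreground iff its distance from
#' the central row is at most half the local width.  This is silhouette
#' reconstruction from the width profile, not image resampling, so the
#' result is symmetric about its axis.
#'
#' @param wp a `width_profile`.
#' @param margin extra rows above and below the widest point.
#' @return logical matrix (the straightened binary silhouette).
#' @export
straighten <- function(wp, margin = 4L) {
  len <- max(wp$s_px)
  w_max <- max(wp$width_px)
  ncols <- max(1L, ceiling(len))
  half <- ceiling(w_max / 2) + margin
  nrows <- 2L * half + 1L
  xs <- seq_len(ncols) - 0.5
  wcol <- stats::approx(wp$s_px, wp$width_px, xout = pmin(xs, len), rule = 2)$y
  rows <- seq_len(nrows)
  ctr <- half + 1L
  outer(rows, seq_len(ncols),
        function(r, j) wcol[j] > 0 & abs(r - ctr) <= wcol[j] / 2)
}
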