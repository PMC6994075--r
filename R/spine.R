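#' Ordered sub-pixel path along the worm's midline
#'
#' Holds the traced spine points (columns `x`, `y`, sub-pixel, pixel
#' units), the per-point unwrapped tangent angle `phi` (radians) and the
#' cumulative arc length `s` (pixels).  `extended` records whether the
#' path has been extended to the worm's true tips.
#'
#' @param points numeric n x 2 matrix of (x, y) positions.
#' @param scale physical length per pixel.
#' @param extended logical flag.
#' @return an object of class \code{spine_path}.
#' @export
spine_path <- function(points, scale = 1, extended = FALSE) {
  stopifnot(is.matrix(points), ncol(points) == 2L, nrow(points) >= 2L)
  d <- diff(points)
  seg <- sqrt(rowSums(d^2))
  if (any(seg <= 0)) stop("coincident consecutive spine points")
  s <- c(0, cumsum(seg))
  # tangent angle: central differences in the interior, one-sided at ends
  n <- nrow(points)
  dx <- c(d[1, 1], points[-(1:2), 1] - points[seq_len(n - 2L), 1], d[n - 1L, 1])
  dy <- c(d[1, 2], points[-(1:2), 2] - points[seq_len(n - 2L), 2], d[n - 1L, 2])
  phi <- unwrap_angles(atan2(dy, dx))
  structure(list(points = points, tangent_angle = phi, arc_length = s,
                 scale = scale, extended = extended),
            class = "spine_path")
}

#' @export
print.spine_path <- function(x, ...) {
  cat(sprintf("<spine_path> %d points, arc length %.1f px (%.4g units)%s\n",
              nrow(x$points), max(x$arc_length), max(x$arc_length) * x$scale,
              if (x$extended) ", extended to tips" else ""))
  invisible(x)
}

#' Total arc length of a spine path
#' @param path a [spine_path].
#' @param physical if TRUE (default) return physical units, else pixels.
#' @return scalar length.
#' @export
spine_length <- function(path, physical = TRUE) {
  max(path$arc_length) * if (physical) path$scale else 1
}

unwrap_angles <- function(phi) {
  d <- diff(phi)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(phi[1], d))
}

#' Sample a straight profile line through a raster
#'
#' Draws a line of `2 * half_length + 1` samples at unit spacing centred on
#' `center` with direction `angle`, reading the raster by bilinear
#' interpolation (0 outside the image).
#'
#' @param raster numeric or logical matrix.
#' @param center length-2 (x, y).
#' @param angle direction in radians.
#' @param half_length half the line length, pixels.
#' @return list with `t` (signed offsets) and `samples`.
#' @export
profile_line <- function(raster, center, angle, half_length = 20) {
  t <- seq(-half_length, half_length, by = 1)
  x <- center[1] + t * cos(angle)
  y <- center[2] + t * sin(angle)
  list(center = center, angle = angle, t = t,
       samples = bilinear_sample(raster + 0, x, y))
}

# Group above-threshold samples of a profile into clusters (runs separated
# by > gap below-threshold samples); returns per-cluster weighted centroid
# offset and weight.
profile_clusters <- function(t, samples, threshold = 0.2, gap = 2L) {
  above <- samples > threshold
  if (!any(above)) return(NULL)
  idx <- which(above)
  brk <- c(0L, which(diff(idx) > gap + 1L), length(idx))
  out <- lapply(seq_len(length(brk) - 1L), function(k) {
    ii <- idx[(brk[k] + 1L):brk[k + 1L]]
    w <- samples[ii]
    c(t = sum(t[ii] * w) / sum(w), weight = sum(w))
  })
  do.call(rbind, out)
}

first_run_center <- function(rows) {
  # topmost run of consecutive indices
  brk <- which(diff(rows) > 1L)
  last <- if (length(brk)) brk[1L] else length(rows)
  mean(rows[1:last])
}

#' Find a starting point and slope on the spine line
#'
#' Samples a vertical line through the horizontal centre of the image; the
#' first (topmost) skeleton crossing gives a point on the spine line.  A
#' second vertical line a few pixels to the right gives a second point
#' (the crossing nearest in row to the first), from which the local slope
#' follows.  If the centre column misses the skeleton, neighbouring
#' columns are scanned outwards.
#'
#' @param skeleton logical matrix from [skeletonize].
#' @param dx column offset of the second vertical line (default 5 px).
#' @return list with `point` (x, y), `slope` and `angle` (radians).
#' @export
find_start <- function(skeleton, dx = 5L) {
  h <- nrow(skeleton); w <- ncol(skeleton)
  cx0 <- as.integer(round(w / 2))
  col1 <- NA_integer_
  for (off in 0:(w - 1L)) {
    for (sgn in if (off == 0L) 1L else c(1L, -1L)) {
      cc <- cx0 + sgn * off
      if (cc >= 1L && cc <= w && any(skeleton[, cc])) { col1 <- cc; break }
    }
    if (!is.na(col1)) break
  }
  if (is.na(col1)) stop("skeleton not crossed by any vertical line")
  y1 <- first_run_center(which(skeleton[, col1]))
  col2 <- if (col1 + dx <= w && any(skeleton[, col1 + dx])) col1 + dx
          else if (col1 - dx >= 1L && any(skeleton[, col1 - dx])) col1 - dx
          else stop("second vertical line misses the skeleton")
  rows2 <- which(skeleton[, col2])
  brk <- c(0L, which(diff(rows2) > 1L), length(rows2))
  centers2 <- vapply(seq_len(length(brk) - 1L), function(k)
    mean(rows2[(brk[k] + 1L):brk[k + 1L]]), numeric(1))
  y2 <- centers2[which.min(abs(centers2 - y1))]
  slope <- (y2 - y1) / (col2 - col1)
  list(point = c(x = col1, y = y1), slope = slope,
       angle = atan2(y2 - y1, col2 - col1))
}

#' Trace the spine line in one direction with moving perpendicular profiles
#'
#' From a seed point on the skeleton, repeatedly advances `step` pixels
#' along the current tangent, re-centres on the skeleton by taking the
#' (weighted) maximum of a short profile line drawn perpendicular to the
#' tangent, and updates the tangent from the last two centres.  Tracing
#' stops when the perpendicular profile no longer meets the skeleton (the
#' end of the spine line).  If the profile meets the skeleton in two
#' clusters closer than `min_clearance`, the worm's midline is too close
#' to another part of itself and tracing aborts: perpendicular profiles
#' become ambiguous when parts of the spine approach within about 20 px.
#'
#' @param skeleton logical matrix.
#' @param seed (x, y) on the skeleton.
#' @param seed_angle initial tangent angle, radians.
#' @param direction +1 to follow `seed_angle`, -1 for the opposite way.
#' @param step advance per iteration, pixels ("a few pixels").
#' @param profile_half half-length of the perpendicular profile (the
#'   profile is about 40 px long in total).
#' @param min_clearance two skeleton crossings closer than this raise the
#'   self-proximity error (unless they are also close *along* the chain,
#'   which happens harmlessly where the skeleton tip hooks back on itself).
#' @return n x 2 matrix of ordered sub-pixel centres, starting at `seed`.
#' @export
trace_from <- function(skeleton, seed, seed_angle, direction = 1,
                       step = 4, profile_half = 20, min_clearance = 20) {
  h <- nrow(skeleton); w <- ncol(skeleton)
  chain_d <- NULL   # geodesic arc position of every skeleton pixel, lazy
  arc_pos <- function(p) {
    if (is.null(chain_d)) {
      nc <- neighbour_count(skeleton)
      ep <- which(skeleton & nc == 1L)
      seed_px <- if (length(ep)) ep[1L] else which(skeleton)[1L]
      chain_d <<- skel_bfs(skeleton, seed_px)$dist
    }
    rr <- round(p[2]); cc <- round(p[1])
    best <- NA_integer_; best_d2 <- Inf
    for (dr in -3:3) for (dc in -3:3) {
      r2 <- rr + dr; c2 <- cc + dc
      if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w && skeleton[r2, c2]) {
        d2 <- (r2 - p[2])^2 + (c2 - p[1])^2
        if (d2 < best_d2) { best_d2 <- d2; best <- chain_d[(c2 - 1L) * h + r2] }
      }
    }
    best
  }
  ang <- if (direction >= 0) seed_angle else seed_angle + pi
  pos <- as.numeric(seed[1:2])
  pts <- matrix(pos, 1L, 2L)
  max_iter <- ceiling(2 * (h + w) / step) + 50L
  for (i in seq_len(max_iter)) {
    pred <- pos + step * c(cos(ang), sin(ang))
    pr <- profile_line(skeleton, pred, ang + pi / 2, profile_half)
    cl <- profile_clusters(pr$t, pr$samples)
    if (is.null(cl)) break                       # end of the spine line
    pick <- which.min(abs(cl[, "t"]))
    nvec <- c(cos(ang + pi / 2), sin(ang + pi / 2))
    if (nrow(cl) > 1L) {
      others <- cl[-pick, , drop = FALSE]
      sep <- abs(others[, "t"] - cl[pick, "t"])
      for (j in which(sep < min_clearance)) {
        # close in space: a genuine failure only if the two crossings are
        # far apart along the skeleton chain (distinct body parts); the
        # skeleton's own tip can hook back within a few pixels of itself
        a1 <- arc_pos(pred + cl[pick, "t"] * nvec)
        a2 <- arc_pos(pred + others[j, "t"] * nvec)
        if (is.na(a1) || is.na(a2) ||
            abs(a1 - a2) > max(40, 2.5 * sep[j]))
          stop("spine self-proximity: midline parts closer than ",
               min_clearance, " px; cannot trace this worm")
      }
    }
    tt <- cl[pick, "t"]
    new <- pred + tt * nvec
    if (sum((new - pos) * c(cos(ang), sin(ang))) <= step * 0.05) break
    new_ang <- atan2(new[2] - pos[2], new[1] - pos[1])
    d_ang <- abs(atan2(sin(new_ang - ang), cos(new_ang - ang)))
    if (d_ang > pi / 3) break   # no worm bends this fast in one step: the
                                # trace has run off the spine's end
    pts <- rbind(pts, new)
    ang <- new_ang
    pos <- new
  }
  unname(pts)
}

#' Trace the full spine line end to end
#'
#' Finds a seed with [find_start], traces forward and backward with
#' [trace_from] and concatenates the two half-traces (reversing the
#' backward one) into a single ordered [spine_path].
#'
#' @inheritParams trace_from
#' @param scale physical length per pixel carried into the path.
#' @return a [spine_path] (not yet extended to the worm's tips).
#' @export
trace_full <- function(skeleton, step = 4, profile_half = 20,
                       min_clearance = 20, scale = 1) {
  st <- find_start(skeleton)
  fwd <- trace_from(skeleton, st$point, st$angle, +1,
                    step, profile_half, min_clearance)
  bwd <- trace_from(skeleton, st$point, st$angle, -1,
                    step, profile_half, min_clearance)
  pts <- rbind(bwd[rev(seq_len(nrow(bwd)))[-nrow(bwd)], , drop = FALSE], fwd)
  if (nrow(pts) < 3L) stop("spine trace too short")
  spine_path(pts, scale = scale, extended = FALSE)
}

#' One-pixel outline of the worm mask
#'
#' The boundary: every foreground pixel with at least one 4-connected
#' background neighbour.  For a filled shape this is a closed one-pixel
#' curve (the `edge` image used for end extension and width measurement).
#'
#' @param mask a [worm_mask].
#' @return logical matrix, TRUE exactly on the boundary.
#' @export
outline <- function(mask) {
  px <- mask$pixels
  inner <- px & shift_mat(px, -1, 0) & shift_mat(px, 1, 0) &
                shift_mat(px, 0, -1) & shift_mat(px, 0, 1)
  px & !inner
}

# Least-squares direction of a small point cloud, oriented along `ref`
principal_direction <- function(pts, ref) {
  ctr <- colMeans(pts)
  m <- sweep(pts, 2L, ctr)
  sv <- svd(m, nu = 0L, nv = 2L)
  v <- sv$v[, 1L]
  if (sum(v * ref) < 0) v <- -v
  v
}

# First crossing of `raster` along a ray from `origin` in direction `dir`
# (unit vector); returns the signed distance, or NA if none within reach.
ray_first_crossing <- function(raster, origin, dir, reach,
                               spacing = 0.25, threshold = 0.2) {
  # t = 0 included: an origin already sitting on the outline crosses at
  # (essentially) zero distance rather than failing
  t <- seq(0, reach, by = spacing)
  v <- bilinear_sample(raster + 0, origin[1] + t * dir[1],
                       origin[2] + t * dir[2])
  above <- v > threshold
  if (!any(above)) return(NA_real_)
  first <- which(above)[1L]
  run <- first
  while (run < length(v) && above[run + 1L]) run <- run + 1L
  ii <- first:run
  sum(t[ii] * v[ii]) / sum(v[ii])
}

#' Extend the spine line to the worm's true endpoints
#'
#' Thinning erodes the skeleton short of the worm's tips.  At each end of
#' the traced path the terminal slope is estimated from the last `k`
#' points (least squares) and a ray is cast outward until it first crosses
#' the one-pixel outline of the complete worm; the crossing point is
#' appended, so the total arc length includes the two extra tip lengths.
#'
#' @param path an unextended [spine_path].
#' @param edge outline raster from [outline].
#' @param k number of terminal points used for the slope estimate.
#' @param max_reach give up ("end extension failed") beyond this many px.
#' @param edge_offset sub-pixel correction added beyond the outline
#'   crossing: outline pixel centres sit half a pixel inside the worm's
#'   continuous boundary (see [measure_widths]).
#' @return the extended [spine_path] (`extended = TRUE`).
#' @export
extend_ends <- function(path, edge, k = 5L, max_reach = 60, edge_offset = 0.5) {
  if (isTRUE(path$extended)) stop("path is already extended")
  pts <- path$points
  n <- nrow(pts)
  k <- min(k, n - 1L)
  ext_one <- function(tail_idx, prev_idx) {
    p_end <- pts[tail_idx[length(tail_idx)], ]
    dir <- principal_direction(pts[tail_idx, , drop = FALSE],
                               ref = p_end - pts[prev_idx, ])
    t <- ray_first_crossing(edge, p_end, dir, max_reach)
    if (is.na(t)) stop("end extension failed: ray misses the outline")
    p_end + (t + edge_offset) * dir
  }
  tip_hi <- ext_one((n - k + 1L):n, n - 1L)
  tip_lo <- ext_one(k:1, 2L)
  spine_path(rbind(tip_lo, pts, tip_hi), scale = path$scale, extended = TRUE)
}
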