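# Vectorized binary raster primitives.  Masks are logical matrices indexed
# [row, col]; point coordinates elsewhere are (x = col, y = row), 1-based,
# sub-pixel positions real-valued at pixel centres.

shift_mat <- function(m, dr, dc, fill = FALSE) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1L, 1L + dr):min(h, h + dr)
  cs <- max(1L, 1L + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# 3x3 (8-connected) structuring element, `iters` passes
dilate3 <- function(m, iters = 1L) {
  for (i in seq_len(iters)) {
    out <- m
    for (dr in -1:1) for (dc in -1:1)
      if (dr || dc) out <- out | shift_mat(m, dr, dc)
    m <- out
  }
  m
}

erode3 <- function(m, iters = 1L) {
  for (i in seq_len(iters)) {
    out <- m
    for (dr in -1:1) for (dc in -1:1)
      if (dr || dc) out <- out & shift_mat(m, dr, dc, fill = FALSE)
    m <- out
  }
  m
}

# Neighbour index offsets for a h x w matrix in column-major order
neighbour_steps <- function(connectivity = 8L) {
  if (connectivity == 4L) rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  else as.matrix(expand.grid(dr = -1:1, dc = -1:1))[-5L, , drop = FALSE]
}

# Frontier BFS growing `seeds` (linear indices) inside `allowed` (logical
# matrix).  Returns logical matrix of reached pixels.
flood_from <- function(allowed, seeds, connectivity = 8L) {
  h <- nrow(allowed); w <- ncol(allowed)
  steps <- neighbour_steps(connectivity)
  reached <- logical(h * w)
  seeds <- seeds[allowed[seeds]]
  reached[seeds] <- TRUE
  frontier <- seeds
  while (length(frontier)) {
    r <- (frontier - 1L) %% h + 1L
    c <- (frontier - 1L) %/% h + 1L
    nxt <- integer(0)
    for (k in seq_len(nrow(steps))) {
      rr <- r + steps[k, 1L]; cc <- c + steps[k, 2L]
      ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
      idx <- (cc[ok] - 1L) * h + rr[ok]
      idx <- idx[allowed[idx] & !reached[idx]]
      if (length(idx)) { reached[idx] <- TRUE; nxt <- c(nxt, idx) }
    }
    frontier <- unique(nxt)
  }
  matrix(reached, h, w)
}

# Connected-component labelling by repeated BFS.  Returns labels (integer
# matrix, 0 = background), n, sizes.
label_components <- function(px, connectivity = 8L) {
  h <- nrow(px); w <- ncol(px)
  labels <- matrix(0L, h, w)
  remaining <- px
  n <- 0L
  sizes <- integer(0)
  repeat {
    seed <- which(remaining)
    if (!length(seed)) break
    n <- n + 1L
    comp <- flood_from(remaining, seed[1L], connectivity)
    labels[comp] <- n
    sizes[n] <- sum(comp)
    remaining <- remaining & !comp
  }
  list(labels = labels, n = n, sizes = sizes)
}

# Background connected to the image border (4-connectivity, the complement
# convention for 8-connected foreground)
border_background <- function(px) {
  h <- nrow(px); w <- ncol(px)
  border <- c(seq_len(h), (w - 1L) * h + seq_len(h),
              (seq_len(w) - 1L) * h + 1L, (seq_len(w) - 1L) * h + h)
  flood_from(!px, unique(border), connectivity = 4L)
}

# Bilinear interpolation of matrix m at (x = col, y = row); outside -> 0
bilinear_sample <- function(m, x, y) {
  h <- nrow(m); w <- ncol(m)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0;   fy <- y - y0
  val <- function(yy, xx) {
    ok <- xx >= 1 & xx <= w & yy >= 1 & yy <= h
    v <- numeric(length(xx))
    v[ok] <- m[cbind(yy[ok], xx[ok])]
    v
  }
  val(y0,      x0)      * (1 - fx) * (1 - fy) +
  val(y0,      x0 + 1)  * fx       * (1 - fy) +
  val(y0 + 1,  x0)      * (1 - fx) * fy       +
  val(y0 + 1,  x0 + 1)  * fx       * fy
}

# Rotate a logical mask by `theta` radians (counter-clockwise in standard
# x-right/y-up terms; y runs down here so visually clockwise) about the
# image centre, bilinear + 0.5 re-threshold.
rotate_mask_raster <- function(px, theta) {
  h <- nrow(px); w <- ncol(px)
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  xx <- matrix(rep(seq_len(w), each = h), h, w)
  yy <- matrix(rep(seq_len(h), times = w), h, w)
  ct <- cos(theta); st <- sin(theta)
  xs <- cx + ct * (xx - cx) - st * (yy - cy)
  ys <- cy + st * (xx - cx) + ct * (yy - cy)
  v <- bilinear_sample(px + 0, as.vector(xs), as.vector(ys))
  matrix(v >= 0.5, h, w)
}

pad_raster <- function(px, pad, fill = FALSE) {
  h <- nrow(px); w <- ncol(px)
  out <- matrix(fill, h + 2L * pad, w + 2L * pad)
  out[pad + seq_len(h), pad + seq_len(w)] <- px
  out
}

fg_bbox <- function(px) {
  idx <- which(px, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty mask")
  c(rmin = min(idx[, 1]), rmax = max(idx[, 1]),
    cmin = min(idx[, 2]), cmax = max(idx[, 2]))
}
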