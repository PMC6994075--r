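# Synthetic worms: binary renders of parametric tubes with analytic ground
# truth.  A worm is a centerline p(s) (arc-length parameterized) swept by a
# radius profile r(s); length, volume (solid of revolution along the arc),
# lateral surface area and curvature are all computed at construction time
# by high-resolution quadrature, independently of any raster, so they serve
# as the oracle for the measurement pipeline.

#' Specify a synthetic worm
#'
#' Centerline families: `"straight"`, `"arc"` (circular, constant
#' curvature), `"sine"` (sinusoidal undulation, the typical crawling
#' posture) and `"hairpin"` (two parallel limbs joined by a U-turn; with a
#' small `gap` this is the adversarial self-proximity fixture).  The radius
#' profile is constant or linear along the body and always tapers
#' quadratically to zero over the final `taper_frac` of arc length at both
#' tips, so the ground-truth volume and area include the closed tips
#' analytically.  Defaults emulate an adult C. elegans imaged at ~1 px/um:
#' about 1000 px (1 mm) long and 50 px (50 um) in diameter, a 20:1
#' length-to-diameter ratio.
#'
#' @param centerline one of `"straight"`, `"arc"`, `"sine"`, `"hairpin"`.
#' @param length_px target centerline arc length in pixels.
#' @param radius_px body radius in pixels (max radius for linear profiles).
#' @param radius_profile `"constant"` or `"linear"`.
#' @param radius_end_px far-end radius for the linear profile.
#' @param amplitude_px,periods sine parameters (peak amplitude, cycles).
#' @param arc_radius_px radius of curvature for the `"arc"` family.
#' @param gap_px centre-to-centre limb separation for `"hairpin"`.
#' @param taper_frac fraction of arc length over which each tip tapers.
#' @param noise_sd boundary jitter: per-vertex Gaussian displacement along
#'   the outward normal, standard deviation in px (default 0.5, emulating
#'   focus/threshold variability).
#' @param rotation_deg rotation applied to the rendered worm.
#' @param seed RNG seed for the jitter (renders are deterministic given
#'   the spec).
#' @param scale physical length per pixel for the emitted mask.
#' @param pad_px canvas margin around the rendered worm.
#' @param allow_self_proximity permit specs whose limbs come closer than
#'   one body width (needed to build failure fixtures).
#' @return a `worm_spec` with element `truth` (see Details).
#' @details `truth` holds `length_px`, `length`, `volume`, `surface_area`
#'   (physical units), `kappa` (curvature vs arc length, signed, in 1/px
#'   on `s_grid`), and `max_radius_px`.
#' @export
worm_spec <- function(centerline = c("sine", "straight", "arc", "hairpin"),
                      length_px = 1000, radius_px = 25,
                      radius_profile = c("constant", "linear"),
                      radius_end_px = radius_px / 2,
                      amplitude_px = 60, periods = 1.5,
                      arc_radius_px = length_px / 2,
                      gap_px = 100, taper_frac = 0.05,
                      noise_sd = 0.5, rotation_deg = 0, seed = 1L,
                      scale = 1, pad_px = 60L,
                      allow_self_proximity = FALSE) {
  centerline <- match.arg(centerline)
  radius_profile <- match.arg(radius_profile)
  stopifnot(length_px > 0, radius_px >= 3, taper_frac > 0, taper_frac < 0.5)

  # dense parametric sample of the centerline (not yet arc-length spaced)
  m <- 8192L
  u <- seq(0, 1, length.out = m)
  xy <- switch(centerline,
    straight = cbind(u * length_px, 0 * u),
    arc = {
      th <- length_px / arc_radius_px
      cbind(arc_radius_px * sin(th * u), arc_radius_px * (1 - cos(th * u)))
    },
    sine = {
      # choose the x-span so the curve's arc length hits length_px
      omega <- 2 * pi * periods
      arclen_of <- function(span) {
        t <- u * span
        sum(sqrt(1 + (amplitude_px * omega / span * cos(omega * t / span))^2)) *
          span / m
      }
      span <- stats::uniroot(function(sp) arclen_of(sp) - length_px,
                             c(length_px / 4, length_px))$root
      t <- u * span
      cbind(t, amplitude_px * sin(omega * t / span))
    },
    hairpin = {
      turn <- pi * gap_px / 2
      limb <- (length_px - turn) / 2
      if (limb <= 0) stop("hairpin gap too large for the requested length")
      s <- u * length_px
      x <- numeric(m); y <- numeric(m)
      i1 <- s <= limb
      x[i1] <- s[i1]; y[i1] <- 0
      i2 <- s > limb & s <= limb + turn
      a <- (s[i2] - limb) / (gap_px / 2)          # 0..pi around the turn
      x[i2] <- limb + gap_px / 2 * sin(a)
      y[i2] <- gap_px / 2 * (1 - cos(a))
      i3 <- s > limb + turn
      x[i3] <- limb - (s[i3] - limb - turn); y[i3] <- gap_px
      cbind(x, y)
    })

  # arc-length reparameterization on the dense grid
  seg <- sqrt(rowSums(diff(xy)^2))
  s_grid <- c(0, cumsum(seg))
  L <- s_grid[m]
  fx <- stats::splinefun(s_grid, xy[, 1], method = "fmm")
  fy <- stats::splinefun(s_grid, xy[, 2], method = "fmm")

  base_r <- function(s) switch(radius_profile,
    constant = rep(radius_px, length(s)),
    linear = radius_px + (radius_end_px - radius_px) * s / L)
  tip <- function(s) {
    uu <- s / L
    f <- rep(1, length(s))
    lo <- uu < taper_frac
    hi <- uu > 1 - taper_frac
    f[lo] <- 1 - ((taper_frac - uu[lo]) / taper_frac)^2
    f[hi] <- 1 - ((uu[hi] - (1 - taper_frac)) / taper_frac)^2
    pmax(f, 0)
  }
  radius_fn <- function(s) base_r(s) * tip(s)

  # ground truth by composite quadrature at high resolution
  nq <- 20001L
  sq <- seq(0, L, length.out = nq)
  rq <- radius_fn(sq)
  ds <- L / (nq - 1L)
  drds <- c(diff(rq[1:2]) / ds,
            (rq[3:nq] - rq[1:(nq - 2L)]) / (2 * ds),
            diff(rq[(nq - 1L):nq]) / ds)
  vol_px <- sum(pi * rq^2) * ds - pi / 2 * (rq[1]^2 + rq[nq]^2) * ds
  area_px <- trapz_weighted(2 * pi * rq * sqrt(1 + drds^2), ds)
  dxq <- fx(sq, deriv = 1); dyq <- fy(sq, deriv = 1)
  d2xq <- fx(sq, deriv = 2); d2yq <- fy(sq, deriv = 2)
  kappa <- (dxq * d2yq - dyq * d2xq) / (dxq^2 + dyq^2)^1.5

  max_r <- max(rq)
  if (!allow_self_proximity) check_clearance(fx, fy, L, max_r)

  spec <- list(centerline = centerline, length_px = L,
               radius_fn = radius_fn, fx = fx, fy = fy,
               taper_frac = taper_frac, noise_sd = noise_sd,
               rotation_deg = rotation_deg, seed = as.integer(seed),
               scale = scale, pad_px = as.integer(pad_px),
               truth = list(length_px = L, length = L * scale,
                            volume = vol_px * scale^3,
                            surface_area = area_px * scale^2,
                            s_grid = sq, kappa = kappa,
                            max_radius_px = max_r))
  class(spec) <- "worm_spec"
  spec
}

trapz_weighted <- function(v, ds) (sum(v) - (v[1] + v[length(v)]) / 2) * ds

# Refuse centerlines whose distant parts come closer than one body width
check_clearance <- function(fx, fy, L, max_r, min_sep = NULL) {
  if (is.null(min_sep)) min_sep <- 2 * max_r + 2
  s <- seq(0, L, by = max(2, L / 2000))
  x <- fx(s); y <- fy(s)
  n <- length(s)
  win <- 3 * max_r          # ignore neighbours along the body
  for (i in seq_len(n)) {
    far <- abs(s - s[i]) > win
    if (!any(far)) next
    d2 <- (x[far] - x[i])^2 + (y[far] - y[i])^2
    if (min(d2) < min_sep^2)
      stop("spec self-intersects: limb clearance ", round(sqrt(min(d2)), 1),
           " px is below one body width (", round(min_sep, 1), " px)")
  }
  invisible(TRUE)
}

#' @export
print.worm_spec <- function(x, ...) {
  cat(sprintf(
    "<worm_spec> %s, L = %.1f px, max radius %.1f px, jitter sd %.2f px, rot %.1f deg\n",
    x$centerline, x$length_px, x$truth$max_radius_px, x$noise_sd,
    x$rotation_deg))
  cat(sprintf("  truth: length %.4g, volume %.4g, area %.4g (scale %g/px)\n",
              x$truth$length, x$truth$volume, x$truth$surface_area, x$scale))
  invisible(x)
}

# Even-odd scanline fill of a closed polygon; pixel centres at integers.
rasterize_polygon <- function(px_poly, h, w) {
  x <- px_poly[, 1]; y <- px_poly[, 2]
  n <- length(x)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  out <- matrix(FALSE, h, w)
  for (row in seq_len(h)) {
    yr <- row
    crosses <- (y < yr) != (y2 < yr)
    if (!any(crosses)) next
    xa <- x[crosses]; ya <- y[crosses]
    xb <- x2[crosses]; yb <- y2[crosses]
    xi <- sort(xa + (yr - ya) * (xb - xa) / (yb - ya))
    if (length(xi) %% 2L) xi <- xi[-length(xi)]   # tangency degeneracy
    if (length(xi) < 2L) next
    for (k in seq(1, length(xi) - 1, by = 2)) {
      c1 <- ceiling(xi[k]); c2 <- floor(xi[k + 1])
      if (c2 >= c1) out[row, max(1L, c1):min(w, c2)] <- TRUE
    }
  }
  out
}

#' Render a synthetic worm to a binary mask
#'
#' Rasterizes the tube swept by the radius profile along the centerline as
#' a filled polygon, after applying seeded per-vertex boundary jitter and
#' the spec's rotation, on a canvas padded by `pad_px`.  The render is
#' bit-deterministic given the spec (including its seed).
#'
#' @param spec a [worm_spec].
#' @return list with `mask` (a [worm_mask]) and `truth` (the spec's ground
#'   truth plus `tip1`/`tip2`, the rendered tip coordinates).
#' @export
render_worm <- function(spec) {
  L <- spec$length_px
  n <- max(200L, ceiling(L))           # ~1 px vertex spacing per side
  s <- seq(0, L, length.out = n)
  x <- spec$fx(s); y <- spec$fy(s)
  dx <- spec$fx(s, deriv = 1); dy <- spec$fy(s, deriv = 1)
  tl <- sqrt(dx^2 + dy^2)
  nx <- -dy / tl; ny <- dx / tl
  r <- spec$radius_fn(s)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(spec$seed)
  j_up <- stats::rnorm(n, 0, spec$noise_sd)
  j_dn <- stats::rnorm(n, 0, spec$noise_sd)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()) else
    rm(list = ".Random.seed", envir = globalenv())
  j_up[c(1, n)] <- 0; j_dn[c(1, n)] <- 0

  up <- cbind(x + nx * (r + j_up), y + ny * (r + j_up))
  dn <- cbind(x - nx * (r + j_dn), y - ny * (r + j_dn))
  poly <- rbind(up, dn[n:1, ])

  th <- spec$rotation_deg * pi / 180
  ctr <- colMeans(poly)
  rot <- cbind(cos(th) * (poly[, 1] - ctr[1]) - sin(th) * (poly[, 2] - ctr[2]),
               sin(th) * (poly[, 1] - ctr[1]) + cos(th) * (poly[, 2] - ctr[2]))
  tips <- rbind(c(x[1], y[1]), c(x[n], y[n]))
  tips <- cbind(cos(th) * (tips[, 1] - ctr[1]) - sin(th) * (tips[, 2] - ctr[2]),
                sin(th) * (tips[, 1] - ctr[1]) + cos(th) * (tips[, 2] - ctr[2]))

  pad <- spec$pad_px
  off <- c(pad + 1 - min(rot[, 1]), pad + 1 - min(rot[, 2]))
  rot <- sweep(rot, 2L, -off)
  tips <- sweep(tips, 2L, -off)
  w <- ceiling(max(rot[, 1])) + pad
  h <- ceiling(max(rot[, 2])) + pad
  px <- rasterize_polygon(rot, h, w)

  truth <- spec$truth
  truth$tip1 <- tips[1, ]; truth$tip2 <- tips[2, ]
  list(mask = worm_mask(px, spec$scale,
                        provenance = sprintf("synthetic:%s,seed=%d,rot=%.2f",
                                             spec$centerline, spec$seed,
                                             spec$rotation_deg)),
       truth = truth)
}

#' Re-render one worm many times under random pose
#'
#' Emulates re-imaging the same worm: `n` renders of one spec under
#' independent uniform rotations (0-360 degrees) and fresh boundary
#' jitter, deterministic given `(spec, n, seed)`.  All renders share the
#' spec's analytic ground truth.
#'
#' @param spec a [worm_spec].
#' @param n number of renders (the repeatability experiment used 18).
#' @param seed master seed; per-render rotations and jitter seeds derive
#'   from it.
#' @return list with `masks` (list of [worm_mask]), `rotations_deg`, and
#'   `truth`.
#' @export
replicate_experiment <- function(spec, n = 18L, seed = 1L) {
  stopifnot(n >= 2L)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  rots <- stats::runif(n, 0, 360)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()) else
    rm(list = ".Random.seed", envir = globalenv())
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    si <- spec
    si$rotation_deg <- rots[i]
    si$seed <- sub_seeds[i]
    masks[[i]] <- render_worm(si)$mask
  }
  list(masks = masks, rotations_deg = rots, truth = spec$truth)
}
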