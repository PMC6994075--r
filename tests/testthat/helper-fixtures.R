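# Fixtures are generated in code; unit tests use small worms (300-500 px)
# so the default run stays fast.  The synthetic module itself is the
# ground-truth oracle and is tested against closed-form geometry.

# Noise-free rendered tube plus its analytic truth
tube_fixture <- function(centerline = "straight", length_px = 400,
                         radius_px = 12, rotation_deg = 0, noise_sd = 0,
                         seed = 1L, scale = 1, ...) {
  spec <- worm_spec(centerline, length_px = length_px, radius_px = radius_px,
                    rotation_deg = rotation_deg, noise_sd = noise_sd,
                    seed = seed, scale = scale, ...)
  c(render_worm(spec), list(spec = spec))
}

# Solid rectangle mask (worm stand-in for geometry-level tests)
rect_mask <- function(h = 200, w = 300, rh = 20, rw = 160, scale = 1,
                      r0 = NULL, c0 = NULL) {
  px <- matrix(FALSE, h, w)
  if (is.null(r0)) r0 <- (h - rh) %/% 2
  if (is.null(c0)) c0 <- (w - rw) %/% 2
  px[r0 + seq_len(rh), c0 + seq_len(rw)] <- TRUE
  worm_mask(px, scale)
}

disk_mask <- function(r = 40, pad = 30, scale = 1) {
  n <- 2 * (r + pad)
  px <- (row(matrix(0, n, n)) - n / 2)^2 +
        (col(matrix(0, n, n)) - n / 2)^2 <= r^2
  worm_mask(px, scale)
}

# Two-level greyscale image with the worm dark on a bright field
grey_from_mask <- function(mask, fg = 0.2, bg = 0.85) {
  px <- matrix(bg, nrow(mask$pixels), ncol(mask$pixels))
  px[mask$pixels] <- fg
  worm_image(px, mask$scale)
}

rel_err <- function(x, ref) abs(x / ref - 1)
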