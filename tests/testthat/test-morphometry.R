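test_that("frustum volume matches its closed-form limits", {
  expect_equal(frustum_volume(0.3, 0.3, 2), pi * 0.3^2 * 2)     # cylinder
  expect_equal(frustum_volume(0.4, 0, 1.5), pi / 3 * 0.4^2 * 1.5) # cone
  # the printed cylindrical cross-check: 1.24 long, 0.1 wide
  expect_equal(round(frustum_volume(0.05, 0.05, 1.24), 4), 0.0097)
  expect_error(frustum_volume(-1, 1, 1))
})

test_that("frustum lateral area matches slant-length geometry", {
  expect_equal(frustum_lateral_area(0.3, 0.3, 2), 2 * pi * 0.3 * 2)
  expect_equal(frustum_lateral_area(1, 0, 0), pi)   # flat annulus limit
  # brute-force comparison with pi * r * slant for full cones on a grid
  for (r in c(0.2, 1, 3)) for (h in c(0, 0.5, 2, 10))
    expect_equal(frustum_lateral_area(r, 0, h), pi * r * sqrt(r^2 + h^2))
})

run_pipeline <- function(spec) {
  mask <- preprocess_mask(render_worm(spec)$mask)
  measure_worm(mask, with_curvature = TRUE)
}

test_that("total morphometrics agree with the analytic solid of revolution", {
  spec <- worm_spec("straight", length_px = 400, radius_px = 12,
                    noise_sd = 0, scale = 0.001)
  m <- run_pipeline(spec)$morphometrics
  expect_lt(rel_err(m$volume, spec$truth$volume), 0.03)
  expect_lt(rel_err(m$length, spec$truth$length), 0.025)
  expect_lt(rel_err(m$surface_area, spec$truth$surface_area), 0.04)

  # resolution convergence: the same tube at double resolution
  spec2 <- worm_spec("straight", length_px = 800, radius_px = 24,
                     noise_sd = 0, scale = 0.0005)
  m2 <- run_pipeline(spec2)$morphometrics
  expect_lt(rel_err(m2$volume, m$volume), 0.015)

  # degenerate 2-point profile reduces to a single frustum
  wp <- structure(list(s = c(0, 1), s_px = c(0, 100),
                       width = c(0.4, 0.2), width_px = c(40, 20)),
                  class = "width_profile")
  fr <- to_frustum_series(wp)
  expect_equal(sum(frustum_volume(fr$r1, fr$r2, fr$h)),
               frustum_volume(0.2, 0.1, 1))
})

test_that("unit coherence: measurements scale exactly with the calibration", {
  fx <- tube_fixture("sine", length_px = 300, radius_px = 10,
                     amplitude_px = 25, scale = 0.002)
  mask <- preprocess_mask(fx$mask)
  m1 <- measure_worm(mask)$morphometrics
  half <- worm_mask(mask$pixels, mask$scale / 2)
  m2 <- measure_worm(half)$morphometrics
  expect_equal(m2$length, m1$length / 2)
  expect_equal(m2$surface_area, m1$surface_area / 4)
  expect_equal(m2$volume, m1$volume / 8)
})

test_that("frustum volume is below the cylinder bound for tapered worms", {
  for (cl in c("straight", "sine")) {
    fx <- tube_fixture(cl, length_px = 350, radius_px = 12,
                       amplitude_px = 25, noise_sd = 0.5, seed = 3)
    mask <- preprocess_mask(fx$mask)
    m <- measure_worm(mask)
    r_max <- max(m$widths$width) / 2
    expect_lt(m$morphometrics$volume,
              pi * r_max^2 * m$morphometrics$length)
  }
})

test_that("curvature is zero on lines, 1/R on arcs, kappa(s) on sine worms", {
  # ideal straight path: k identically ~0 (formula limit)
  line <- spine_path(cbind(seq(0, 100, by = 2), 50), extended = TRUE)
  expect_true(all(abs(curvature(line)) < 1e-12))
  # traced straight worm: residual k is skeleton-quantization noise, well
  # under 1e-3 px^-1 once averaged
  straight <- run_pipeline(worm_spec("straight", length_px = 400,
                                     radius_px = 12, noise_sd = 0))
  k0 <- curvature(straight$spine, smooth_sd = 2)
  s0 <- straight$spine$arc_length
  int0 <- s0 > 0.1 * max(s0) & s0 < 0.9 * max(s0)
  expect_lt(abs(mean(k0[int0])), 1e-3)

  # arc worm: constant curvature 1/R at interior points
  R <- 250
  arcw <- run_pipeline(worm_spec("arc", length_px = 450, radius_px = 12,
                                 arc_radius_px = R, noise_sd = 0))
  k <- curvature(arcw$spine, smooth_sd = 2)
  s <- arcw$spine$arc_length
  interior <- s > 0.15 * max(s) & s < 0.85 * max(s)
  expect_lt(rel_err(mean(abs(k[interior])), 1 / R), 0.05)

  # sine worm: k(s) matches the generator's closed-form curvature; the
  # Gaussian-smoothing flag (sd 4 samples ~ 16 px, far below the ~500 px
  # undulation wavelength) suppresses quantization noise without
  # attenuating the signal
  spec <- worm_spec("sine", length_px = 500, radius_px = 10,
                    amplitude_px = 60, periods = 1, noise_sd = 0)
  sinw <- run_pipeline(spec)
  ks <- curvature(sinw$spine, smooth_sd = 4)
  ss <- sinw$spine$arc_length
  inside <- ss > 0.1 * max(ss) & ss < 0.9 * max(ss)
  rms <- function(x) sqrt(mean(x^2))
  # the trace's orientation and s origin are arbitrary: allow flip/sign
  err <- sapply(list(ss, max(ss) - ss), function(spos) {
    kt <- approx(spec$truth$s_grid, spec$truth$kappa,
                 pmin(pmax(spos, 0), max(spec$truth$s_grid)))$y
    min(rms((ks - kt)[inside]), rms((ks + kt)[inside]))
  })
  expect_lt(min(err) / rms(ks[inside]), 0.10)
})

test_that("straightening rebuilds the silhouette faithfully", {
  mf_mask <- preprocess_mask(tube_fixture("straight", length_px = 350,
                                          radius_px = 12)$mask)
  m <- measure_worm(mf_mask)
  st <- straighten(m$widths)
  # a straight worm straightens to (nearly) itself: areas agree closely
  expect_lt(rel_err(sum(st), sum(mf_mask$pixels)), 0.02)

  curved <- preprocess_mask(tube_fixture("sine", length_px = 350,
                                         radius_px = 10, amplitude_px = 30,
                                         periods = 1.5)$mask)
  mc <- measure_worm(curved)
  stc <- straighten(mc$widths)
  expect_lt(rel_err(sum(stc), sum(curved$pixels)), 0.03)
  # symmetric about the central row
  expect_identical(stc, stc[rev(seq_len(nrow(stc))), , drop = FALSE])

  empty <- structure(list(s_px = c(0, 50), width_px = c(0, 0)),
                     class = "width_profile")
  expect_false(any(straighten(empty)))
})
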