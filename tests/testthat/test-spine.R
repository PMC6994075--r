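# Rasterize a parametric curve into a 1-px chain (test-only oracle input)
curve_raster <- function(fx, fy, t, h, w) {
  px <- matrix(FALSE, h, w)
  px[cbind(pmax(1, pmin(h, round(fy(t)))),
           pmax(1, pmin(w, round(fx(t)))))] <- TRUE
  px
}

test_that("skeletonize reduces a bar to its one-pixel midline", {
  mask <- rect_mask(60, 140, 9, 100)
  sk <- skeletonize(mask)
  expect_true(all(wormetrics:::neighbour_count(sk)[sk] <= 2))
  bb <- wormetrics:::fg_bbox(sk)
  expect_equal(unname(bb["rmax"]), unname(bb["rmin"]))  # a horizontal line
  # thinning shortens a 9-px-wide bar by about its width (here exactly
  # 100 - 9 = 91 px)
  span <- bb["cmax"] - bb["cmin"] + 1
  expect_gte(unname(span), 90)
  expect_lte(unname(span), 100)
})

test_that("skeletonize is robust to bumps and rejects degenerate shapes", {
  mask <- rect_mask(60, 140, 9, 100)
  bumped <- mask$pixels
  bumped[24:25, 60:61] <- TRUE                  # 4-px bump on one side
  sk0 <- skeletonize(mask)
  sk1 <- skeletonize(worm_mask(bumped, 1))
  # same longest path up to a few pixels near the bump
  expect_lt(sum(xor(sk0, sk1)) / sum(sk0), 0.10)

  expect_error(skeletonize(disk_mask(20)), "degenerate")
})

test_that("find_start picks the topmost centre-column crossing and its slope", {
  h <- 100; w <- 120
  horiz <- curve_raster(function(t) t, function(t) rep(50, length(t)),
                        seq(10, 110, by = 0.5), h, w)
  st <- find_start(horiz)
  expect_equal(unname(st$point), c(60, 50))
  expect_equal(st$slope, 0)

  diag45 <- curve_raster(function(t) t, function(t) t,
                         seq(5, 95, by = 0.25), h, w)
  st45 <- find_start(diag45)
  expect_lt(abs(st45$slope - 1), 0.1)

  u <- matrix(FALSE, h, w)
  u[30, 20:100] <- TRUE; u[70, 20:100] <- TRUE; u[30:70, 20] <- TRUE
  stu <- find_start(u)
  expect_equal(unname(stu$point[2]), 30)        # first (topmost) crossing
})

test_that("tracing recovers length on straight and semicircular skeletons", {
  h <- 100; w <- 160
  bar <- curve_raster(function(t) t, function(t) rep(50, length(t)),
                      seq(20, 140, by = 0.5), h, w)
  st <- find_start(bar)
  fwd <- trace_from(bar, st$point, st$angle, +1)
  expect_true(all(diff(fwd[, 1]) > 0))          # monotone advance
  sp <- trace_full(bar)
  expect_equal(max(sp$arc_length), 120, tolerance = 4 / 120)

  # semicircle radius 100: arc length should match pi*R within 2%
  R <- 100
  semi <- curve_raster(function(a) 150 + R * cos(a), function(a) 140 - R * sin(a),
                       seq(0, pi, length.out = 2000), 260, 300)
  sps <- trace_full(semi)
  expect_lt(rel_err(max(sps$arc_length), pi * R), 0.02)
})

test_that("spine paths are ordered with continuous tangents", {
  for (seed in 1:2) {
    fx <- tube_fixture("sine", length_px = 400, radius_px = 10,
                       amplitude_px = 25, periods = 1.5, seed = seed,
                       noise_sd = 0.4, rotation_deg = 15 * seed)
    mask <- preprocess_mask(fx$mask)
    sp <- trace_full(skeletonize(mask))
    expect_true(all(diff(sp$arc_length) > 0))
    expect_true(all(diff(sp$arc_length) <= 4 * 1.5))   # spacing bound
    expect_true(all(abs(diff(sp$tangent_angle)) < pi / 2))
  }
})

test_that("traced length is invariant to the seeding crossing", {
  fx <- tube_fixture("arc", length_px = 400, radius_px = 12,
                     arc_radius_px = 260)
  mask <- preprocess_mask(fx$mask)
  sk <- skeletonize(mask)
  sp_centre <- trace_full(sk)
  # seed manually well off-centre: full trace must agree within one step
  cols <- which(colSums(sk) > 0)
  c_off <- cols[round(length(cols) * 0.25)]
  y <- which(sk[, c_off])[1]
  y2 <- which(sk[, c_off + 5])[1]
  ang <- atan2(y2 - y, 5)
  fwd <- trace_from(sk, c(c_off, y), ang, +1)
  bwd <- trace_from(sk, c(c_off, y), ang, -1)
  len_off <- sum(sqrt(rowSums(diff(rbind(bwd[rev(seq_len(nrow(bwd))), ],
                                         fwd[-1, ]))^2)))
  expect_lt(abs(len_off - max(sp_centre$arc_length)), 2 * 4)
})

test_that("self-proximal hairpins raise an error instead of a wrong path", {
  spec <- worm_spec("hairpin", length_px = 450, radius_px = 5, gap_px = 15,
                    noise_sd = 0, allow_self_proximity = TRUE)
  mask <- preprocess_mask(render_worm(spec)$mask)
  sk <- skeletonize(mask)
  expect_error(trace_full(sk), "self-proximity")
})

test_that("outline is the one-pixel boundary", {
  sq <- rect_mask(40, 40, 10, 10)
  expect_equal(sum(outline(sq)), 36)            # 10x10 square ring

  one <- matrix(FALSE, 20, 20); one[10, 10] <- TRUE
  expect_identical(outline(worm_mask(one, 1)), one)

  # independent oracle for the disk boundary: enumerate foreground pixels
  # with a 4-neighbour outside the analytic disk (note this count runs
  # ~11% above 2*pi*r because diagonal stretches need extra pixels)
  dk <- disk_mask(50, pad = 10)
  n <- nrow(dk$pixels)
  inside <- function(r, c) (r - n / 2)^2 + (c - n / 2)^2 <= 50^2
  rr <- row(dk$pixels); cc <- col(dk$pixels)
  expected <- inside(rr, cc) &
    !(inside(rr - 1, cc) & inside(rr + 1, cc) &
      inside(rr, cc - 1) & inside(rr, cc + 1))
  expect_equal(sum(outline(dk)), sum(expected))
  expect_lt(rel_err(sum(outline(dk)), 2 * pi * 50), 0.15)

  # closed curve: every outline pixel touches at least 2 others
  ol <- outline(dk)
  expect_true(all(wormetrics:::neighbour_count(ol)[ol] >= 2))
})

test_that("extend_ends reaches the worm's true tips", {
  fx <- tube_fixture("straight", length_px = 400, radius_px = 12)
  mask <- preprocess_mask(fx$mask)
  sk <- skeletonize(mask)
  sp <- trace_full(sk, scale = 1)
  edge <- outline(mask)
  ext <- extend_ends(sp, edge)
  expect_true(ext$extended)
  expect_gt(max(ext$arc_length), max(sp$arc_length))
  # mask length along x is the worm's true extent for a horizontal tube
  bb <- wormetrics:::fg_bbox(mask$pixels)
  expect_lt(abs(max(ext$arc_length) - (bb["cmax"] - bb["cmin"] + 1)), 2.5)
  expect_error(extend_ends(ext, edge), "already extended")

  # tapered (pointed) tips: the appended end points land within 1.5 px of
  # the mask's extreme points along the axis
  ends <- ext$points[c(1, nrow(ext$points)), ]
  expect_lt(abs(min(ends[, 1]) - bb["cmin"]), 1.5)
  expect_lt(abs(max(ends[, 1]) - bb["cmax"]), 1.5)
})
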