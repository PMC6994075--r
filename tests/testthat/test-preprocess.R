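test_that("select_channel picks the highest-SD channel and passes grey through", {
  g <- worm_image(matrix(runif(100), 10, 10), 1)
  expect_identical(select_channel(g)$pixels, g$pixels)

  # construct channels with known contrast; oracle: per-channel SD by
  # direct computation
  set.seed(1)
  a <- array(0, c(20, 20, 3))
  a[, , 1] <- 0.5 + rnorm(400, 0, 0.02)
  a[, , 2] <- 0.5 + rnorm(400, 0, 0.16)
  a[, , 3] <- 0.5 + rnorm(400, 0, 0.02)
  a[a < 0] <- 0; a[a > 1] <- 1
  sds <- apply(a, 3, sd)
  expect_equal(which.max(sds), 2L)
  img <- worm_image(a, 1)
  expect_identical(select_channel(img)$pixels, a[, , 2])

  flat <- worm_image(array(0.5, c(10, 10, 3)), 1)
  expect_error(select_channel(flat), "no contrast")
  expect_error(worm_image(array(0.5, c(10, 10, 2)), 1), "2 channels")
})

test_that("binarize thresholds bimodal images and is polarity invariant", {
  mask <- rect_mask()
  img <- grey_from_mask(mask, fg = 0.2, bg = 0.85)
  out <- binarize(img)
  expect_identical(out$pixels, mask$pixels)    # dark minority is the worm

  inverted <- worm_image(1 - img$pixels, 1)
  expect_identical(binarize(inverted)$pixels, out$pixels)

  hard <- worm_image(ifelse(mask$pixels, 0, 1), 1)
  expect_identical(binarize(hard)$pixels, mask$pixels)

  expect_error(binarize(worm_image(matrix(0.4, 10, 10), 1)), "no contrast")
})

test_that("fill_holes fills interior background only, idempotently", {
  # annulus -> disk (forced by definition)
  n <- 80
  d2 <- (row(matrix(0, n, n)) - 40)^2 + (col(matrix(0, n, n)) - 40)^2
  annulus <- worm_mask(d2 <= 30^2 & d2 >= 15^2, 1)
  filled <- fill_holes(annulus)
  expect_identical(filled$pixels, d2 <= 30^2)

  expect_identical(fill_holes(filled)$pixels, filled$pixels)

  # two interior holes of 5 and 50 px; oracle: flood from border + complement
  m <- rect_mask(100, 200, 40, 160)
  holey <- m$pixels
  holey[50, 60:64] <- FALSE                     # 5 px
  holey[45:49, 100:109] <- FALSE                # 50 px
  out <- fill_holes(worm_mask(holey, 1))
  expect_identical(out$pixels, m$pixels)
})

test_that("morphological_cleanup removes eggs and keeps one worm", {
  worm <- rect_mask(120, 300, 24, 220)
  withegg <- worm$pixels
  withegg[20, 20:22] <- TRUE                    # 3 px "egg"
  out <- morphological_cleanup(worm_mask(withegg, 1), close_iters = 0,
                               open_iters = 2)
  expect_equal(wormetrics:::label_components(out$pixels)$n, 1L)
  expect_false(any(out$pixels[20, 20:22]))
  expect_true(sum(out$pixels) > 0.9 * sum(worm$pixels))

  # no-op settings still guarantee one component
  two <- worm$pixels
  two[10:12, 10:12] <- TRUE
  out2 <- morphological_cleanup(worm_mask(two, 1), 0, 0)
  expect_equal(sum(out2$pixels), sum(worm$pixels))

  # equal-area tie broken topmost-then-leftmost
  px <- matrix(FALSE, 400, 400)
  px[21:40, 21:40] <- TRUE      # topmost-leftmost
  px[301:320, 301:320] <- TRUE
  tie <- morphological_cleanup(worm_mask(px, 1), 0, 0)
  expect_true(all(which(tie$pixels, arr.ind = TRUE)[, 1] <= 40))

  lone <- matrix(FALSE, 10, 10)
  lone[5, 5] <- TRUE
  expect_error(morphological_cleanup(worm_mask(lone, 1), 0, 5), "eliminated")
})

test_that("orient_horizontal makes the long axis horizontal, conserving area", {
  horiz <- rect_mask(200, 300, 20, 160)
  out <- orient_horizontal(horiz)
  bb <- wormetrics:::fg_bbox(out$pixels)
  expect_equal(unname(bb["cmax"] - bb["cmin"] + 1), 160, tolerance = 0.02)
  expect_equal(unname(bb["rmax"] - bb["rmin"] + 1), 20, tolerance = 0.1)

  # same rectangle pre-rotated 30 degrees comes back to the same box
  spec_px <- horiz$pixels
  rot30 <- wormetrics:::rotate_mask_raster(
    wormetrics:::pad_raster(spec_px, 80), 30 * pi / 180)
  out30 <- orient_horizontal(worm_mask(rot30, 1))
  bb30 <- wormetrics:::fg_bbox(out30$pixels)
  expect_lt(abs((bb30["cmax"] - bb30["cmin"]) - (bb["cmax"] - bb["cmin"])), 2.5)
  expect_lt(abs((bb30["rmax"] - bb30["rmin"]) - (bb["rmax"] - bb["rmin"])), 2.5)

  # area conservation under the rotation resampling
  expect_lt(abs(sum(out30$pixels) / sum(spec_px) - 1), 0.02)

  # a disk cannot clip or fail regardless of its rotation invariance
  expect_silent(orient_horizontal(disk_mask(30)))
})

test_that("preprocess chain is idempotent and yields a valid mask", {
  fx <- tube_fixture("sine", length_px = 300, radius_px = 10,
                     amplitude_px = 25, rotation_deg = 40, noise_sd = 0.5)
  img <- grey_from_mask(fx$mask)
  m1 <- preprocess_image(img)
  expect_silent(validate_mask(m1))

  m2 <- preprocess_mask(m1)
  # idempotence: re-running changes under 1% of foreground pixels
  a1 <- sum(m1$pixels); a2 <- sum(m2$pixels)
  expect_lt(abs(a2 - a1) / a1, 0.01)
})
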