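test_that("sRGB transfer function matches the piecewise standard and round-trips", {
  expect_identical(srgb_to_linear(0), 0)
  expect_identical(srgb_to_linear(1), 1)
  # independent evaluation of the decoding formula at 0.5
  expect_equal(srgb_to_linear(0.5), ((0.5 + 0.055) / 1.055)^2.4, tolerance = 1e-12)
  expect_equal(srgb_to_linear(0.02), 0.02 / 12.92, tolerance = 1e-15)
  x <- withr::with_seed(1, runif(1000))
  expect_lt(max(abs(srgb_to_linear(linear_to_srgb(x)) - x)), 1e-12)
  expect_error(srgb_to_linear(c(0.2, 1.3)), "\\[0, 1\\]")
  expect_error(srgb_to_linear(-0.1), "\\[0, 1\\]")
})

test_that("linear_to_dkl maps the background to the origin and matches a per-pixel matrix oracle", {
  cfg <- dkl_config()
  bg <- array(0.5, c(3, 3, 3))
  d <- linear_to_dkl(bg, cfg)
  expect_lt(max(abs(c(d$ach, d$lm, d$s))), 1e-12)

  img <- withr::with_seed(7, array(runif(5 * 4 * 3), c(5, 4, 3)))
  d <- linear_to_dkl(img, cfg)
  for (i in 1:5) for (j in 1:4) {
    lms <- cfg$xyz_to_lms %*% (cfg$rgb_to_xyz %*% img[i, j, ])
    raw <- cfg$opponent %*% (lms - cfg$background_lms)
    exp_dkl <- as.numeric(raw) * cfg$axis_sign * cfg$axis_scale
    expect_equal(c(d$ach[i, j], d$lm[i, j], d$s[i, j]), exp_dkl, tolerance = 1e-12)
  }
})

test_that("achromatic inputs carry no chromatic signal; achromatic axis is monotone", {
  ramp <- fixture_images()$achromatic_ramp
  d <- srgb_to_dkl(ramp)
  expect_lt(max(abs(d$lm)), 1e-10)
  expect_lt(max(abs(d$s)), 1e-10)
  expect_true(all(diff(d$ach[1, ]) > 0))
})

test_that("the DKL map is affine in linear RGB", {
  cfg <- dkl_config()
  for (seed in 1:5) {
    pq <- withr::with_seed(seed, runif(7))
    p <- array(pq[1:3], c(1, 1, 3)); q <- array(pq[4:6], c(1, 1, 3))
    a <- pq[7]
    mix <- linear_to_dkl(a * p + (1 - a) * q, cfg)
    dp <- linear_to_dkl(p, cfg); dq <- linear_to_dkl(q, cfg)
    for (ax in c("ach", "lm", "s"))
      expect_equal(mix[[ax]][1], a * dp[[ax]][1] + (1 - a) * dq[[ax]][1],
                   tolerance = 1e-10)
  }
})

test_that("axis polarity puts red at +L/M, yellow at +S, blue at -S", {
  cfg <- dkl_config()
  px <- function(rgb) linear_to_dkl(array(rgb, c(1, 1, 3)), cfg)
  expect_gt(px(c(1, 0, 0))$lm[1], 0)   # red / cherry
  expect_lt(px(c(0, 1, 1))$lm[1], 0)   # cyan opposite sign
  expect_gt(px(c(1, 1, 0))$s[1], 0)    # yellow toward lime
  expect_lt(px(c(0, 0, 1))$s[1], 0)    # blue toward violet
})

test_that("srgb_to_luv gives the standard chromaticity, white point for black, luminance invariance", {
  white <- srgb_to_luv(array(1, c(3, 3, 3)))
  expect_equal(white$u[1, 1], 0.1978398, tolerance = 1e-6)
  expect_equal(white$v[1, 1], 0.4683363, tolerance = 1e-6)
  expect_equal(white$L[1, 1], 1)

  black <- srgb_to_luv(array(0, c(3, 3, 3)))
  expect_equal(black$u[1, 1], white$u[1, 1])
  expect_equal(black$v[1, 1], white$v[1, 1])
  expect_equal(black$L[1, 1], 0)

  # scaling linear RGB by a scalar leaves (u', v') unchanged
  base <- withr::with_seed(3, runif(3, 0.2, 0.9))
  for (k in c(0.25, 0.5, 1)) {
    lin <- array(base * k, c(1, 1, 3))
    luv <- srgb_to_luv(array(linear_to_srgb(lin), c(1, 1, 3)))
    ref <- srgb_to_luv(array(linear_to_srgb(array(base, c(1, 1, 3))), c(1, 1, 3)))
    expect_equal(luv$u[1, 1], ref$u[1, 1], tolerance = 1e-12)
    expect_equal(luv$v[1, 1], ref$v[1, 1], tolerance = 1e-12)
  }
})

test_that("RGB cube projection is in histogram range with achromatic corners at the origin", {
  cfg <- dkl_config()
  proj <- rgb_cube_projection(cfg, samples_per_edge = 6)
  expect_equal(nrow(proj), 6^3)
  corners <- proj[(proj$r %in% c(0, 1)) & (proj$g %in% c(0, 1)) & (proj$b %in% c(0, 1)), ]
  bw <- corners[corners$r == corners$g & corners$g == corners$b, ]
  expect_lt(max(abs(c(bw$lm, bw$s))), 1e-10)
  red <- corners[corners$r == 1 & corners$g == 0 & corners$b == 0, ]
  cyan <- corners[corners$r == 0 & corners$g == 1 & corners$b == 1, ]
  expect_lt(red$lm * cyan$lm, 0)
  expect_true(all(abs(proj[, c("ach", "lm", "s")]) <= 2 + 1e-9))
  # gamut calibration is tight: some corner attains magnitude 2 on each axis
  for (ax in c("ach", "lm", "s"))
    expect_equal(max(abs(proj[[ax]])), 2, tolerance = 1e-9)
})

test_that("invalid configurations are rejected", {
  expect_error(dkl_config(rgb_to_xyz = matrix(0, 3, 3)), "invertible")
  expect_error(dkl_config(background_rgb = c(0, 0, 0)), "positive")
  expect_error(dkl_config(axis_sign = c(1, 2, 1)))
})

test_that("a key-value config file overrides the defaults", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("background_rgb: [0.4, 0.4, 0.4]",
               "axis_sign: [1, -1, 1]",
               "axis_scale: [1, 5, 2]"), path)
  cfg <- read_dkl_config(path)
  expect_equal(cfg$background_rgb, c(0.4, 0.4, 0.4))
  expect_equal(cfg$axis_sign, c(1, -1, 1))
  expect_equal(cfg$axis_scale, c(1, 5, 2))
  d <- linear_to_dkl(array(0.4, c(2, 2, 3)), cfg)
  expect_lt(max(abs(c(d$ach, d$lm, d$s))), 1e-12)
})

test_that("image IO round-trips 16-bit TIFF and 8-bit PNG and handles channel quirks", {
  img <- withr::with_seed(11, quantize_image(array(runif(6 * 5 * 3), c(6, 5, 3)), 16L))
  tf <- withr::local_tempfile(fileext = ".tiff")
  write_image(img, tf)
  back <- read_image(tf)
  expect_equal(as.numeric(back), as.numeric(img), tolerance = 1e-9)
  expect_equal(attr(back, "bit_depth"), 16L)

  img8 <- quantize_image(img, 8L)
  pf <- withr::local_tempfile(fileext = ".png")
  write_image(img8, pf)
  expect_equal(as.numeric(read_image(pf)), as.numeric(img8), tolerance = 1e-9)

  gray <- matrix(withr::with_seed(2, runif(16)), 4, 4)
  gf <- withr::local_tempfile(fileext = ".png")
  png::writePNG(gray, gf)
  expect_warning(g3 <- read_image(gf), "grayscale")
  expect_equal(dim(g3), c(4, 4, 3))

  rgba <- withr::with_seed(3, array(runif(4 * 4 * 4), c(4, 4, 4)))
  af <- withr::local_tempfile(fileext = ".png")
  png::writePNG(rgba, af)
  expect_equal(dim(read_image(af))[3], 3)
})
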