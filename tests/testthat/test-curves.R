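test_that("the default grid has exactly 1464 contrast levels, matching a brute-force oracle", {
  lv <- contrast_levels()
  expect_length(lv, 1464)
  expect_true(all(diff(lv) > 0))
  centers <- hist_bin_centers()
  brute <- sort(unique(oracle_round4(sqrt(outer(centers^2, centers^2, `+`)))))
  expect_equal(lv, brute, tolerance = 1e-12)
})

test_that("a 2x2 grid collapses all corners to one level", {
  lv <- contrast_levels(nbins = 2L)
  expect_equal(lv, 1.4142)
})

test_that("contrast rounding is half away from zero at 4 decimals", {
  expect_equal(round_contrast(0.00005), 0.0001)
  expect_equal(round_contrast(1.23455), 1.2346)
  expect_equal(round_contrast(-0.00005), -0.0001)
  expect_equal(round_contrast(2.80633), 2.8063)
})

test_that("quadrant sets partition the grid with no axis-line bins", {
  q <- lapply(c("Q1", "Q2", "Q3", "Q4"), quadrant_set)
  expect_true(all(vapply(q, `[[`, 0, "n_bins") == 64^2))
  expect_equal(Reduce(`+`, lapply(q, `[[`, "mask")), matrix(1, 128, 128))
  q234 <- quadrant_complement(quadrant_set("Q1"))
  expect_setequal(q234$included, c("Q2", "Q3", "Q4"))
  expect_equal(q234$n_bins, 3 * 64^2)
  expect_error(quadrant_set(character(0)), "non-empty")
})

test_that("contrast curves group histogram mass by rounded radius (oracle check)", {
  # sparse random histogram
  counts <- matrix(0, 128, 128)
  pos <- withr::with_seed(4, sample(128 * 128, 300))
  counts[pos] <- withr::with_seed(5, runif(300))
  counts <- counts / sum(counts)
  h <- dklstats:::new_joint_histogram(counts, plane_pair("lm_s"), 1, 0)
  for (qs in list(quadrant_set("Q1"), quadrant_set(c("Q2", "Q3", "Q4")))) {
    cv <- contrast_curve(h, qs)
    o <- oracle_curve(counts, qs$mask, cv$contrast)
    expect_equal(cv$density, o, tolerance = 1e-12)
  }
})

test_that("all mass near the origin lands at the smallest contrast level", {
  h <- compute_joint_histogram(srgb_to_dkl(fixture_images()$gray))
  cv <- contrast_curve(h, quadrant_set(c("Q1", "Q2", "Q3", "Q4")))
  expect_equal(which(cv$density > 0), 1L)
  expect_equal(cv$contrast[1], round_contrast(sqrt(2) * 4 / 256))
})

test_that("per-bin normalization equalizes quadrants of a uniform histogram", {
  counts <- matrix(1 / 128^2, 128, 128)
  h <- dklstats:::new_joint_histogram(counts, plane_pair("lm_s"), 1, 0)
  c1 <- contrast_curve(h, quadrant_set("Q1"))
  c234 <- contrast_curve(h, quadrant_set(c("Q2", "Q3", "Q4")))
  expect_equal(c1$density, c234$density, tolerance = 1e-12)
})

test_that("count-weighted quadrant curves recombine to the all-quadrant profile", {
  h <- compute_joint_histogram(
    srgb_to_dkl(generate_still_life(still_life_params(seed = 3, width = 64, height = 64))$image))
  c1 <- contrast_curve(h, quadrant_set("Q1"))
  c234 <- contrast_curve(h, quadrant_set(c("Q2", "Q3", "Q4")))
  call <- contrast_curve(h, quadrant_set(c("Q1", "Q2", "Q3", "Q4")))
  recon <- (c1$density * c1$quadrants$n_bins + c234$density * c234$quadrants$n_bins) /
    call$quadrants$n_bins
  expect_equal(recon, call$density, tolerance = 1e-12)
})

test_that("rotating the histogram by 90 degrees maps the Q1 curve to the Q2 curve", {
  counts <- matrix(withr::with_seed(8, runif(128^2)), 128, 128)
  counts <- counts / sum(counts)
  h <- dklstats:::new_joint_histogram(counts, plane_pair("lm_s"), 1, 0)
  # rotate: (x, y) -> (-y, x); bin (i, j) -> (129 - j, i)
  rot <- t(counts)[rev(seq_len(128)), ]
  hr <- dklstats:::new_joint_histogram(rot, plane_pair("lm_s"), 1, 0)
  q1 <- contrast_curve(h, quadrant_set("Q1"))
  q2 <- contrast_curve(hr, quadrant_set("Q2"))
  expect_equal(q2$density, q1$density, tolerance = 1e-14)
})

test_that("Gaussian smoothing preserves constants, mass, and the impulse response", {
  lv <- contrast_levels()
  const <- make_curve(rep(0.3, length(lv)), lv)
  sm <- smooth_curve(const, sigma = 10)
  expect_lt(max(abs(sm$density - 0.3)), 1e-9)
  expect_true(sm$smoothed)
  expect_equal(sm$sigma, 10)

  imp <- rep(0, 301); imp[151] <- 1
  smi <- smooth_curve(make_curve(imp), sigma = 10)
  r <- ceiling(4 * 10)
  k <- exp(-0.5 * ((-r):r / 10)^2); k <- k / sum(k)
  expect_equal(smi$density[151 + (-r):r], k, tolerance = 1e-12)
  expect_equal(sum(smi$density), 1, tolerance = 1e-9)

  expect_error(smooth_curve(const, sigma = 0), "positive")
  expect_error(smooth_curve(sm, sigma = 10), "already smoothed")
})

test_that("smoothing matches the direct-convolution oracle including boundaries", {
  for (seed in c(2, 12)) {
    y <- withr::with_seed(seed, runif(120))
    cv <- smooth_curve(make_curve(y), sigma = 7)
    expect_equal(cv$density, oracle_smooth(y, sigma = 7), tolerance = 1e-12)
  }
})

test_that("curve differences are pointwise, antisymmetric, and grid-checked", {
  h <- compute_joint_histogram(
    srgb_to_dkl(generate_still_life(still_life_params(seed = 6, width = 64, height = 64))$image))
  a <- contrast_curve(h, quadrant_set("Q1"))
  b <- contrast_curve(h, quadrant_set(c("Q2", "Q3", "Q4")))
  expect_equal(curve_difference(a, a)$density, rep(0, length(a$contrast)))
  expect_equal(curve_difference(a, b)$density, -curve_difference(b, a)$density)
  short <- make_curve(rep(0, 10))
  expect_error(curve_difference(a, short), "different contrast grids")
  expect_error(curve_difference(a, smooth_curve(b)), "smoothing state")
})

test_that("warm-excess statistic is zero for matched profiles and increases with the warm gain", {
  counts <- matrix(1 / 128^2, 128, 128)
  h <- dklstats:::new_joint_histogram(counts, plane_pair("lm_s"), 1, 0)
  expect_equal(warm_excess_statistic(h), 0, tolerance = 1e-12)

  gains <- c(1, 1.25, 1.5, 2)
  n_seeds <- 8
  stats <- matrix(NA_real_, n_seeds, length(gains))
  for (si in seq_len(n_seeds)) {
    for (gi in seq_along(gains)) {
      hists <- corpus_hists(3, gains[gi], seed = 1000 * si)  # paired seeds across gains
      stats[si, gi] <- warm_excess_statistic(hists)
    }
  }
  # monotone non-decreasing across the gain ladder for the large majority of seeds
  concord <- mean(apply(stats, 1, function(r) all(diff(r) > 0)))
  expect_gte(concord, 0.95)
  # null is near zero, boosted corpora clearly positive
  expect_lt(mean(abs(stats[, 1])), 0.02)
  expect_gt(min(stats[, 4]), 0.05)
})
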