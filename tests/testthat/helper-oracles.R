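# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: plain loops, string-based rounding, textbook formulas.

# decimal rounding via C's formatted printing (independent of round_contrast)
oracle_round4 <- function(x) as.numeric(formatC(x, digits = 4, format = "f"))

# per-pixel loop histogram over one plane, half-open bins, last bin closed
oracle_hist <- function(x, y, nbins = 128, lim = c(-2, 2)) {
  edges <- seq(lim[1], lim[2], length.out = nbins + 1)
  counts <- matrix(0, nbins, nbins)
  oor <- 0
  for (k in seq_along(x)) {
    ix <- iy <- NA
    for (b in seq_len(nbins)) {
      hi_ok_x <- if (b == nbins) x[k] <= edges[b + 1] else x[k] < edges[b + 1]
      if (x[k] >= edges[b] && hi_ok_x) ix <- b
      hi_ok_y <- if (b == nbins) y[k] <= edges[b + 1] else y[k] < edges[b + 1]
      if (y[k] >= edges[b] && hi_ok_y) iy <- b
    }
    if (is.na(ix) || is.na(iy)) oor <- oor + 1 else counts[ix, iy] <- counts[ix, iy] + 1
  }
  list(counts = counts / length(x), oor = oor)
}

# group histogram bins by rounded radius with an explicit loop, keyed by the
# printed 4-decimal representation (independent of the package's rounding)
oracle_curve <- function(counts, quad_mask, levels, nbins = 128, lim = c(-2, 2)) {
  h <- (lim[2] - lim[1]) / nbins
  centers <- lim[1] + (seq_len(nbins) - 0.5) * h
  keys <- formatC(levels, digits = 4, format = "f")
  density <- stats::setNames(rep(0, length(levels)), keys)
  for (i in seq_len(nbins)) for (j in seq_len(nbins)) {
    if (!quad_mask[i, j]) next
    key <- formatC(sqrt(centers[i]^2 + centers[j]^2), digits = 4, format = "f")
    stopifnot(key %in% keys)
    density[key] <- density[key] + counts[i, j]
  }
  unname(density) / sum(quad_mask)
}

# direct convolution with explicit reflecting indices
oracle_smooth <- function(y, sigma = 10) {
  r <- ceiling(4 * sigma)
  k <- exp(-0.5 * ((-r):r / sigma)^2)
  k <- k / sum(k)
  n <- length(y)
  reflect <- function(i) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 2 - i
      if (i > n) i <- 2 * n - i
    }
    i
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in (-r):r) s <- s + k[j + r + 1] * y[reflect(i + j)]
    out[i] <- s
  }
  out
}

# triple loop over interior pixels and their 8 neighbors
oracle_local_diffs <- function(L, u, v) {
  n <- nrow(L); p <- ncol(L)
  chrom <- achro <- matrix(NA_real_, n - 2, p - 2)
  for (i in 2:(n - 1)) for (j in 2:(p - 1)) {
    cs <- as <- 0
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      cs <- cs + sqrt((u[i + di, j + dj] - u[i, j])^2 + (v[i + di, j + dj] - v[i, j])^2)
      as <- as + abs(L[i + di, j + dj] - L[i, j])
    }
    chrom[i - 1, j - 1] <- cs / 8
    achro[i - 1, j - 1] <- as / 8
  }
  list(chromatic = chrom, achromatic = achro)
}

# textbook Pearson r
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# random in-gamut dkl_image for oracle tests: coordinates drawn inside [-2,2]
random_dkl <- function(h, w, seed, spread = 1.9) {
  withr::with_seed(seed, {
    structure(list(ach = matrix(stats::runif(h * w, -spread, spread), h, w),
                   lm = matrix(stats::runif(h * w, -spread, spread), h, w),
                   s = matrix(stats::runif(h * w, -spread, spread), h, w)),
              class = "dkl_image")
  })
}

# wrap a density vector as a contrast_curve on the default level grid (or a
# synthetic grid) for bootstrap tests
make_curve <- function(density, contrast = NULL) {
  if (is.null(contrast)) contrast <- seq_len(length(density)) / length(density)
  structure(list(contrast = contrast, density = density,
                 quadrants = NULL, smoothed = FALSE, sigma = NA_real_),
            class = "contrast_curve")
}

# small synthetic corpus -> per-image joint histograms for a plane
corpus_hists <- function(n, g, seed, plane = "lm_s", size = 64L) {
  corpus_hists_multi(n, g, seed, plane, size)[[plane]]
}

# one generation pass, histograms for several planes
corpus_hists_multi <- function(n, g, seed, planes = c("lm_s", "s_ach"), size = 64L) {
  seeds <- withr::with_seed(seed, sample.int(2^30, n))
  out <- stats::setNames(vector("list", length(planes)), planes)
  for (pl in planes) out[[pl]] <- vector("list", n)
  for (i in seq_len(n)) {
    p <- still_life_params(width = size, height = size, seed = seeds[i],
                           warm_saturation_gain = g)
    d <- srgb_to_dkl(generate_still_life(p)$image)
    for (pl in planes) out[[pl]][[i]] <- compute_joint_histogram(d, plane_pair(pl))
  }
  out
}
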