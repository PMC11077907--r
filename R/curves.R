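#' Round to 4 decimal places, half away from zero
#'
#' The discretization applied to radial chromatic contrast before grouping
#' bins into contrast levels. On the default 128x128 grid it yields exactly
#' 1,464 unique levels.
#'
#' @param x non-negative numeric.
#' @param digits decimal places (default 4).
#' @return rounded values.
#' @export
round_contrast <- function(x, digits = 4L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Enumerate the radial chromatic-contrast levels of a histogram grid
#'
#' Distance of every bin center to the origin (0, 0), rounded via
#' [round_contrast()], deduplicated and sorted. Every quadrant of the grid
#' realizes the same level set (the centers are symmetric about both axes).
#'
#' @param nbins bins per axis (default 128).
#' @param lim axis range (default `c(-2, 2)`).
#' @param digits rounding digits.
#' @return sorted numeric vector of unique contrast levels (length 1,464 for
#'   the defaults).
#' @export
contrast_levels <- function(nbins = 128L, lim = c(-2, 2), digits = 4L) {
  cc <- hist_bin_centers(nbins, lim)
  r <- sqrt(outer(cc^2, cc^2, `+`))
  sort(unique(as.numeric(round_contrast(r, digits))))
}

# nbins x nbins matrix of level indices into contrast_levels(); memoized
.level_cache <- new.env(parent = emptyenv())
contrast_level_index <- function(nbins = 128L, lim = c(-2, 2), digits = 4L) {
  key <- paste(nbins, lim[1], lim[2], digits, sep = "|")
  hit <- .level_cache[[key]]
  if (!is.null(hit)) return(hit)
  cc <- hist_bin_centers(nbins, lim)
  r <- round_contrast(sqrt(outer(cc^2, cc^2, `+`)), digits)
  lv <- sort(unique(as.numeric(r)))
  out <- list(levels = lv, index = matrix(match(as.numeric(r), lv), nbins, nbins))
  .level_cache[[key]] <- out
  out
}

#' Quadrant subsets of the histogram grid
#'
#' Quadrants are defined by the sign of the bin center: Q1 = (+x, +y),
#' Q2 = (-x, +y), Q3 = (-x, -y), Q4 = (+x, -y). No bin center of the default
#' grid lies on an axis (centers sit at odd multiples of half the bin width),
#' so membership by strict sign is total; this is asserted.
#'
#' @param included character subset of `c("Q1","Q2","Q3","Q4")`.
#' @param nbins,lim grid specification.
#' @return A `quadrant_set`: list with `included`, `mask`
#'   (nbins x nbins logical), `n_bins`.
#' @export
quadrant_set <- function(included, nbins = 128L, lim = c(-2, 2)) {
  if (length(included) == 0) stop("quadrant set must be non-empty")
  included <- unique(match.arg(included, c("Q1", "Q2", "Q3", "Q4"),
                               several.ok = TRUE))
  cc <- hist_bin_centers(nbins, lim)
  if (any(cc == 0)) stop("grid has bin centers on an axis; quadrants undefined")
  xs <- matrix(cc, nbins, nbins)          # x varies along rows
  ys <- matrix(cc, nbins, nbins, byrow = TRUE)
  qmask <- list(Q1 = xs > 0 & ys > 0, Q2 = xs < 0 & ys > 0,
                Q3 = xs < 0 & ys < 0, Q4 = xs > 0 & ys < 0)
  mask <- Reduce(`|`, qmask[included])
  structure(list(included = included, mask = mask, n_bins = sum(mask),
                 nbins = nbins, lim = lim),
            class = "quadrant_set")
}

#' Complement of a quadrant set
#' @param quads a [quadrant_set()].
#' @return the `quadrant_set` of the remaining quadrants.
#' @export
quadrant_complement <- function(quads) {
  quadrant_set(setdiff(c("Q1", "Q2", "Q3", "Q4"), quads$included),
               quads$nbins, quads$lim)
}

#' Radial chromatic-contrast curve of a joint histogram
#'
#' For each contrast level (rounded bin-center distance to the origin), sums
#' the histogram mass over the bins of the quadrant subset at that level, then
#' divides by the number of grid bins in the subset so that quadrant subsets
#' of different sizes are comparable.
#'
#' @param hist a normalized `joint_histogram`.
#' @param quads a [quadrant_set()] on the same grid.
#' @param digits contrast rounding digits.
#' @return A `contrast_curve`: list with `contrast` (sorted levels),
#'   `density`, `quadrants`, `smoothed`, `sigma`.
#' @export
contrast_curve <- function(hist, quads = quadrant_set("Q1"), digits = 4L) {
  stopifnot(inherits(hist, "joint_histogram"), inherits(quads, "quadrant_set"))
  if (quads$nbins != hist$nbins || !identical(quads$lim, hist$lim))
    stop("quadrant set and histogram use different grids")
  li <- contrast_level_index(hist$nbins, hist$lim, digits)
  idx <- li$index[quads$mask]
  mass <- hist$counts[quads$mask]
  density <- rep(0, length(li$levels))
  acc <- rowsum(mass, idx)
  density[as.integer(rownames(acc))] <- acc
  structure(list(contrast = li$levels, density = density / quads$n_bins,
                 quadrants = quads, smoothed = FALSE, sigma = NA_real_),
            class = "contrast_curve")
}

gaussian_kernel <- function(sigma, radius = ceiling(4 * sigma)) {
  if (sigma <= 0) stop("sigma must be positive")
  k <- exp(-0.5 * ((-radius):radius / sigma)^2)
  k / sum(k)
}

# 1-D convolution with reflecting boundary, unit-sum kernel
convolve_reflect <- function(y, kernel) {
  r <- (length(kernel) - 1L) / 2L
  n <- length(y)
  if (r == 0) return(y)
  pad <- c(y[pmin(r:1 + 1L, n)], y, y[pmax(n - (1:r), 1L)])
  as.numeric(stats::filter(pad, kernel, sides = 2))[(r + 1L):(r + n)]
}

#' Gaussian smoothing of a contrast curve
#'
#' Convolves the density with a unit-sum 1-D Gaussian over the sample index
#' axis (standard deviation in curve samples; default 10), truncated at 4
#' standard deviations and renormalized, with reflecting boundary.
#'
#' @param curve an unsmoothed `contrast_curve` (or a `curve_band`).
#' @param sigma kernel standard deviation in samples.
#' @return the smoothed object, with `smoothed = TRUE` and `sigma` recorded.
#' @export
smooth_curve <- function(curve, sigma = 10) {
  if (sigma <= 0) stop("sigma must be positive")
  k <- gaussian_kernel(sigma)
  if (inherits(curve, "curve_band")) {
    for (f in c("mean", "lower", "upper")) curve[[f]] <- convolve_reflect(curve[[f]], k)
    curve$smoothed <- TRUE; curve$sigma <- sigma
    return(curve)
  }
  stopifnot(inherits(curve, "contrast_curve"))
  if (isTRUE(curve$smoothed)) stop("curve is already smoothed")
  curve$density <- convolve_reflect(curve$density, k)
  curve$smoothed <- TRUE
  curve$sigma <- sigma
  curve
}

#' Pointwise difference of two contrast curves
#'
#' @param a,b `contrast_curve`s on the same contrast grid and smoothing state.
#' @return A `contrast_curve` whose density is `a - b` (signed), tagged with
#'   both quadrant sets.
#' @export
curve_difference <- function(a, b) {
  stopifnot(inherits(a, "contrast_curve"), inherits(b, "contrast_curve"))
  if (!isTRUE(all.equal(a$contrast, b$contrast, tolerance = 0)))
    stop("curves are on different contrast grids")
  if (!identical(a$smoothed, b$smoothed)) stop("curves differ in smoothing state")
  structure(list(contrast = a$contrast, density = a$density - b$density,
                 quadrants = list(a = a$quadrants, b = b$quadrants),
                 smoothed = a$smoothed, sigma = a$sigma),
            class = "contrast_curve")
}

#' Density-weighted mean contrast of a curve
#' @param curve a `contrast_curve`.
#' @return scalar; `NA` if the curve carries no mass.
#' @export
mean_contrast <- function(curve) {
  tot <- sum(curve$density)
  if (tot <= 0) return(NA_real_)
  sum(curve$contrast * curve$density) / tot
}

#' Warm-excess statistic of a corpus
#'
#' One-number summary of how much farther from the origin the mass of one
#' quadrant subset sits compared with its complement. Per-image normalized
#' histograms are averaged binwise; unsmoothed contrast curves are formed for
#' the quadrant set and its complement; the statistic is the difference of
#' their density-weighted mean contrasts. It is 0 when the two profiles have
#' equal mean radial contrast, positive when the chosen (warm) quadrant
#' carries relatively more high-contrast mass, and strictly increasing in any
#' saturation boost confined to that quadrant.
#'
#' @param hists list of normalized per-image `joint_histogram`s (same plane),
#'   or a single (e.g. mean) histogram.
#' @param quads [quadrant_set()] of interest (default Q1, the warm quadrant).
#' @param digits contrast rounding digits.
#' @return scalar statistic.
#' @export
warm_excess_statistic <- function(hists, quads = quadrant_set("Q1"), digits = 4L) {
  if (inherits(hists, "joint_histogram")) hists <- list(hists)
  mh <- mean_histogram(hists)
  q <- contrast_curve(mh, quads, digits)
  rest <- contrast_curve(mh, quadrant_complement(quads), digits)
  mean_contrast(q) - mean_contrast(rest)
}

#' Serialize curves (and optional band/difference) to CSV
#'
#' @param curves named list of `contrast_curve`s sharing one contrast grid.
#' @param path output CSV path.
#' @param band optional `curve_band` providing `lower`/`upper` columns.
#' @return `path`, invisibly.
#' @export
write_curves_csv <- function(curves, path, band = NULL) {
  stopifnot(length(curves) >= 1)
  df <- data.frame(contrast = curves[[1]]$contrast)
  for (nm in names(curves)) df[[nm]] <- curves[[nm]]$density
  if (!is.null(band)) {
    df$lower <- band$lower
    df$upper <- band$upper
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
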