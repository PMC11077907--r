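#' The three cardinal DKL plane pairs
#'
#' Axis pairs over which joint histograms are built: the isoluminant plane
#' (`lm_s`: x = L/M, y = S), the L/M vs achromatic plane (`lm_ach`) and the
#' S vs achromatic plane (`s_ach`).
#'
#' @param name one of `"lm_s"`, `"lm_ach"`, `"s_ach"`.
#' @return A `plane_pair`: list with `name`, `x_axis`, `y_axis`.
#' @export
plane_pair <- function(name = c("lm_s", "lm_ach", "s_ach")) {
  name <- match.arg(name)
  axes <- switch(name,
                 lm_s = c("lm", "s"),
                 lm_ach = c("lm", "ach"),
                 s_ach = c("s", "ach"))
  structure(list(name = name, x_axis = axes[1], y_axis = axes[2]),
            class = "plane_pair")
}

#' @rdname plane_pair
#' @export
dkl_planes <- function() lapply(c("lm_s", "lm_ach", "s_ach"), plane_pair)

plane_coords <- function(dkl, plane) {
  list(x = dkl[[plane$x_axis]], y = dkl[[plane$y_axis]])
}

hist_bin_edges <- function(nbins = 128L, lim = c(-2, 2)) {
  seq(lim[1], lim[2], length.out = nbins + 1L)
}

#' Bin centers of the default joint-histogram grid
#' @param nbins bins per axis.
#' @param lim axis range.
#' @return numeric vector of `nbins` centers.
#' @export
hist_bin_centers <- function(nbins = 128L, lim = c(-2, 2)) {
  h <- (lim[2] - lim[1]) / nbins
  lim[1] + (seq_len(nbins) - 0.5) * h
}

# half-open bins [e_k, e_{k+1}), last bin closed; 0 marks out-of-range
bin_index <- function(v, nbins = 128L, lim = c(-2, 2)) {
  h <- (lim[2] - lim[1]) / nbins
  ix <- floor((v - lim[1]) / h) + 1
  ix[v == lim[2]] <- nbins
  ix[v < lim[1] | v > lim[2]] <- 0L
  as.integer(ix)
}

new_joint_histogram <- function(counts, plane, n_total, n_oor,
                                normalized = TRUE, nbins = 128L, lim = c(-2, 2)) {
  structure(list(plane = plane, counts = counts,
                 bin_edges_x = hist_bin_edges(nbins, lim),
                 bin_edges_y = hist_bin_edges(nbins, lim),
                 n_pixels_total = n_total, n_pixels_out_of_range = n_oor,
                 normalized = normalized, nbins = nbins, lim = lim),
            class = "joint_histogram")
}

#' Joint 2-D histogram of a DKL image over one plane pair
#'
#' Discretizes the plane into `nbins` x `nbins` equal-width bins spanning
#' [-2, 2] on each axis and counts the pixels falling into each bin. The
#' histogram is normalized by the total number of image pixels, so it is
#' independent of image size. Pixels outside the range are excluded from the
#' grid but counted in `n_pixels_out_of_range` (empty for in-gamut inputs
#' under the gamut-calibrated axis scaling).
#'
#' @param dkl a `dkl_image` from [srgb_to_dkl()].
#' @param plane a [plane_pair()] (or its name).
#' @param nbins bins per axis (default 128).
#' @param lim axis range (default `c(-2, 2)`).
#' @return A `joint_histogram` whose `counts` matrix is indexed
#'   `[x_bin, y_bin]`.
#' @export
compute_joint_histogram <- function(dkl, plane = plane_pair("lm_s"),
                                    nbins = 128L, lim = c(-2, 2)) {
  if (is.character(plane)) plane <- plane_pair(plane)
  co <- plane_coords(dkl, plane)
  n <- length(co$x)
  if (n == 0) stop("empty image")
  if (!all(is.finite(co$x)) || !all(is.finite(co$y)))
    stop("DKL coordinates must be finite")
  ix <- bin_index(co$x, nbins, lim)
  iy <- bin_index(co$y, nbins, lim)
  ok <- ix > 0L & iy > 0L
  counts <- matrix(tabulate(ix[ok] + (iy[ok] - 1L) * nbins, nbins * nbins),
                   nbins, nbins)
  new_joint_histogram(counts / n, plane, n, sum(!ok), TRUE, nbins, lim)
}

#' Joint histogram restricted to a pixel mask
#'
#' As [compute_joint_histogram()], but only mask-true pixels contribute and
#' normalization is by the mask pixel count. Used for cut-out (region of
#' interest) analyses.
#'
#' @param dkl a `dkl_image`.
#' @param mask HxW logical (or 0/1) matrix matching the image.
#' @inheritParams compute_joint_histogram
#' @return A `joint_histogram`.
#' @export
masked_histogram <- function(dkl, mask, plane = plane_pair("lm_s"),
                             nbins = 128L, lim = c(-2, 2)) {
  if (is.character(plane)) plane <- plane_pair(plane)
  mask <- mask != 0
  if (!identical(dim(mask), dim(dkl$ach))) stop("mask shape does not match image")
  if (!any(mask)) stop("empty mask")
  sub <- structure(list(ach = dkl$ach[mask], lm = dkl$lm[mask], s = dkl$s[mask]),
                   class = "dkl_image")
  compute_joint_histogram(sub, plane, nbins, lim)
}

#' Unweighted binwise mean of per-image joint histograms
#'
#' Corpus summary: the mean of each bin across images (every image carries
#' equal weight regardless of pixel count).
#'
#' @param hists list of normalized `joint_histogram`s over the same plane and
#'   binning.
#' @return A `joint_histogram` with an added `n_images` field.
#' @export
mean_histogram <- function(hists) {
  stopifnot(length(hists) >= 1)
  p0 <- hists[[1]]$plane$name
  for (h in hists) {
    if (!inherits(h, "joint_histogram")) stop("inputs must be joint_histograms")
    if (h$plane$name != p0) stop("histograms span different planes")
    if (h$nbins != hists[[1]]$nbins || !identical(h$lim, hists[[1]]$lim))
      stop("histograms use different binning")
    if (!isTRUE(h$normalized)) stop("histograms must be normalized")
  }
  counts <- Reduce(`+`, lapply(hists, `[[`, "counts")) / length(hists)
  out <- new_joint_histogram(counts, hists[[1]]$plane,
                             sum(vapply(hists, `[[`, 0, "n_pixels_total")),
                             sum(vapply(hists, `[[`, 0, "n_pixels_out_of_range")),
                             TRUE, hists[[1]]$nbins, hists[[1]]$lim)
  out$n_images <- length(hists)
  out
}

#' Chromogram: per-bin mean color of a joint histogram
#'
#' Colors each occupied bin of the joint histogram with the mean sRGB-encoded
#' value of the pixels that fall into it; empty bins are flagged in `support`
#' and carry `NA` color.
#'
#' @param img HxWx3 sRGB-encoded array aligned with `dkl`.
#' @param dkl the `dkl_image` of the same pixels.
#' @inheritParams compute_joint_histogram
#' @return A `chromogram`: list with `plane`, `mean_color`
#'   (nbins x nbins x 3), `support` (nbins x nbins logical).
#' @export
compute_chromogram <- function(img, dkl, plane = plane_pair("lm_s"),
                               nbins = 128L, lim = c(-2, 2)) {
  if (is.character(plane)) plane <- plane_pair(plane)
  if (!identical(dim(img)[1:2], dim(dkl$ach))) stop("image and DKL shapes differ")
  co <- plane_coords(dkl, plane)
  ix <- bin_index(co$x, nbins, lim)
  iy <- bin_index(co$y, nbins, lim)
  ok <- ix > 0L & iy > 0L
  lin <- ix[ok] + (iy[ok] - 1L) * nbins
  px <- pixel_matrix(img)[ok, , drop = FALSE]
  n_by_bin <- tabulate(lin, nbins * nbins)
  mean_color <- array(NA_real_, c(nbins, nbins, 3))
  for (ch in 1:3) {
    s <- rep(0, nbins * nbins)
    acc <- rowsum(px[, ch], lin)
    s[as.integer(rownames(acc))] <- acc
    mean_color[, , ch] <- matrix(ifelse(n_by_bin > 0, s / pmax(n_by_bin, 1), NA_real_),
                                 nbins, nbins)
  }
  structure(list(plane = plane, mean_color = mean_color,
                 support = matrix(n_by_bin > 0, nbins, nbins),
                 nbins = nbins, lim = lim),
            class = "chromogram")
}

#' Serialize a joint histogram to CSV
#'
#' Long format with one row per bin: `bin_x_center`, `bin_y_center`, `value`.
#'
#' @param hist a `joint_histogram`.
#' @param path output CSV path.
#' @param keep_zero write all bins (default drops empty bins).
#' @return `path`, invisibly.
#' @export
write_histogram_csv <- function(hist, path, keep_zero = FALSE) {
  cx <- hist_bin_centers(hist$nbins, hist$lim)
  df <- data.frame(bin_x_center = rep(cx, times = hist$nbins),
                   bin_y_center = rep(cx, each = hist$nbins),
                   value = as.numeric(hist$counts))
  if (!keep_zero) df <- df[df$value > 0, ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
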