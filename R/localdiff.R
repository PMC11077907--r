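#' Central square crop and bicubic resize
#'
#' Crops the centered `min(H, W)` square (offsets floored) and resizes it to
#' `side` x `side` with Keys bicubic interpolation (a = -0.5), antialiased
#' when downsampling; output clipped to [0, 1]. This is the preprocessing
#' applied before the local chromatic/achromatic difference analysis.
#'
#' @param img HxWx3 array in [0, 1].
#' @param side output side length (default 256).
#' @return `side` x `side` x 3 array.
#' @export
central_crop_resize <- function(img, side = 256L) {
  d <- dim(img)
  if (d[1] < 2 || d[2] < 2) stop("image must be at least 2x2")
  s <- min(d[1], d[2])
  r0 <- floor((d[1] - s) / 2)
  c0 <- floor((d[2] - s) / 2)
  cropped <- img[(r0 + 1):(r0 + s), (c0 + 1):(c0 + s), , drop = FALSE]
  resize_bicubic(cropped, side, side)
}

keys_cubic <- function(x, a = -0.5) {
  ax <- abs(x)
  ifelse(ax <= 1, (a + 2) * ax^3 - (a + 3) * ax^2 + 1,
         ifelse(ax < 2, a * (ax^3 - 5 * ax^2 + 8 * ax - 4), 0))
}

# out_n x in_n row-stochastic interpolation weights along one dimension;
# kernel widened by 1/scale when downsampling (antialiasing), borders clamped
bicubic_weights <- function(in_n, out_n) {
  scale <- out_n / in_n
  ksc <- min(scale, 1)
  support <- 2 / ksc
  u <- (seq_len(out_n) - 0.5) / scale + 0.5   # 1-based input coordinate
  W <- matrix(0, out_n, in_n)
  for (i in seq_len(out_n)) {
    lo <- floor(u[i] - support)
    j <- lo:(lo + ceiling(2 * support) + 1)
    w <- keys_cubic((u[i] - j) * ksc) * ksc
    keep <- w != 0
    j <- pmin(pmax(j[keep], 1L), in_n)        # replicate border samples
    w <- w[keep]
    acc <- rowsum(w, j)
    W[i, as.integer(rownames(acc))] <- acc / sum(w)
  }
  W
}

#' Bicubic image resampling
#'
#' Separable Keys cubic convolution (a = -0.5) with antialiasing on
#' downsampling and border replication, the convention of Matlab-style
#' `imresize`. Identity when the size is unchanged.
#'
#' @param img HxW matrix or HxWx3 array in [0, 1].
#' @param out_h,out_w output dimensions.
#' @return resampled array, clipped to [0, 1].
#' @export
resize_bicubic <- function(img, out_h, out_w) {
  d <- dim(img)
  Wr <- bicubic_weights(d[1], out_h)
  Wc <- bicubic_weights(d[2], out_w)
  if (length(d) == 2) return(pmin(pmax(Wr %*% img %*% t(Wc), 0), 1))
  out <- array(0, c(out_h, out_w, d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- Wr %*% img[, , ch] %*% t(Wc)
  pmin(pmax(out, 0), 1)
}

# interior view of m shifted by (dr, dc); result is (n-2) x (p-2)
shift_mat <- function(m, dr, dc) {
  n <- nrow(m); p <- ncol(m)
  m[(2 + dr):(n - 1 + dr), (2 + dc):(p - 1 + dc)]
}

#' Local 8-neighbor chromatic and achromatic difference maps
#'
#' For each interior pixel, the mean over its eight neighbors of the Euclidean
#' distance in the (u', v') chromaticity plane (chromatic map) and of the
#' absolute difference in the L plane (achromatic map). The one-pixel border,
#' where the 8-neighborhood is undefined, is excluded.
#'
#' @param luv a `luv_image` (at least 3x3).
#' @return list with `chromatic` and `achromatic` (H-2)x(W-2) matrices.
#' @export
local_difference_maps <- function(luv) {
  d <- dim(luv$L)
  if (d[1] < 3 || d[2] < 3) stop("image must be at least 3x3")
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  u0 <- shift_mat(luv$u, 0, 0); v0 <- shift_mat(luv$v, 0, 0); L0 <- shift_mat(luv$L, 0, 0)
  chrom <- achro <- matrix(0, d[1] - 2, d[2] - 2)
  for (k in seq_len(nrow(offs))) {
    du <- shift_mat(luv$u, offs$dr[k], offs$dc[k]) - u0
    dv <- shift_mat(luv$v, offs$dr[k], offs$dc[k]) - v0
    dL <- shift_mat(luv$L, offs$dr[k], offs$dc[k]) - L0
    chrom <- chrom + sqrt(du^2 + dv^2)
    achro <- achro + abs(dL)
  }
  list(chromatic = chrom / 8, achromatic = achro / 8)
}

#' Per-image local difference record
#'
#' Full chain: central crop, bicubic resize to `side` x `side`, conversion to
#' CIELUV, 8-neighbor difference maps, and the mean over interior pixels of
#' each map.
#'
#' @param img HxWx3 sRGB array in [0, 1].
#' @param source_id identifier carried into the record (defaults to the
#'   array's `source_id` attribute if present).
#' @param group corpus label.
#' @param side resize target (default 256).
#' @param cfg a [dkl_config()] (for the RGB -> XYZ matrix).
#' @param L_channel luminance channel passed to [srgb_to_luv()].
#' @return one-row data.frame: `source_id`, `group`, `chromatic_diff`,
#'   `achromatic_diff`.
#' @export
image_local_diffs <- function(img, source_id = NULL, group = "",
                              side = 256L, cfg = dkl_config(),
                              L_channel = c("Y", "Lstar")) {
  if (is.null(source_id))
    source_id <- if (!is.null(attr(img, "source_id"))) attr(img, "source_id") else ""
  luv <- srgb_to_luv(central_crop_resize(img, side), cfg, match.arg(L_channel))
  maps <- local_difference_maps(luv)
  data.frame(source_id = source_id, group = group,
             chromatic_diff = mean(maps$chromatic),
             achromatic_diff = mean(maps$achromatic),
             stringsAsFactors = FALSE)
}

#' Correlation of chromatic and achromatic local differences
#'
#' Pearson correlation between the per-image chromatic and achromatic
#' difference means within one corpus, with a t-approximation p-value
#' (two-sided by default; a one-sided alternative can be requested).
#'
#' @param records data.frame of [image_local_diffs()] rows.
#' @param group optional corpus label to filter on (default: use all rows).
#' @param alternative passed to [stats::cor.test()].
#' @return one-row data.frame: `group`, `n`, `r`, `p`.
#' @export
correlate_diffs <- function(records, group = NULL,
                            alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!is.null(group)) records <- records[records$group == group, ]
  if (nrow(records) < 3) stop("need at least 3 records")
  x <- records$chromatic_diff
  y <- records$achromatic_diff
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = alternative)
  data.frame(group = if (is.null(group)) "" else group, n = nrow(records),
             r = unname(ct$estimate), p = ct$p.value,
             stringsAsFactors = FALSE)
}
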