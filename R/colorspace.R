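#' Cone-opponent (DKL) color-space configuration
#'
#' Builds the fixed transform used throughout the package: sRGB-encoded pixels
#' are decoded to linear light, mapped to CIE XYZ, then to LMS cone excitations,
#' and expressed as opponent contrasts relative to an adapting mid-gray
#' background. The three opponent axes are the achromatic axis (L+M excitation
#' difference), the L/M "teal--cherry" axis (L-M), and the S "violet--lime" axis
#' (S-(L+M)). Axis scales are calibrated so that the most extreme RGB-cube
#' corner on each axis maps to magnitude 2, placing the whole display gamut
#' inside the [-2, 2] histogram range.
#'
#' @param rgb_to_xyz 3x3 matrix mapping linear RGB to XYZ. Default: IEC sRGB
#'   primaries with D65 white.
#' @param xyz_to_lms 3x3 matrix mapping XYZ to LMS. Default:
#'   Hunt-Pointer-Estevez, D65-normalized.
#' @param background_rgb length-3 linear RGB of the adapting background
#'   (defines the DKL origin). Default mid-gray `c(0.5, 0.5, 0.5)`.
#' @param axis_sign length-3 vector in \{-1, +1\} giving the polarity of the
#'   (achromatic, L/M, S) axes. The default `c(1, 1, -1)` orients +L/M toward
#'   cherry/red and +S toward lime/yellow, so the warm red-orange-yellow hues
#'   occupy the (+,+) quadrant of the isoluminant plane and blue falls at
#'   negative S.
#' @param axis_scale length-3 positive scale factors; `NULL` (default)
#'   calibrates each axis so the RGB-cube corner of largest magnitude maps to 2.
#' @return An object of class `dkl_config`.
#' @examples
#' cfg <- dkl_config()
#' srgb_to_dkl(fixture_images()$gray, cfg)$lm[1, 1]  # background -> origin
#' @export
dkl_config <- function(rgb_to_xyz = NULL, xyz_to_lms = NULL,
                       background_rgb = c(0.5, 0.5, 0.5),
                       axis_sign = c(1, 1, -1), axis_scale = NULL) {
  if (is.null(rgb_to_xyz)) {
    rgb_to_xyz <- matrix(c(
      0.4124564, 0.3575761, 0.1804375,
      0.2126729, 0.7151522, 0.0721750,
      0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  }
  if (is.null(xyz_to_lms)) {
    xyz_to_lms <- matrix(c(
      0.4002, 0.7076, -0.0808,
      -0.2263, 1.1653, 0.0457,
      0.0000, 0.0000, 0.9182), 3, 3, byrow = TRUE)
  }
  stopifnot(is.matrix(rgb_to_xyz), dim(rgb_to_xyz) == c(3, 3),
            is.matrix(xyz_to_lms), dim(xyz_to_lms) == c(3, 3),
            length(background_rgb) == 3, length(axis_sign) == 3,
            all(axis_sign %in% c(-1, 1)))
  if (abs(det(rgb_to_xyz)) < 1e-12 || abs(det(xyz_to_lms)) < 1e-12)
    stop("color-space matrices must be invertible")
  rgb_to_lms <- xyz_to_lms %*% rgb_to_xyz
  # opponent rows: ach = dL + dM; lm = dL - k*dM; s = dS - k2*(dL + dM).
  # k, k2 null the achromatic (R=G=B) direction exactly, so achromatic inputs
  # carry no chromatic signal under whatever fundamentals are configured.
  w <- as.numeric(rgb_to_lms %*% c(1, 1, 1))
  opponent <- rbind(ach = c(1, 1, 0),
                    lm = c(1, -w[1] / w[2], 0),
                    s = c(-w[3] / (w[1] + w[2]), -w[3] / (w[1] + w[2]), 1))
  background_lms <- as.numeric(rgb_to_lms %*% background_rgb)
  if (any(background_lms <= 0))
    stop("background cone excitations must be strictly positive")
  if (is.null(axis_scale)) {
    corners <- t(as.matrix(expand.grid(0:1, 0:1, 0:1)))
    raw <- opponent %*% (rgb_to_lms %*% corners - background_lms)
    axis_scale <- 2 / apply(abs(raw), 1, max)
  }
  stopifnot(length(axis_scale) == 3, all(axis_scale > 0))
  structure(list(rgb_to_xyz = rgb_to_xyz, xyz_to_lms = xyz_to_lms,
                 rgb_to_lms = rgb_to_lms, opponent = opponent,
                 background_rgb = as.numeric(background_rgb),
                 background_lms = background_lms,
                 axis_sign = as.numeric(axis_sign),
                 axis_scale = as.numeric(axis_scale)),
            class = "dkl_config")
}

#' @export
print.dkl_config <- function(x, ...) {
  cat("DKL color-space configuration\n")
  cat("  background (linear RGB):", format(x$background_rgb), "\n")
  cat("  axis_sign :", format(x$axis_sign), "\n")
  cat("  axis_scale:", format(x$axis_scale, digits = 5), "\n")
  invisible(x)
}

#' Read a flat key-value color-space configuration file
#'
#' Accepted keys (all optional): `rgb_to_xyz`, `xyz_to_lms` (9 numbers each,
#' row-major), `background_rgb`, `axis_scale`, `axis_sign`.
#'
#' @param path YAML file with flat keys.
#' @return A `dkl_config`.
#' @export
read_dkl_config <- function(path) {
  kv <- yaml::read_yaml(path)
  as_mat <- function(v) if (is.null(v)) NULL else matrix(as.numeric(v), 3, 3, byrow = TRUE)
  dkl_config(rgb_to_xyz = as_mat(kv$rgb_to_xyz),
             xyz_to_lms = as_mat(kv$xyz_to_lms),
             background_rgb = if (is.null(kv$background_rgb)) c(0.5, 0.5, 0.5) else as.numeric(kv$background_rgb),
             axis_sign = if (is.null(kv$axis_sign)) c(1, 1, -1) else as.numeric(kv$axis_sign),
             axis_scale = if (is.null(kv$axis_scale)) NULL else as.numeric(kv$axis_scale))
}

check_unit_range <- function(x, what = "image") {
  if (!all(is.finite(x))) stop(what, " contains non-finite values")
  if (min(x) < 0 || max(x) > 1) stop(what, " values must lie in [0, 1]")
  invisible(x)
}

#' sRGB transfer function
#'
#' Channelwise electro-optical decoding (`srgb_to_linear`) and its inverse
#' encoding (`linear_to_srgb`), per the standard sRGB piecewise curve.
#'
#' @param img array or vector of sRGB-encoded values in [0, 1].
#' @return Object of the same shape with decoded (linear-light) values.
#' @export
srgb_to_linear <- function(img) {
  check_unit_range(img, "sRGB")
  out <- ifelse(img <= 0.04045, img / 12.92, ((img + 0.055) / 1.055)^2.4)
  attributes(out) <- attributes(img)
  out
}

#' @rdname srgb_to_linear
#' @param linear array or vector of linear-light values in [0, 1].
#' @export
linear_to_srgb <- function(linear) {
  check_unit_range(linear, "linear RGB")
  out <- ifelse(linear <= 0.0031308, 12.92 * linear,
                1.055 * linear^(1 / 2.4) - 0.055)
  attributes(out) <- attributes(linear)
  out
}

# flatten HxWx3 to (H*W)x3, run f, reshape back per-plane
pixel_matrix <- function(img) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  dim(img) <- c(prod(dim(img)[1:2]), 3)
  img
}

#' Convert linear RGB to DKL opponent coordinates
#'
#' Pixels are mapped RGB -> XYZ -> LMS; opponent coordinates are formed as
#' excitation differences relative to the background LMS, then signed and
#' scaled per the configuration. The background itself maps to (0, 0, 0); the
#' map is affine in linear RGB.
#'
#' @param linear HxWx3 array of linear RGB in [0, 1].
#' @param cfg a [dkl_config()].
#' @return A `dkl_image`: list with HxW matrices `ach`, `lm`, `s`.
#' @export
linear_to_dkl <- function(linear, cfg = dkl_config()) {
  stopifnot(inherits(cfg, "dkl_config"))
  check_unit_range(linear, "linear RGB")
  hw <- dim(linear)[1:2]
  px <- pixel_matrix(linear)
  raw <- (px %*% t(cfg$rgb_to_lms) -
            matrix(cfg$background_lms, nrow(px), 3, byrow = TRUE)) %*% t(cfg$opponent)
  dkl <- raw * matrix(cfg$axis_sign * cfg$axis_scale, nrow(px), 3, byrow = TRUE)
  structure(list(ach = matrix(dkl[, 1], hw[1], hw[2]),
                 lm = matrix(dkl[, 2], hw[1], hw[2]),
                 s = matrix(dkl[, 3], hw[1], hw[2])),
            class = "dkl_image")
}

#' @rdname linear_to_dkl
#' @param img HxWx3 array of sRGB-encoded values in [0, 1].
#' @export
srgb_to_dkl <- function(img, cfg = dkl_config()) {
  linear_to_dkl(srgb_to_linear(img), cfg)
}

#' Invert the DKL transform back to linear RGB
#'
#' Used by the synthetic generator to author pixels directly in DKL. Values
#' outside the display gamut are reported, not clipped.
#'
#' @param dkl a `dkl_image`.
#' @param cfg a [dkl_config()].
#' @return list with `linear` (HxWx3, unclipped) and `out_of_gamut`
#'   (HxW logical).
#' @export
dkl_to_linear <- function(dkl, cfg = dkl_config()) {
  hw <- dim(dkl$ach)
  coords <- cbind(as.numeric(dkl$ach), as.numeric(dkl$lm), as.numeric(dkl$s))
  raw <- coords / matrix(cfg$axis_sign * cfg$axis_scale, nrow(coords), 3, byrow = TRUE)
  lms <- raw %*% t(solve(cfg$opponent)) +
    matrix(cfg$background_lms, nrow(coords), 3, byrow = TRUE)
  px <- lms %*% t(solve(cfg$rgb_to_lms))
  oog <- matrix(px[, 1] < 0 | px[, 1] > 1 | px[, 2] < 0 | px[, 2] > 1 |
                  px[, 3] < 0 | px[, 3] > 1, hw[1], hw[2])
  linear <- array(pmin(pmax(px, 0), 1), c(hw, 3))
  list(linear = linear, out_of_gamut = oog)
}

#' Convert sRGB to CIELUV chromaticity and luminance
#'
#' Computes the CIE 1976 uniform chromaticity coordinates
#' u' = 4X / (X + 15Y + 3Z), v' = 9Y / (X + 15Y + 3Z) and a luminance channel.
#' By default L is the relative luminance Y in [0, 1]; `L_channel = "Lstar"`
#' gives CIE L* instead. Black pixels (X = Y = Z = 0) take the white-point
#' (u', v') to avoid 0/0.
#'
#' @param img HxWx3 sRGB-encoded array in [0, 1].
#' @param cfg a [dkl_config()] (supplies the RGB -> XYZ matrix).
#' @param L_channel `"Y"` (relative luminance, default) or `"Lstar"`.
#' @return A `luv_image`: list with HxW matrices `L`, `u`, `v`.
#' @export
srgb_to_luv <- function(img, cfg = dkl_config(), L_channel = c("Y", "Lstar")) {
  L_channel <- match.arg(L_channel)
  check_unit_range(img, "sRGB")
  hw <- dim(img)[1:2]
  xyz <- pixel_matrix(srgb_to_linear(img)) %*% t(cfg$rgb_to_xyz)
  white <- as.numeric(cfg$rgb_to_xyz %*% c(1, 1, 1))
  wden <- white[1] + 15 * white[2] + 3 * white[3]
  den <- xyz[, 1] + 15 * xyz[, 2] + 3 * xyz[, 3]
  zero <- den <= 0
  u <- ifelse(zero, 4 * white[1] / wden, 4 * xyz[, 1] / den)
  v <- ifelse(zero, 9 * white[2] / wden, 9 * xyz[, 2] / den)
  Y <- xyz[, 2] / white[2]
  L <- if (L_channel == "Y") Y else {
    ifelse(Y > (6 / 29)^3, 116 * Y^(1 / 3) - 16, (29 / 3)^3 * Y)
  }
  structure(list(L = matrix(L, hw[1], hw[2]),
                 u = matrix(u, hw[1], hw[2]),
                 v = matrix(v, hw[1], hw[2])),
            class = "luv_image")
}

#' Project the RGB display cube into the DKL planes
#'
#' Samples a regular lattice over the RGB cube and returns its DKL
#' coordinates. Used to draw gamut outlines and to check the [-2, 2]
#' calibration of the axis scales.
#'
#' @param cfg a [dkl_config()].
#' @param samples_per_edge lattice resolution per cube edge (>= 2).
#' @return data.frame with columns `r`, `g`, `b` (linear RGB) and
#'   `ach`, `lm`, `s`.
#' @export
rgb_cube_projection <- function(cfg = dkl_config(), samples_per_edge = 8) {
  stopifnot(samples_per_edge >= 2)
  u <- seq(0, 1, length.out = samples_per_edge)
  grid <- as.matrix(expand.grid(r = u, g = u, b = u))
  arr <- array(grid, c(nrow(grid), 1, 3))
  dkl <- linear_to_dkl(arr, cfg)
  data.frame(r = grid[, 1], g = grid[, 2], b = grid[, 3],
             ach = as.numeric(dkl$ach), lm = as.numeric(dkl$lm),
             s = as.numeric(dkl$s))
}
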